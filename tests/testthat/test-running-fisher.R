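# Frozen golden values below were computed ahead of implementation by
# term-by-term tail summation with exact rational arithmetic.

test_that("hypergeometric upper tail matches the exact-summation value", {
  expect_equal(hypergeometric_enrichment_p(5, 10, 10, 100),
               6.7162774826505e-4, tolerance = 1e-10)
  expect_identical(hypergeometric_enrichment_p(0, 10, 10, 100), 1)
  expect_identical(hypergeometric_enrichment_p(1, 1, 1, 1), 1)
  # agrees with the summation oracle across random valid inputs
  set.seed(17)
  for (i in 1:50) {
    N <- sample(10:1e4, 1)
    n <- sample(1:min(N, 500), 1)
    K <- sample(1:min(N, 500), 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeometric_enrichment_p(k, K, n, N),
                 oracle_hyper_tail(k, K, n, N), tolerance = 1e-9)
  }
})

test_that("hypergeometric bounds are validated", {
  expect_error(hypergeometric_enrichment_p(5, 4, 10, 100), "bounds")
  expect_error(hypergeometric_enrichment_p(2, 10, 1, 100), "bounds")
  expect_error(hypergeometric_enrichment_p(0, 10, 200, 100), "bounds")
  expect_error(hypergeometric_enrichment_p(-1, 4, 4, 100), "bounds")
})

test_that("ranking is by |FC| desc, then p asc, then symbol, order-invariant", {
  g <- gene_table(c("A", "B", "C"), c(2.0, -3.0, 1.5), c(0.01, 0.02, 0.03))
  expect_identical(rank_by_magnitude(g)$symbol, c("B", "A", "C"))
  tie <- gene_table(c("T2", "T1"), c(2.0, 2.0), c(0.02, 0.01))
  expect_identical(rank_by_magnitude(tie)$symbol, c("T1", "T2"))
  symtie <- gene_table(c("Z", "Y"), c(2.0, 2.0), c(0.01, 0.01))
  expect_identical(rank_by_magnitude(symtie)$symbol, c("Y", "Z"))
  set.seed(5)
  g2 <- gene_table(sprintf("G%02d", 1:40),
                   sample(c(-1, 1), 40, TRUE) * sample(seq(1.2, 3, 0.2), 40, TRUE),
                   sample(c(0.01, 0.02), 40, TRUE))
  perm <- g2[sample(40), ]
  expect_identical(rank_by_magnitude(perm), rank_by_magnitude(g2))
})

test_that("a fully contained query attains its minimum at the full prefix", {
  universe <- sprintf("G%04d", 1:1000)
  query <- universe[1:4]
  res <- running_fisher_pair(query, query, 1000)
  expect_equal(res$p_raw, 2.4144602167247258e-11, tolerance = 1e-9)
  expect_equal(res$p_corrected, 4 * res$p_raw)
  expect_equal(res$best_prefix_length, 4L)
  expect_equal(res$overlap_at_best, 4L)
})

test_that("disjoint query and target give corrected p of 1", {
  res <- running_fisher_pair(c("A", "B"), c("C", "D"), 100)
  expect_equal(res$p_corrected, 1)
  expect_equal(res$overlap_at_best, 0L)
})

test_that("empty query or target is no evidence, not an error", {
  for (res in list(running_fisher_pair(character(0), "A", 100),
                   running_fisher_pair("A", character(0), 100))) {
    expect_equal(res$p_raw, 1)
    expect_equal(res$p_corrected, 1)
    expect_equal(res$overlap_at_best, 0L)
  }
})

test_that("pair scan equals exhaustive prefix enumeration on random instances", {
  set.seed(29)
  for (i in 1:120) {
    inst <- random_pair_instance()
    got <- running_fisher_pair(inst$query, inst$target, inst$N)
    want <- oracle_pair(inst$query, inst$target, inst$N)
    expect_equal(got$p_raw, want$p_raw, tolerance = 1e-9)
    expect_equal(got$p_corrected, want$p_corrected, tolerance = 1e-9)
    expect_equal(got$best_prefix_length, want$best_prefix_length)
    expect_equal(got$overlap_at_best, want$overlap_at_best)
    expect_true(got$p_raw > 0 && got$p_corrected <= 1)
    expect_true(got$p_corrected >= got$p_raw)
  }
})

test_that("the frozen six-gene directional trace reproduces exactly", {
  bm <- biomarker(data.frame(
    symbol = c("U1", "U2", "U3", "D1", "D2", "D3"),
    fold_change = c(2.0, 1.8, 1.6, -2.2, -1.9, -1.7)))
  bs <- make_bioset(c("U1", "U2", "D1", "D2", "X1", "X2"),
                    c(1.5, 1.4, -1.6, -1.3, 1.9, -2.5),
                    c(0.01, 0.02, 0.01, 0.03, 0.005, 0.001),
                    bioset_id = "trace", universe_size = 100)
  res <- signed_correlation_score(bm, bs)
  expect_equal(res$pairs[["++"]]$p_corrected, 0.0018181818181818,
               tolerance = 1e-10)
  expect_equal(res$pairs[["++"]]$best_prefix_length, 2L)
  expect_equal(res$pairs[["--"]]$p_corrected, 0.0018181818181818,
               tolerance = 1e-10)
  expect_equal(res$pairs[["+-"]]$p_corrected, 1)
  expect_equal(res$pairs[["-+"]]$p_corrected, 1)
  expect_equal(res$signed_score, 4.34655348308988, tolerance = 1e-9)
  expect_identical(res$call, "activator")
})

test_that("maximal concordance and its mirror produce confident calls", {
  path <- system.file("extdata", "synthetic_nfkb_biomarker_s1_style.tsv",
                      package = "biosetscreen")
  bm <- read_biomarker(path)
  # embed the biomarker symbols into the simulation universe convention
  self <- bioset(data.frame(symbol = bm$genes$symbol,
                            fold_change = bm$genes$fold_change,
                            p_value = 0.001), bioset_id = "self",
                 universe_size = 20000)
  res <- signed_correlation_score(bm, self)
  expect_identical(res$call, "activator")
  expect_gt(res$signed_score, 4)
  flipped <- signed_correlation_score(bm, flip_bioset(self))
  expect_identical(flipped$call, "suppressor")
  expect_equal(flipped$signed_score, -res$signed_score)
})

test_that("flipping a bioset exactly negates the signed score", {
  spec0 <- synthetic_spec(universe_size = 3000, n_de = 120, seed = 1)
  bm <- simulate_biomarker(spec0, n_up = 20, n_down = 15)
  for (s in 1:40) {
    spec <- synthetic_spec(universe_size = 3000, n_de = 120,
                           signal_fraction = runif(1), concordance = runif(1),
                           seed = s)
    sim <- simulate_bioset(bm, spec, mode = "activator")
    a <- signed_correlation_score(bm, sim$bioset)$signed_score
    b <- signed_correlation_score(bm, flip_bioset(sim$bioset))$signed_score
    expect_identical(a, -b)
  }
})

test_that("concordant additions never lower, discordant never raise the score", {
  spec <- synthetic_spec(universe_size = 3000, n_de = 100,
                         signal_fraction = 0.5, seed = 77)
  bm <- simulate_biomarker(spec, n_up = 20, n_down = 15)
  sim <- simulate_bioset(bm, spec, mode = "activator")
  base <- signed_correlation_score(bm, sim$bioset)$signed_score
  absent <- bm$genes[!bm$genes$symbol %in% sim$bioset$genes$symbol, ]
  add_gene <- function(row, sign_mult) {
    b <- sim$bioset
    b$genes <- rbind(data.frame(symbol = row$symbol,
                                fold_change = sign_mult * 10 *
                                  sign(row$fold_change),
                                p_value = 1e-6), b$genes)
    b
  }
  for (i in seq_len(min(5, nrow(absent)))) {
    conc <- signed_correlation_score(bm, add_gene(absent[i, ], 1))$signed_score
    disc <- signed_correlation_score(bm, add_gene(absent[i, ], -1))$signed_score
    expect_gte(conc, base)
    expect_lte(disc, base)
  }
})

test_that("an empty bioset scores zero and is inconclusive", {
  bm <- simulate_biomarker(synthetic_spec(seed = 2), n_up = 5, n_down = 5)
  empty <- bioset(gene_table(character(0), numeric(0), numeric(0)),
                  bioset_id = "empty")
  res <- signed_correlation_score(bm, empty)
  expect_identical(res$signed_score, 0)
  expect_identical(res$call, "inconclusive")
})

test_that("extreme concordance caps the score at 300 with a flag", {
  spec <- synthetic_spec(seed = 4)
  bm <- simulate_biomarker(spec)
  self <- bioset(data.frame(symbol = bm$genes$symbol,
                            fold_change = bm$genes$fold_change,
                            p_value = 0.001), universe_size = 20000)
  res <- signed_correlation_score(bm, self)
  expect_true(res$capped)
  expect_equal(abs(res$signed_score), 300)
})
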