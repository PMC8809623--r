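# Independent oracles used by the unit and acceptance tests. These never
# call the implementation paths they check: the hypergeometric tail is a
# term-by-term summation of the probability mass function and the pair
# oracle enumerates every rank prefix directly.

oracle_hyper_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(exp(lchoose(n, i) + lchoose(N - n, K - i) - lchoose(N, K)))
}

oracle_pair <- function(query, target, N) {
  if (length(query) == 0L || length(target) == 0L) {
    return(list(p_raw = 1, p_corrected = 1, best_prefix_length = 0L,
                overlap_at_best = 0L))
  }
  best_p <- 2
  best_j <- 0L
  best_k <- 0L
  for (j in seq_along(query)) {
    k <- length(intersect(query[seq_len(j)], target))
    p <- oracle_hyper_tail(k, j, length(target), N)
    if (p < best_p - 1e-15 * best_p) {
      best_p <- p
      best_j <- j
      best_k <- k
    }
  }
  list(p_raw = best_p, p_corrected = min(1, best_p * length(query)),
       best_prefix_length = best_j, overlap_at_best = best_k)
}

# quick constructors
gene_table <- function(symbol, fold_change, p_value = 0.01) {
  data.frame(symbol = symbol, fold_change = fold_change,
             p_value = rep_len(p_value, length(symbol)),
             stringsAsFactors = FALSE)
}

make_bioset <- function(symbol, fold_change, p_value = 0.01, ...) {
  bioset(gene_table(symbol, fold_change, p_value), ...)
}

random_pair_instance <- function() {
  N <- sample(20:200, 1)
  nq <- sample(1:25, 1)
  nt <- sample(1:min(25, N), 1)
  universe <- sprintf("G%03d", seq_len(N))
  list(query = sample(universe, nq), target = sample(universe, nt), N = N)
}
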