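# Independent oracles the implementation is checked against.  None of these
# share code paths with the package: edges via all-pairs adist, shortest
# paths via Floyd-Warshall, clustering via adjacency-matrix triangle
# counting, the sampler via exact path enumeration, and a hand-written
# dynamic-programming edit distance.

# unit-cost Levenshtein by the textbook DP recurrence
lev_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(x) + 1L, length(y) + 1L)
  d[, 1L] <- 0:length(x)
  d[1L, ] <- 0:length(y)
  for (i in seq_along(x)) for (j in seq_along(y))
    d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                             d[i, j] + (x[i] != y[j]))
  d[length(x) + 1L, length(y) + 1L]
}

# all-pairs Levenshtein-1 edge set, lexicographically sorted 2-column matrix
oracle_edges <- function(words) {
  if (length(words) < 2L) return(matrix(character(0), ncol = 2L))
  D <- utils::adist(words, words, useBytes = FALSE)
  hit <- which(D == 1L & upper.tri(D), arr.ind = TRUE)
  if (nrow(hit) == 0L) return(matrix(character(0), ncol = 2L))
  a <- pmin(words[hit[, 1L]], words[hit[, 2L]])
  b <- pmax(words[hit[, 1L]], words[hit[, 2L]])
  o <- order(a, b, method = "radix")
  cbind(a[o], b[o])
}

random_words <- function(n, alphabet_size = 5L, max_len = 6L) {
  unique(replicate(n, paste0(
    sample(letters[seq_len(alphabet_size)], sample.int(max_len, 1L),
           replace = TRUE), collapse = "")))
}

# Floyd-Warshall all-pairs shortest paths on an adjacency matrix
oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  d
}

oracle_avg_path_length <- function(adj) {
  d <- oracle_floyd_warshall(adj)
  vals <- d[is.finite(d) & d > 0]
  mean(vals)
}

oracle_diameter <- function(adj) {
  d <- oracle_floyd_warshall(adj)
  max(d[is.finite(d)])
}

# mean local clustering via triangle counting: T_i = (A^3)_ii / 2
oracle_avg_clustering <- function(adj) {
  deg <- rowSums(adj)
  tri <- diag(adj %*% adj %*% adj) / 2
  ci <- 2 * tri / (deg * (deg - 1))
  mean(ci[deg >= 2])
}

# exact successive-sampling probability of drawing each m-subset, by
# enumerating every ordered draw path
oracle_subset_probs <- function(weights, m) {
  n <- length(weights)
  probs <- new.env()
  recurse <- function(remaining, chosen, p) {
    if (length(chosen) == m) {
      key <- paste(sort(chosen), collapse = ",")
      prev <- mget(key, envir = probs, ifnotfound = 0)[[1]]
      assign(key, prev + p, envir = probs)
      return(invisible())
    }
    w <- weights[remaining]
    for (i in seq_along(remaining))
      recurse(remaining[-i], c(chosen, remaining[i]),
              p * w[i] / sum(w))
  }
  recurse(seq_len(n), integer(0), 1)
  unlist(as.list(probs))
}

# random connected-ish igraph for metric oracles
random_test_graph <- function(n, p = 0.05) {
  igraph::sample_gnp(n, p, directed = FALSE)
}

adj_of <- function(ig) {
  as.matrix(igraph::as_adjacency_matrix(ig, sparse = FALSE))
}

# small synthetic corpus + cohort used by several tests
small_demo_cohort <- function(seed = 1L, n_types = 1000L,
                              n_participants = 3L) {
  cp <- generate_corpus(corpus_gen_config(n_types = n_types, seed = seed))
  sch <- growth_schedule(c("1", "2", "3"),
                         round(n_types * c(0.2, 0.35, 0.6)))
  list(corpus = cp,
       cohort = simulate_cohort(cp, sch, n_participants, base_seed = seed),
       schedule = sch)
}
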