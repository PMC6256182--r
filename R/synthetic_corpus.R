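#' Configuration for the synthetic frequency-lexicon generator
#'
#' The generator emulates the statistical structure of a children's print
#' corpus that the downstream analysis relies on: a Zipfian token-frequency
#' distribution over word types, word lengths that shorten with frequency
#' (high-frequency words are short, hence neighbour-rich), and a substantial
#' fraction of types with no edit-distance-1 neighbour at all.
#'
#' @param n_types number of distinct word types to generate.
#' @param zipf_exponent exponent of the frequency power law: the type at
#'   frequency rank `r` has frequency proportional to `r^-zipf_exponent`.
#' @param alphabet the character inventory, either a single string or a
#'   character vector of single characters; at least 2 distinct symbols.
#' @param length_min,length_max inclusive bounds on word length.
#' @param length_frequency_link real in `[0, 1]`: 0 makes word length
#'   independent of frequency rank; 1 moves the expected length linearly
#'   from `length_min` (rank 1) to `length_max` (rank `n_types`).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a `corpus_gen_config` list.
#' @export
corpus_gen_config <- function(n_types = 5000L,
                              zipf_exponent = 1,
                              alphabet = letters,
                              length_min = 2L,
                              length_max = 7L,
                              length_frequency_link = 0.7,
                              seed = 1L) {
  if (length(alphabet) == 1L && nchar(alphabet) > 1L)
    alphabet <- strsplit(alphabet, "", fixed = TRUE)[[1L]]
  alphabet <- unique(stringi::stri_trans_nfc(alphabet))
  n_types <- as.integer(n_types)
  length_min <- as.integer(length_min)
  length_max <- as.integer(length_max)
  stopifnot(n_types >= 1L, zipf_exponent > 0,
            length_min >= 1L, length_min <= length_max,
            length_frequency_link >= 0, length_frequency_link <= 1)
  if (length(alphabet) < 2L)
    stop("alphabet must contain at least 2 distinct characters")
  structure(list(n_types = n_types, zipf_exponent = zipf_exponent,
                 alphabet = alphabet, length_min = length_min,
                 length_max = length_max,
                 length_frequency_link = length_frequency_link,
                 seed = as.integer(seed)),
            class = "corpus_gen_config")
}

# number of distinct strings available within the length bounds (capped)
.corpus_capacity <- function(config) {
  lens <- config$length_min:config$length_max
  cap <- sum(length(config$alphabet)^lens)
  if (!is.finite(cap)) cap <- Inf
  cap
}

#' Generate a synthetic frequency lexicon
#'
#' Frequencies follow an exact power law in rank (so they are strictly
#' decreasing and tie-free).  For each rank a word length is drawn from a
#' clamped, discretised normal distribution whose centre shifts from
#' `length_min` towards `length_max` as rank increases, with strength
#' `length_frequency_link`; characters are then drawn i.i.d. uniformly from
#' the alphabet.  Collisions with already-generated strings are resolved by
#' regeneration (re-drawing length and characters).
#'
#' @param config a [corpus_gen_config()].
#' @return a [frequency_lexicon()] with `n_types` rows ordered by descending
#'   frequency.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_gen_config"))
  n <- config$n_types
  if (.corpus_capacity(config) < n)
    stop("alphabet of ", length(config$alphabet), " characters cannot host ",
         n, " distinct strings with lengths in [", config$length_min, ", ",
         config$length_max, "]")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  rank_frac <- if (n == 1L) 0 else (seq_len(n) - 1) / (n - 1)
  span <- config$length_max - config$length_min
  centre <- config$length_min +
    span * (config$length_frequency_link * rank_frac +
              (1 - config$length_frequency_link) * 0.5)
  len_sd <- max(0.5, span / 4)

  draw_lengths <- function(centres) {
    len <- as.integer(round(stats::rnorm(length(centres), centres, len_sd)))
    pmin(pmax(len, config$length_min), config$length_max)
  }
  draw_words <- function(lens) {
    words <- character(length(lens))
    for (l in unique(lens)) {
      idx <- which(lens == l)
      chars <- sample(config$alphabet, length(idx) * l, replace = TRUE)
      mat <- matrix(chars, nrow = length(idx), ncol = l)
      words[idx] <- do.call(paste0, asplit(mat, 2L))
    }
    words
  }

  lens <- draw_lengths(centre)
  words <- draw_words(lens)
  iter <- 0L
  repeat {
    dup <- which(duplicated(words))
    if (length(dup) == 0L) break
    iter <- iter + 1L
    if (iter > 10000L)
      stop("could not generate ", n, " distinct strings; alphabet and ",
           "length bounds leave too little room")
    lens[dup] <- draw_lengths(centre[dup])
    words[dup] <- draw_words(lens[dup])
  }

  frequency <- 1e6 * seq_len(n)^(-config$zipf_exponent)
  frequency_lexicon(words, frequency)
}
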