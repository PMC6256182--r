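#' Construct a growth schedule
#'
#' A growth schedule fixes the grade checkpoints of the simulation: an
#' ordered set of grade labels with target lexicon sizes in types.  Sizes
#' must be strictly increasing (lexicons only grow) and labels unique.
#'
#' @param grades character (or coercible) vector of grade labels.
#' @param sizes integer vector of target type-lexicon sizes.
#' @return a `growth_schedule`: a `data.frame` with columns `grade`, `size`.
#' @export
growth_schedule <- function(grades, sizes) {
  grades <- as.character(grades)
  sizes <- as.integer(sizes)
  if (length(grades) != length(sizes) || length(grades) == 0L)
    stop("grades and sizes must be non-empty vectors of equal length")
  if (anyDuplicated(grades))
    stop("grade labels must be unique")
  if (any(sizes < 1L))
    stop("target sizes must be positive")
  if (length(sizes) > 1L && any(diff(sizes) <= 0L))
    stop("target sizes must be strictly increasing across grades")
  structure(data.frame(grade = grades, size = sizes,
                       stringsAsFactors = FALSE),
            class = c("growth_schedule", "data.frame"))
}

#' Published average German type-lexicon sizes by grade
#'
#' The estimated average orthographic lexicon sizes (in word types) of German
#' school children in grades 1-6 and 8, as derived from dictionary-method
#' vocabulary estimates: 31,570; 32,606; 46,757; 58,238; 71,344; 93,293;
#' 130,675 types.
#'
#' @return a [growth_schedule()] with seven checkpoints.
#' @export
german_grade_schedule <- function() {
  growth_schedule(grades = c("1", "2", "3", "4", "5", "6", "8"),
                  sizes = c(31570L, 32606L, 46757L, 58238L, 71344L,
                            93293L, 130675L))
}

#' Scale the German grade schedule to a smaller corpus
#'
#' Keeps the proportions of the published grade sizes relative to a
#' 180,000-type corpus but rescales them to a corpus of `corpus_size` types,
#' optionally restricted to a subset of grades.  Useful for desk-scale
#' simulations with synthetic corpora.
#'
#' @param corpus_size number of types in the corpus to be sampled from.
#' @param grades which grade labels of [german_grade_schedule()] to keep.
#' @return a [growth_schedule()].
#' @export
scaled_grade_schedule <- function(corpus_size,
                                  grades = c("1", "3", "5", "8")) {
  full <- german_grade_schedule()
  keep <- full[full$grade %in% as.character(grades), , drop = FALSE]
  if (nrow(keep) == 0L)
    stop("no matching grades in the German schedule")
  sizes <- as.integer(round(keep$size / 180000 * corpus_size))
  growth_schedule(keep$grade, sizes)
}

# platform-stable seed derivation keyed by participant and stage; all
# arithmetic stays exact in doubles and the result fits a 32-bit integer
.derive_seed <- function(base_seed, participant, stage) {
  s <- (abs(as.numeric(base_seed)) %% 2147483647) * 48271 +
    as.numeric(participant) * 30269 + as.numeric(stage) * 3001 + 17
  as.integer(s %% 2147483647)
}

#' Weighted sampling without replacement (successive sampling)
#'
#' Draws `m` items with probability proportional to weight among the items
#' still remaining, removing each drawn item — the probability-
#' proportional-to-size successive-sampling scheme.  The implementation uses
#' per-item exponential keys (`rexp(n) / weights`, take the `m` smallest),
#' which induces exactly the successive-sampling distribution over ordered
#' draws while running in `O(n log n)`.  Ties between keys (a measure-zero
#' event) resolve by input order.  Uses R's global RNG stream: call
#' `set.seed()` first for reproducibility.
#'
#' @param items vector to sample from.
#' @param weights positive numeric weights, one per item.
#' @param m number of items to draw.
#' @return `m` items in draw order.
#' @export
weighted_sample_without_replacement <- function(items, weights, m) {
  n <- length(items)
  if (length(weights) != n)
    stop("`weights` must match `items` in length")
  if (any(!is.finite(weights) | weights <= 0))
    stop("all weights must be positive and finite")
  m <- as.integer(m)
  if (m < 0L) stop("`m` must be non-negative")
  if (m > n)
    stop("cannot draw ", m, " items from ", n, " without replacement")
  if (m == 0L) return(items[0L])
  keys <- stats::rexp(n) / weights
  items[order(keys)[seq_len(m)]]
}

#' Construct a virtual lexicon
#'
#' One virtual participant's set of known word types at one grade, with the
#' grade at which each type entered the lexicon.
#'
#' @param participant_id integer participant index.
#' @param grade_label grade label of this checkpoint.
#' @param types character vector of known types.
#' @param acquisition_stage named character vector mapping each type to the
#'   grade label at which it was acquired.
#' @return a `virtual_lexicon`.
#' @export
virtual_lexicon <- function(participant_id, grade_label, types,
                            acquisition_stage) {
  stopifnot(length(acquisition_stage) == length(types),
            all(names(acquisition_stage) %in% types))
  structure(list(participant_id = as.integer(participant_id),
                 grade_label = as.character(grade_label),
                 types = types,
                 acquisition_stage = acquisition_stage),
            class = "virtual_lexicon")
}

#' @export
print.virtual_lexicon <- function(x, ...) {
  cat("virtual lexicon: participant", x$participant_id, "grade", x$grade_label,
      "-", length(x$types), "types\n")
  invisible(x)
}

#' Sample a participant's initial lexicon
#'
#' Draws `target_size` types from the corpus by frequency-weighted sampling
#' without replacement, emulating a learner whose early vocabulary is biased
#' towards the high-frequency head of the print environment.  Each
#' participant uses an independent RNG stream derived from `base_seed` and
#' the participant index.
#'
#' @param corpus a [frequency_lexicon()].
#' @param target_size lexicon size in types.
#' @param participant_id participant index (keys the derived seed).
#' @param base_seed cohort-level seed.
#' @param grade_label label to tag the initial types with.
#' @return a [virtual_lexicon()].
#' @export
sample_initial_lexicon <- function(corpus, target_size, participant_id = 1L,
                                   base_seed = 1L, grade_label = "1") {
  stopifnot(inherits(corpus, "frequency_lexicon"))
  target_size <- as.integer(target_size)
  if (target_size > nrow(corpus))
    stop("target size ", target_size, " exceeds corpus size ", nrow(corpus))
  set.seed(.derive_seed(base_seed, participant_id, 1L))
  drawn <- weighted_sample_without_replacement(corpus$type, corpus$frequency,
                                               target_size)
  virtual_lexicon(participant_id, grade_label, drawn,
                  stats::setNames(rep(as.character(grade_label),
                                      length(drawn)), drawn))
}

#' Grow a lexicon to the next checkpoint
#'
#' Samples the required number of new types from the participant's learning
#' environment — the corpus minus the types already known — with frequency-
#' weighted sampling without replacement, and returns the enlarged lexicon.
#' Already-known words are never re-drawn.
#'
#' @param lexicon a [virtual_lexicon()].
#' @param corpus the [frequency_lexicon()] the cohort learns from.
#' @param next_grade_label label of the new checkpoint.
#' @param next_target_size lexicon size after growth; must exceed the
#'   current size.
#' @param seed optional integer seed for this growth step; if `NULL` the
#'   current RNG stream is used.
#' @return a new [virtual_lexicon()] at the next checkpoint.
#' @export
grow_lexicon <- function(lexicon, corpus, next_grade_label, next_target_size,
                         seed = NULL) {
  stopifnot(inherits(lexicon, "virtual_lexicon"),
            inherits(corpus, "frequency_lexicon"))
  next_target_size <- as.integer(next_target_size)
  n_new <- next_target_size - length(lexicon$types)
  if (n_new <= 0L)
    stop("next target size must exceed the current lexicon size")
  remaining <- !(corpus$type %in% lexicon$types)
  if (sum(remaining) < n_new)
    stop("learning environment holds ", sum(remaining),
         " types but ", n_new, " new types are required")
  if (!is.null(seed)) set.seed(seed)
  new_types <- weighted_sample_without_replacement(
    corpus$type[remaining], corpus$frequency[remaining], n_new)
  acquisition <- c(lexicon$acquisition_stage,
                   stats::setNames(rep(as.character(next_grade_label), n_new),
                                   new_types))
  virtual_lexicon(lexicon$participant_id, next_grade_label,
                  c(lexicon$types, new_types), acquisition)
}

#' Simulate a cohort of virtual participants
#'
#' Runs the staged sampling procedure for `n_participants` independent
#' virtual learners along a growth schedule: an initial frequency-weighted
#' draw at the first checkpoint, then successive frequency-weighted draws of
#' the size increments from each participant's shrinking learning
#' environment.  Fully reproducible from `base_seed`; per-participant,
#' per-stage streams are derived deterministically from it.
#'
#' @param corpus a [frequency_lexicon()].
#' @param schedule a [growth_schedule()]; the final size must not exceed the
#'   corpus size.
#' @param n_participants number of virtual participants.
#' @param base_seed cohort-level integer seed.
#' @return a `lexicon_cohort`: a list with element `lexicons`, a list indexed
#'   by participant, each a list indexed by grade label holding a
#'   [virtual_lexicon()]; plus the schedule, `n_participants` and
#'   `base_seed`.
#' @export
simulate_cohort <- function(corpus, schedule, n_participants = 50L,
                            base_seed = 1L) {
  stopifnot(inherits(corpus, "frequency_lexicon"),
            inherits(schedule, "growth_schedule"))
  n_participants <- as.integer(n_participants)
  stopifnot(n_participants >= 1L)
  if (schedule$size[nrow(schedule)] > nrow(corpus))
    stop("final schedule size ", schedule$size[nrow(schedule)],
         " exceeds corpus size ", nrow(corpus))
  lexicons <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    per_grade <- vector("list", nrow(schedule))
    names(per_grade) <- schedule$grade
    lex <- sample_initial_lexicon(corpus, schedule$size[1L], p, base_seed,
                                  schedule$grade[1L])
    per_grade[[1L]] <- lex
    for (g in seq_len(nrow(schedule))[-1L]) {
      lex <- grow_lexicon(lex, corpus, schedule$grade[g], schedule$size[g],
                          seed = .derive_seed(base_seed, p, g))
      per_grade[[g]] <- lex
    }
    lexicons[[p]] <- per_grade
  }
  structure(list(lexicons = lexicons, schedule = schedule,
                 n_participants = n_participants,
                 base_seed = as.integer(base_seed)),
            class = "lexicon_cohort")
}

#' @export
print.lexicon_cohort <- function(x, ...) {
  cat("lexicon cohort:", x$n_participants, "participants x",
      nrow(x$schedule), "checkpoints (grades",
      paste(x$schedule$grade, collapse = ", "), ")\n")
  invisible(x)
}

#' Mean corpus frequency of newly acquired words per grade
#'
#' Diagnostic of the sampling procedure: for each checkpoint, the mean
#' corpus frequency of the types acquired at that checkpoint, averaged over
#' participants.  Under frequency-sensitive sampling this trajectory
#' decreases — high-frequency words are acquired first.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param corpus the [frequency_lexicon()] the cohort was sampled from.
#' @return a `data.frame` with columns `grade` and `mean_frequency`, one row
#'   per checkpoint in schedule order.
#' @export
new_word_frequency_trajectory <- function(cohort, corpus) {
  stopifnot(inherits(cohort, "lexicon_cohort"),
            inherits(corpus, "frequency_lexicon"))
  freq <- stats::setNames(corpus$frequency, corpus$type)
  grades <- cohort$schedule$grade
  final <- lapply(cohort$lexicons, function(pl) pl[[length(pl)]])
  means <- vapply(grades, function(g) {
    per_part <- vapply(final, function(lex) {
      acquired <- names(lex$acquisition_stage)[lex$acquisition_stage == g]
      mean(freq[acquired])
    }, numeric(1))
    mean(per_part)
  }, numeric(1))
  data.frame(grade = grades, mean_frequency = unname(means),
             stringsAsFactors = FALSE)
}
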