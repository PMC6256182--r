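#' Pipeline configuration
#'
#' Bundles everything one reproducible run needs: the corpus (a TSV path or
#' a [corpus_gen_config()] for a synthetic one), the growth schedule, cohort
#' size, the base seed, path-length mode, clustering policy and the output
#' directory.
#'
#' @param corpus path to a frequency-lexicon TSV, or a [corpus_gen_config()].
#' @param schedule a [growth_schedule()].
#' @param n_participants number of virtual participants.
#' @param base_seed integer seed driving every random stage.
#' @param path_mode `"auto"`, `"exact"` or `"sampled"` (see
#'   [compute_all_measures()]).
#' @param n_sources BFS sources in sampled path mode.
#' @param clustering_policy `"exclude"` or `"zero"` (see
#'   [average_clustering()]).
#' @param max_trend_order maximum polynomial order for trend fits.
#' @param output_dir directory the run artifacts are written to.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(corpus, schedule, n_participants = 10L,
                            base_seed = 1L,
                            path_mode = c("auto", "exact", "sampled"),
                            n_sources = 1000L,
                            clustering_policy = c("exclude", "zero"),
                            max_trend_order = 4L,
                            output_dir = tempfile("lexnetgrow-run-")) {
  stopifnot(inherits(schedule, "growth_schedule"), n_participants >= 1L)
  if (!inherits(corpus, "corpus_gen_config") &&
      !(is.character(corpus) && length(corpus) == 1L))
    stop("corpus must be a file path or a corpus_gen_config")
  structure(list(corpus = corpus, schedule = schedule,
                 n_participants = as.integer(n_participants),
                 base_seed = as.integer(base_seed),
                 path_mode = match.arg(path_mode),
                 n_sources = as.integer(n_sources),
                 clustering_policy = match.arg(clustering_policy),
                 max_trend_order = as.integer(max_trend_order),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Demonstration configuration
#'
#' A desk-scale run: a synthetic 5,000-type corpus, 10 virtual participants,
#' and a four-stage growth schedule whose sizes keep the proportions of the
#' published German grade sizes (grades 1, 3, 5, 8 scaled from a
#' 180,000-type corpus down to 5,000 types: 877, 1299, 1982, 3630).
#'
#' @param output_dir directory for artifacts.
#' @param base_seed integer seed.
#' @param n_types synthetic corpus size.
#' @param n_participants cohort size.
#' @return a [pipeline_config()].
#' @export
demo_pipeline_config <- function(output_dir = tempfile("lexnetgrow-demo-"),
                                 base_seed = 1L, n_types = 5000L,
                                 n_participants = 10L) {
  pipeline_config(
    corpus = corpus_gen_config(n_types = n_types, seed = base_seed),
    schedule = scaled_grade_schedule(n_types),
    n_participants = n_participants,
    base_seed = base_seed,
    output_dir = output_dir)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file mirrors [pipeline_config()]: either `corpus: <path>` or a
#' `corpus:` mapping with generator fields (`n_types`, `zipf_exponent`,
#' `alphabet`, `length_min`, `length_max`, `length_frequency_link`, `seed`),
#' plus `schedule:` as a list of `{grade, size}` entries and the scalar
#' options.
#'
#' @param path YAML file path.
#' @param output_dir overrides the file's `output_dir` when given.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, output_dir = NULL) {
  y <- yaml::read_yaml(path)
  corpus <- if (is.character(y$corpus)) {
    y$corpus
  } else {
    do.call(corpus_gen_config, y$corpus)
  }
  schedule <- growth_schedule(vapply(y$schedule, `[[`, character(1), "grade"),
                              vapply(y$schedule, function(s)
                                as.numeric(s[["size"]]), numeric(1)))
  args <- list(corpus = corpus, schedule = schedule)
  for (key in c("n_participants", "base_seed", "path_mode", "n_sources",
                "clustering_policy", "max_trend_order", "output_dir"))
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  if (!is.null(output_dir)) args$output_dir <- output_dir
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Corpus (load or generate) -> cohort simulation -> neighbour graphs ->
#' network measures -> per-grade aggregates -> trend statistics -> log-log
#' degree-distribution fits.  Writes `measures.tsv` (per participant and
#' grade), `aggregate.tsv` (means and SDs over participants per grade),
#' `trends.tsv`, `pairwise.tsv`, `degree_fits.tsv`, `trajectory.tsv` (mean
#' corpus frequency of newly acquired words per grade), `corpus.tsv` (when
#' generated) and `manifest.json` into the output directory.  A rerun with
#' the same configuration reproduces every table bit for bit (the manifest's
#' timestamps aside).  On error, files written by the failed run are removed.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage progress messages (written to stderr).
#' @return invisibly, a list with `corpus`, `cohort`, `measures`,
#'   `aggregate`, `trends`, `pairwise`, `degree_fits`, `trajectory`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  say <- function(...) if (!quiet) message("[lexnetgrow] ", ...)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    say(stage, " done in ", timings[[stage]], "s")
    res
  }
  emit <- function(name) {
    written <<- c(written, file.path(config$output_dir, name))
    file.path(config$output_dir, name)
  }
  write_tsv <- function(df, name) {
    con <- file(emit(name), open = "wb")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8", eol = "\n")
  }

  corpus <- clock("corpus", {
    if (inherits(config$corpus, "corpus_gen_config")) {
      cp <- generate_corpus(config$corpus)
      write_frequency_lexicon(cp, emit("corpus.tsv"))
      cp
    } else {
      read_frequency_lexicon(config$corpus)
    }
  })

  cohort <- clock("simulate", simulate_cohort(corpus, config$schedule,
                                              config$n_participants,
                                              config$base_seed))

  grades <- config$schedule$grade
  records <- clock("measures", {
    recs <- list()
    fits <- list()
    for (p in seq_len(config$n_participants)) {
      for (gi in seq_along(grades)) {
        lex <- cohort$lexicons[[p]][[gi]]
        g <- build_neighbor_graph(lex$types)
        m <- compute_all_measures(
          lex, g, path_mode = config$path_mode,
          n_sources = config$n_sources,
          clustering_policy = config$clustering_policy,
          seed = .derive_seed(config$base_seed, p, 1000L + gi))
        recs[[length(recs) + 1L]] <- m
        pf <- loglog_degree_fit(m$degree_distribution)
        fits[[length(fits) + 1L]] <- data.frame(
          participant = p, grade = grades[gi], slope = pf$slope,
          intercept = pf$intercept, r_squared = pf$r_squared,
          n_points = pf$n_points, stringsAsFactors = FALSE)
      }
    }
    list(measures = recs, degree_fits = do.call(rbind, fits))
  })

  measures <- clock("tables", {
    df <- write_measures_table(records$measures,
                               emit("measures.tsv"))
    write_tsv(records$degree_fits, "degree_fits.tsv")
    df
  })

  aggregate_tbl <- clock("aggregate", {
    cols <- c("lexicon_size", "n", "mean_degree", "L", "D", "C", "hermits",
              "hermit_proportion")
    agg <- do.call(rbind, lapply(grades, function(g) {
      sub <- measures[measures$grade == g, , drop = FALSE]
      row <- data.frame(grade = g, stringsAsFactors = FALSE)
      for (cl in cols) {
        row[[paste0(cl, "_mean")]] <- mean(sub[[cl]])
        row[[paste0(cl, "_sd")]] <- stats::sd(sub[[cl]])
      }
      row
    }))
    out <- agg
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], signif, 6L)
    write_tsv(out, "aggregate.tsv")
    agg
  })

  trends <- clock("trends", {
    tr <- trend_statistics(measures,
                           measure_cols = c("n", "mean_degree", "L", "D", "C",
                                            "hermit_proportion"),
                           max_order = config$max_trend_order)
    out <- tr$trends
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], signif, 6L)
    write_tsv(out, "trends.tsv")
    pw <- tr$pairwise
    pw$diff <- signif(pw$diff, 6L)
    pw$adjusted_p <- signif(pw$adjusted_p, 6L)
    write_tsv(pw, "pairwise.tsv")
    tr
  })

  trajectory <- clock("trajectory", {
    tj <- new_word_frequency_trajectory(cohort, corpus)
    out <- tj
    out$mean_frequency <- signif(out$mean_frequency, 6L)
    write_tsv(out, "trajectory.tsv")
    tj
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("lexnetgrow")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    base_seed = config$base_seed,
    n_participants = config$n_participants,
    schedule = as.list(stats::setNames(config$schedule$size,
                                       config$schedule$grade)),
    corpus = if (inherits(config$corpus, "corpus_gen_config"))
      unclass(config$corpus) else list(path = config$corpus),
    path_mode = config$path_mode,
    n_sources = config$n_sources,
    clustering_policy = config$clustering_policy,
    max_trend_order = config$max_trend_order,
    stage_seconds = timings)
  manifest$corpus$alphabet <- paste(manifest$corpus$alphabet, collapse = "")
  jsonlite::write_json(manifest, emit("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  say("artifacts in ", config$output_dir)
  invisible(list(corpus = corpus, cohort = cohort, measures = measures,
                 aggregate = aggregate_tbl, trends = trends$trends,
                 pairwise = trends$pairwise,
                 degree_fits = records$degree_fits,
                 trajectory = trajectory, manifest = manifest))
}
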