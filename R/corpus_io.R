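#' Construct a frequency lexicon
#'
#' A frequency lexicon is the model of the learning environment: an ordered
#' table of distinct word types with positive token frequencies.  Entry order
#' is meaningful (sampling ties are broken by it) and is preserved exactly.
#'
#' Word types are normalised to Unicode NFC so that composed and decomposed
#' spellings of the same grapheme (e.g. German umlauts) compare equal and
#' count as a single symbol in edit distances.  Comparison is case-sensitive:
#' distinct orthographic sequences are distinct types.
#'
#' @param type character vector of word types (non-empty strings).
#' @param frequency numeric vector of positive token frequencies (real-valued
#'   counts are allowed, e.g. for normalised corpora).
#' @param merge_duplicates if `TRUE`, duplicate types after NFC normalisation
#'   are merged by summing their frequencies (first occurrence keeps its
#'   position) with a warning; if `FALSE` duplicates are an error.
#' @return a `frequency_lexicon`: a `data.frame` with columns `type` and
#'   `frequency`, one row per distinct type.
#' @export
frequency_lexicon <- function(type, frequency, merge_duplicates = TRUE) {
  if (length(type) != length(frequency))
    stop("`type` and `frequency` must have the same length")
  if (length(type) == 0L)
    stop("a frequency lexicon must contain at least one entry")
  type <- stringi::stri_trans_nfc(as.character(type))
  frequency <- as.numeric(frequency)
  bad <- which(!is.finite(frequency) | frequency <= 0)
  if (length(bad) > 0L)
    stop("non-positive or non-numeric frequency at entry ", bad[1L],
         " (type \"", type[bad[1L]], "\")")
  if (any(is.na(type) | type == ""))
    stop("word types must be non-empty strings")
  if (anyDuplicated(type)) {
    if (!merge_duplicates)
      stop("duplicate word types after NFC normalization")
    warning("duplicate word types after NFC normalization merged by summing frequencies")
    frequency <- vapply(split(frequency, factor(type, levels = unique(type))),
                        sum, numeric(1))
    type <- unique(type)
  }
  structure(
    data.frame(type = type, frequency = as.numeric(frequency),
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("frequency_lexicon", "data.frame")
  )
}

#' Read a frequency lexicon from a TSV file
#'
#' The file must be UTF-8 tab-separated with the exact header
#' `type<TAB>frequency`.  Types are NFC-normalised on read; duplicates after
#' normalisation are merged by summing frequencies, with a warning.  Row
#' order is preserved.
#'
#' @param path path to a UTF-8 TSV file.
#' @return a [frequency_lexicon()].
#' @export
read_frequency_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L)
    stop("empty file: ", path)
  if (!identical(lines[1L], "type\tfrequency"))
    stop("malformed header in ", path,
         ": expected 'type<TAB>frequency', got '", lines[1L], "'")
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L)
    stop("no entries in ", path)
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L))
    stop("malformed row at line ", which(nf != 2L)[1L] + 1L, " of ", path)
  type <- vapply(parts, `[[`, character(1), 1L)
  freq_chr <- vapply(parts, `[[`, character(1), 2L)
  frequency <- suppressWarnings(as.numeric(freq_chr))
  bad <- which(is.na(frequency) | frequency <= 0)
  if (length(bad) > 0L)
    stop("non-positive or non-numeric frequency at line ", bad[1L] + 1L,
         " of ", path)
  frequency_lexicon(type, frequency)
}

#' Write a frequency lexicon to a TSV file
#'
#' Inverse of [read_frequency_lexicon()]: UTF-8, LF line endings, header
#' `type<TAB>frequency`, entry order preserved.
#'
#' @param lexicon a [frequency_lexicon()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frequency_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "frequency_lexicon"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("type\tfrequency",
               paste(lexicon$type,
                     format(lexicon$frequency, scientific = FALSE, trim = TRUE,
                            digits = 15),
                     sep = "\t")),
             con, sep = "\n", useBytes = FALSE)
  invisible(path)
}

#' Write a lexicon snapshot
#'
#' A snapshot is one virtual participant's known types at one grade: a UTF-8
#' text file with a sidecar header line
#' `# participant=<id> grade=<label> size=<n>` followed by one type per line.
#'
#' @param lexicon a [virtual_lexicon()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lexicon_snapshot <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "virtual_lexicon"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- sprintf("# participant=%d grade=%s size=%d",
                    lexicon$participant_id, lexicon$grade_label,
                    length(lexicon$types))
  writeLines(c(header, lexicon$types), con, sep = "\n")
  invisible(path)
}

#' Read a lexicon snapshot
#'
#' @param path path written by [write_lexicon_snapshot()].
#' @return a [virtual_lexicon()] (acquisition stages are not stored in
#'   snapshots; all types are tagged with the snapshot's grade).
#' @export
read_lexicon_snapshot <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  m <- regmatches(lines[1L],
                  regexec("^# participant=(\\d+) grade=(\\S+) size=(\\d+)$",
                          lines[1L]))[[1L]]
  if (length(m) != 4L)
    stop("malformed snapshot header in ", path)
  types <- lines[-1L]
  types <- types[nzchar(types)]
  if (length(types) != as.integer(m[4L]))
    stop("snapshot size mismatch in ", path, ": header says ", m[4L],
         ", found ", length(types))
  virtual_lexicon(participant_id = as.integer(m[2L]), grade_label = m[3L],
                  types = types,
                  acquisition_stage = stats::setNames(rep(m[3L], length(types)),
                                                      types))
}

#' Write a per-participant network-measures table
#'
#' Long-form TSV with one row per participant and grade, the form from which
#' per-grade summary tables (means and SDs over participants) aggregate.
#' Columns: `participant`, `grade`, `lexicon_size`, `n`, `mean_degree`, `L`,
#' `D`, `C`, `hermits`, `hermit_proportion`.  Floats are written at 6
#' significant digits; rows are sorted by participant, then grade.
#'
#' @param records a list of `network_measures` records, each carrying
#'   `participant` and `grade` fields, or an already-assembled `data.frame`
#'   with the columns above.
#' @param path output path.
#' @return the written `data.frame`, invisibly.
#' @export
write_measures_table <- function(records, path) {
  if (is.data.frame(records)) {
    df <- records
  } else {
    if (length(records) == 0L)
      stop("no records to write")
    df <- do.call(rbind, lapply(records, function(r) {
      stopifnot(inherits(r, "network_measures"))
      data.frame(participant = r$participant, grade = r$grade,
                 lexicon_size = r$lexicon_size, n = r$n,
                 mean_degree = r$mean_degree, L = r$avg_path_length,
                 D = r$diameter, C = r$clustering, hermits = r$hermit_count,
                 hermit_proportion = r$hermit_proportion,
                 stringsAsFactors = FALSE)
    }))
  }
  if (nrow(df) == 0L)
    stop("no records to write")
  df <- df[order(df$participant, df$grade), , drop = FALSE]
  rownames(df) <- NULL
  out <- df
  for (col in c("mean_degree", "L", "D", "C", "hermit_proportion"))
    out[[col]] <- signif(out[[col]], 6L)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(df)
}

#' Read a network-measures table written by [write_measures_table()]
#'
#' @param path path to the TSV file.
#' @return a `data.frame` in the same column order.
#' @export
read_measures_table <- function(path) {
  utils::read.delim(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE,
                    colClasses = c(grade = "character"))
}
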