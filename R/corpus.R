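#' Column mapping for reading heterogeneous corpus files
#'
#' Vocal-sequence corpora arrive in many tabular layouts. A dialect maps the
#' columns of a particular file onto the canonical schema used throughout the
#' package: one row per vocal element with an `individual`, an `element`
#' label, optional `onset`/`offset` times in seconds, and optional unit
#' annotations (`day`, `bout`, `word`, `utterance`) plus an explicit
#' `sequence` id.
#'
#' @param individual,label Names of the required columns in the file.
#' @param onset,offset,day,bout,word,utterance,sequence Names of the optional
#'   columns; set to `NULL` when absent from the file.
#' @return A named list of class `corpus_dialect`.
#' @examples
#' corpus_dialect(individual = "bird", label = "syllable", onset = "start_s")
#' @export
corpus_dialect <- function(individual = "individual", label = "element",
                           onset = "onset", offset = "offset",
                           day = "day", bout = "bout", word = "word",
                           utterance = "utterance", sequence = "sequence") {
  structure(
    list(
      individual = individual, label = label, onset = onset, offset = offset,
      day = day, bout = bout, word = word, utterance = utterance,
      sequence = sequence
    ),
    class = "corpus_dialect"
  )
}

#' Read a symbolic-sequence corpus from a delimited file
#'
#' Reads a long-format TSV/CSV file (one vocal element per row) and returns a
#' corpus tibble. Rows are grouped into sequences by `(individual, day,
#' sequence)` using whichever of those columns the dialect resolves; row
#' order within a sequence is preserved.
#'
#' @param path Path to a TSV or CSV file (decided by extension; `.csv` is
#'   comma-separated, anything else tab-separated).
#' @param dialect A [corpus_dialect()] mapping file columns onto the
#'   canonical schema.
#' @return A corpus tibble with columns `individual`, `sequence`, `element`
#'   and any of `onset`, `offset`, `day`, `bout`, `word`, `utterance` present
#'   in the file.
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(path, dialect = corpus_dialect()) {
  if (!file.exists(path)) {
    abort(paste0("Corpus file not found: ", path))
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  for (col in c("individual", "label")) {
    if (!(dialect[[col]] %in% names(raw))) {
      abort(paste0(
        "Required column `", dialect[[col]], "` (", col,
        ") not found in ", path, "."
      ))
    }
  }
  out <- tibble::tibble(
    individual = as.character(raw[[dialect$individual]]),
    element = as.character(raw[[dialect$label]])
  )
  for (col in c("onset", "offset")) {
    nm <- dialect[[col]]
    if (!is.null(nm) && nm %in% names(raw)) out[[col]] <- as.numeric(raw[[nm]])
  }
  for (col in c("day", "bout", "word", "utterance")) {
    nm <- dialect[[col]]
    if (!is.null(nm) && nm %in% names(raw)) out[[col]] <- as.character(raw[[nm]])
  }
  seq_nm <- dialect$sequence
  if (!is.null(seq_nm) && seq_nm %in% names(raw)) {
    out$sequence <- paste(out$individual, as.character(raw[[seq_nm]]), sep = "/")
  } else if ("day" %in% names(out)) {
    out$sequence <- paste(out$individual, out$day, sep = "/")
  } else {
    out$sequence <- out$individual
  }
  out <- dplyr::relocate(out, "individual", "sequence", "element")
  validate_corpus(out)
}

#' Write a corpus tibble to a delimited file
#'
#' The inverse of [read_corpus()] with the default dialect: columns are
#' written under their canonical names so that reading the file back
#' reproduces labels, times and unit annotations.
#'
#' @param corpus A corpus tibble.
#' @param path Output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  corpus <- validate_corpus(corpus)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(corpus, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Segment sequences into bouts by inter-element gaps
#'
#' A bout is a continuous period of vocalising delimited by long silent
#' gaps. Each sequence is split wherever the silent gap before an element
#' exceeds `gap` seconds, and a fresh `bout` id is assigned to every run.
#' Typical thresholds are 60 s for species with long song sessions
#' (e.g. vireos, thrashers) and 10 s for species with denser song
#' (e.g. starlings).
#'
#' @param corpus A corpus tibble with `onset` (and, for the default rule,
#'   `offset`) times in seconds.
#' @param gap Positive gap threshold in seconds. Default 60.
#' @param rule How to measure the silent gap: `"offset_onset"` (default)
#'   uses `onset[i+1] - offset[i]`; `"onset_onset"` uses successive onset
#'   differences, for corpora that record onsets only.
#' @return The corpus with a (re)computed `bout` column; element order is
#'   unchanged, so re-keying sequences to bouts with
#'   [concatenate_level()] partitions each sequence without reordering.
#' @examples
#' x <- tibble::tibble(
#'   individual = "b1", sequence = "b1", element = letters[1:5],
#'   onset = c(0, 1, 2, 75, 76), offset = c(0, 1, 2, 75, 76) + 0.5
#' )
#' segment_bouts(x, gap = 60)$bout
#' @export
segment_bouts <- function(corpus, gap = 60, rule = c("offset_onset", "onset_onset")) {
  rule <- match.arg(rule)
  corpus <- validate_corpus(corpus, require_times = TRUE)
  if (!is.numeric(gap) || length(gap) != 1 || gap <= 0) {
    abort("`gap` must be a single positive number of seconds.")
  }
  if (rule == "offset_onset" && !"offset" %in% names(corpus)) {
    abort("`rule = \"offset_onset\"` needs an `offset` column; use `rule = \"onset_onset\"` for onset-only corpora.")
  }
  corpus |>
    dplyr::group_by(.data$sequence) |>
    dplyr::mutate(
      .gap = if (rule == "offset_onset") {
        .data$onset - dplyr::lag(.data$offset)
      } else {
        .data$onset - dplyr::lag(.data$onset)
      },
      .bout_idx = cumsum(dplyr::coalesce(.data$.gap > gap, FALSE)),
      bout = sprintf("%s/b%04d", .data$sequence, .data$.bout_idx + 1L)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".gap", -".bout_idx")
}

#' Re-key sequences to the units of an annotation level
#'
#' Pair counting never crosses sequence boundaries, so the choice of what
#' counts as "a sequence" sets the scope of the analysis. This operation
#' re-partitions the corpus so that each unit at `level` becomes one
#' sequence: `level = "day"` concatenates all elements an individual
#' produced in a day into a single sequence (pairs may then cross bout
#' boundaries), while `level = "bout"` restricts pairs to within bouts.
#'
#' @param corpus A corpus tibble carrying the `level` column.
#' @param level One of `"day"`, `"bout"`, `"word"`, `"utterance"`, or
#'   `"individual"`.
#' @return The corpus with `sequence` replaced by the unit ids at `level`,
#'   elements kept in their original temporal order.
#' @export
concatenate_level <- function(corpus, level) {
  corpus <- validate_corpus(corpus)
  levels_ok <- c(.corpus_unit_levels, "individual")
  if (!is.character(level) || length(level) != 1 || !(level %in% levels_ok)) {
    abort(paste0("`level` must be one of: ", paste(levels_ok, collapse = ", "), "."))
  }
  if (!(level %in% names(corpus))) {
    abort(paste0("Corpus has no `", level, "` annotation column."))
  }
  if (anyNA(corpus[[level]])) {
    abort(paste0("`", level, "` annotations contain missing values."))
  }
  dplyr::mutate(
    corpus,
    sequence = paste(.data$individual, as.character(.data[[level]]), sep = "/")
  )
}

#' Collapse runs of repeated labels to a single element
#'
#' Immediate repetitions of the same label (e.g. trilled syllables) can
#' inflate short-range dependency estimates. This collapses every maximal
#' run of identical consecutive labels within a sequence to one element,
#' keeping the onset of the run's first element and the offset of its last.
#' The operation is idempotent.
#'
#' @param corpus A corpus tibble.
#' @return The compressed corpus tibble.
#' @examples
#' x <- tibble::tibble(
#'   individual = "b1", sequence = "b1",
#'   element = c("a", "a", "b", "b", "b", "a")
#' )
#' compress_repeats(x)$element
#' @export
compress_repeats <- function(corpus) {
  corpus <- validate_corpus(corpus)
  grouped <- corpus |>
    dplyr::group_by(.data$sequence) |>
    dplyr::mutate(
      .run = cumsum(.data$element != dplyr::lag(.data$element, default = "\r\r"))
    )
  if ("offset" %in% names(corpus)) {
    grouped <- grouped |>
      dplyr::group_by(.data$.run, .add = TRUE) |>
      dplyr::mutate(offset = .data$offset[dplyr::n()]) |>
      dplyr::group_by(.data$sequence)
  }
  grouped |>
    dplyr::filter(.data$element != dplyr::lag(.data$element, default = "\r\r")) |>
    dplyr::ungroup() |>
    dplyr::select(-".run")
}

#' Alphabet of a corpus
#'
#' @param corpus A corpus tibble.
#' @return Sorted character vector of distinct element labels.
#' @export
corpus_alphabet <- function(corpus) {
  corpus <- validate_corpus(corpus)
  sort(unique(as.character(corpus$element)))
}
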