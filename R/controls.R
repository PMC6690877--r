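#' Shuffle-based controls isolating within-unit and between-unit structure
#'
#' Two complementary permutations dissect where sequential information
#' lives relative to an annotation level (bouts in birdsong, words or
#' utterances in speech):
#'
#' * `"shuffle_units_keep_within"` permutes the order of the units within
#'   each scope group while leaving the internal element order of every
#'   unit intact — between-unit structure is destroyed, within-unit
#'   structure preserved.
#' * `"shuffle_within_keep_units"` permutes the elements within every unit
#'   while leaving the unit order intact — within-unit structure is
#'   destroyed, between-unit structure preserved.
#'
#' Either way the multiset of elements within each scope group is
#' conserved. Element times are meaningless after permutation and are
#' dropped from the output.
#'
#' @param corpus A corpus tibble carrying the `level` column.
#' @param level Annotation level whose units are shuffled (`"bout"`,
#'   `"word"`, `"utterance"`, or `"day"`).
#' @param mode `"shuffle_units_keep_within"` or
#'   `"shuffle_within_keep_units"`.
#' @param scope Column defining the groups within which shuffling happens;
#'   default `"sequence"` (e.g. a day of song or a transcript).
#' @param seed Integer seed; output is reproducible.
#' @return The shuffled corpus tibble.
#' @export
apply_shuffle <- function(corpus, level,
                          mode = c("shuffle_units_keep_within",
                                   "shuffle_within_keep_units"),
                          scope = "sequence", seed = 1) {
  mode <- match.arg(mode)
  corpus <- validate_corpus(corpus)
  if (!(level %in% names(corpus))) {
    abort(paste0("Corpus has no `", level, "` annotation column."))
  }
  if (!(scope %in% names(corpus))) {
    abort(paste0("Corpus has no `", scope, "` column to scope the shuffle."))
  }
  if (anyNA(corpus[[level]])) {
    abort(paste0("`", level, "` annotations contain missing values."))
  }
  corpus$onset <- NULL
  corpus$offset <- NULL
  scope_f <- factor(corpus[[scope]], levels = unique(corpus[[scope]]))
  rows_by_scope <- split(seq_len(nrow(corpus)), scope_f)
  unit_vec <- corpus[[level]]
  new_order <- local_seed_eval(seed, {
    unlist(lapply(rows_by_scope, function(rows) {
      units_here <- factor(unit_vec[rows], levels = unique(unit_vec[rows]))
      blocks <- split(rows, units_here)
      if (mode == "shuffle_units_keep_within") {
        unlist(blocks[sample.int(length(blocks))], use.names = FALSE)
      } else {
        unlist(lapply(blocks, function(b) b[sample.int(length(b))]),
               use.names = FALSE)
      }
    }), use.names = FALSE)
  })
  corpus[new_order, , drop = FALSE]
}

#' MI decay restricted to pairs within the same unit
#'
#' Computes the shuffle-corrected MI decay curve using only element pairs
#' that fall inside the same unit at `level` (e.g. within-bout pairs).
#' Units become the sequences of the analysis, so both the pair counting
#' and the per-sequence shuffle baseline respect unit boundaries;
#' otherwise the computation is identical to [mi_decay_curve()]. Units
#' shorter than `d + 1` elements contribute no pairs at distance `d`.
#'
#' @inheritParams mi_decay_curve
#' @param level Annotation level restricting the pairs.
#' @return An `mi_decay` tibble.
#' @export
mi_decay_within_units <- function(corpus, level, max_distance = 100,
                                  n_reps = 1, seed = 1, min_pairs = 30) {
  mi_decay_curve(
    concatenate_level(corpus, level),
    max_distance = max_distance, n_reps = n_reps, seed = seed,
    min_pairs = min_pairs
  )
}
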