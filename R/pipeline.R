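#' Run a full MI-decay analysis from a configuration
#'
#' Orchestrates the complete pipeline: obtain a corpus (from a file or by
#' sampling a grammar), optionally re-key sequences to an annotation
#' level, compute the shuffle-corrected MI decay curve, fit and compare
#' the decay families, compute the curvature profile when the composite
#' model wins, and run any requested shuffle controls. Identical
#' configuration and inputs yield an identical report.
#'
#' @param config A named list (or path to a YAML/JSON file readable by
#'   [read_analysis_config()]) with fields:
#'   * `corpus`: path to a corpus file, **or** `grammar`: a grammar object
#'     or path to a grammar JSON;
#'   * `level`: optional annotation level passed to [concatenate_level()];
#'   * `max_distance` (default 100), `n_reps` (default 1),
#'     `min_pairs` (default 30), `seed` (default 1);
#'   * `families`: families to fit (default all three);
#'   * `weighting`: residual weighting (default `"log1p"`);
#'   * `shuffles`: optional list of shuffle controls, each a list with
#'     `level`, `mode` and optional `scope`/`seed`, re-analysed with the
#'     same curve and fit settings;
#'   * `output_dir`: optional directory to write TSV/JSON artifacts into.
#' @return An object of class `mi_analysis_report`: a list with `curve`,
#'   `comparison`, `best`, `curvature` (or `NULL`), `shuffles` (named list
#'   of sub-reports), and `provenance` (config, config hash, package
#'   version, R version).
#' @examples
#' g <- random_markov_grammar(5, seed = 4, length = 80, n_sequences = 40)
#' rep <- run_analysis(list(grammar = g, max_distance = 20, seed = 1))
#' rep$best
#' @export
run_analysis <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_analysis_config(config)
  }
  if (!is.list(config)) abort("`config` must be a named list or a config file path.")
  cfg <- config
  cfg$max_distance <- cfg$max_distance %||% 100
  cfg$n_reps <- cfg$n_reps %||% 1
  cfg$min_pairs <- cfg$min_pairs %||% 30
  cfg$seed <- cfg$seed %||% 1
  cfg$families <- cfg$families %||% c("exponential", "power_law", "composite")
  cfg$weighting <- cfg$weighting %||% "log1p"

  corpus <- stage("load_corpus", {
    if (!is.null(cfg$corpus)) {
      read_corpus(cfg$corpus)
    } else if (!is.null(cfg$grammar)) {
      g <- if (is.character(cfg$grammar)) read_grammar(cfg$grammar) else cfg$grammar
      sample_corpus(g)
    } else {
      abort("Config must provide either `corpus` (path) or `grammar`.")
    }
  })
  if (!is.null(cfg$level)) {
    corpus <- stage("concatenate_level", concatenate_level(corpus, cfg$level))
  }

  report <- analyse_corpus(corpus, cfg)
  report$shuffles <- purrr::imap(cfg$shuffles %||% list(), function(sh, nm) {
    stage(paste0("shuffle_", nm), {
      shuffled <- apply_shuffle(
        corpus, level = sh$level, mode = sh$mode,
        scope = sh$scope %||% "sequence", seed = sh$seed %||% cfg$seed
      )
      analyse_corpus(shuffled, cfg)
    })
  })
  report$provenance <- list(
    config = cfg,
    config_hash = rlang::hash(cfg),
    package_version = as.character(utils::packageVersion("midecay")),
    r_version = R.version.string
  )
  class(report) <- "mi_analysis_report"

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_mi_curve(report$curve, file.path(cfg$output_dir, "curve.tsv"))
    write_comparison(report$comparison, file.path(cfg$output_dir, "comparison.json"))
    if (!is.null(report$curvature)) {
      jsonlite::write_json(
        list(min_location = report$curvature$min_location,
             max_location = report$curvature$max_location),
        file.path(cfg$output_dir, "curvature.json"),
        digits = NA, auto_unbox = TRUE
      )
    }
    jsonlite::write_json(report$provenance,
                         file.path(cfg$output_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE,
                         force = TRUE)
  }
  report
}

# One curve + comparison (+ curvature if composite wins) for a corpus.
analyse_corpus <- function(corpus, cfg) {
  curve <- stage("mi_decay_curve", mi_decay_curve(
    corpus, max_distance = cfg$max_distance, n_reps = cfg$n_reps,
    seed = cfg$seed, min_pairs = cfg$min_pairs
  ))
  comparison <- stage("fit_decay_models", fit_decay_models(
    curve, families = cfg$families, weighting = cfg$weighting
  ))
  best <- best_family(comparison)
  curvature <- NULL
  if (best == "composite") {
    curvature <- stage("curvature_profile", curvature_profile(
      attr(comparison, "fits")$composite
    ))
  }
  list(curve = curve, comparison = comparison, best = best,
       curvature = curvature)
}

# Wrap a pipeline stage so failures carry the stage name.
stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    abort(paste0("Stage `", name, "` failed: ", conditionMessage(e)))
  })
}

#' Read an analysis configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A named list suitable for [run_analysis()].
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' @export
print.mi_analysis_report <- function(x, ...) {
  cat("MI decay analysis report\n")
  cat(sprintf("  curve: %d distances, %d..%d\n", nrow(x$curve),
              min(x$curve$distance), max(x$curve$distance)))
  cat(sprintf("  best model: %s (relative probability %.4f)\n",
              x$best, max(x$comparison$rel_prob)))
  if (!is.null(x$curvature) && !is.na(x$curvature$min_location)) {
    cat(sprintf("  curvature knee: %.3g elements\n", x$curvature$min_location))
  }
  if (length(x$shuffles) > 0) {
    for (nm in names(x$shuffles)) {
      cat(sprintf("  shuffle control %s: best model %s\n", nm,
                  x$shuffles[[nm]]$best))
    }
  }
  invisible(x)
}

#' Small deterministic fixture corpora
#'
#' Generates the toy corpora used throughout the test suite: a periodic
#' two-label sequence (MI of 1 bit at every distance), an i.i.d. uniform
#' 10-label corpus (corrected MI of 0 at every distance), a symmetric
#' two-state Markov chain with flip probability 0.1 (exponential decay
#' with a known closed-form MI at lag 1), and a small hierarchical corpus.
#'
#' @param seed Integer seed.
#' @return Named list of corpus tibbles: `periodic`, `iid`, `markov2`,
#'   `hierarchy`.
#' @export
make_fixtures <- function(seed = 1) {
  flip <- 0.1
  m2 <- matrix(c(1 - flip, flip, flip, 1 - flip), nrow = 2)
  list(
    periodic = tibble::tibble(
      individual = "fix", sequence = "fix/periodic",
      element = rep(c("a", "b"), length.out = 10000)
    ),
    iid = local_seed_eval(seed, tibble::tibble(
      individual = "fix", sequence = "fix/iid",
      element = sample(sprintf("s%02d", 1:10), 100000, replace = TRUE)
    )),
    markov2 = sample_corpus(markov_grammar(
      m2, length = 1000, n_sequences = 100, seed = seed + 1,
      states = c("A", "B")
    )),
    hierarchy = sample_corpus(random_hierarchical_grammar(
      4, q = 2, depth = 8, n_sequences = 50, seed = seed + 2
    ))
  )
}
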