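#' Search configuration
#'
#' Bundles the knobs of a spectral search. The defaults (`n = 8`,
#' `m = 15`, `R = 50`, score threshold 0.6) are the recommended operating
#' point for GC-MS library search with prescreening: eight query top peaks
#' against fifteen library top peaks with a 50-candidate threshold.
#'
#' @param prescreen A [prescreen_params()], or `NULL` to disable
#'   prescreening (full search only).
#' @param tolerance A [match_tolerance()] or bare number (Th); `NULL`
#'   selects [default_tolerance()] for the library's resolution at search
#'   time.
#' @param score_threshold Hits must score strictly greater than this
#'   (in `[0, 1)`).
#' @param top_n Maximum hits returned per query (`Inf` = unlimited).
#' @return An object of class `SearchConfig`.
#' @export
search_config <- function(prescreen = prescreen_params(),
                          tolerance = NULL,
                          score_threshold = 0.6,
                          top_n = Inf) {
  if (!is.null(prescreen) && !inherits(prescreen, "PrescreenParams")) {
    stop("'prescreen' must be a PrescreenParams or NULL", call. = FALSE)
  }
  if (!is.null(tolerance)) tolerance <- as_tolerance(tolerance)
  score_threshold <- as.numeric(score_threshold)
  if (length(score_threshold) != 1L || is.na(score_threshold) ||
      score_threshold < 0 || score_threshold >= 1) {
    stop("'score_threshold' must lie in [0, 1)", call. = FALSE)
  }
  if (!(is.numeric(top_n) && length(top_n) == 1L && top_n >= 1)) {
    stop("'top_n' must be a positive count or Inf", call. = FALSE)
  }
  structure(list(prescreen = prescreen, tolerance = tolerance,
                 score_threshold = score_threshold, top_n = top_n),
            class = "SearchConfig")
}

resolve_tolerance <- function(config, library) {
  config$tolerance %||% default_tolerance(library$resolution)
}

# score one query against a subset of a pre-scaled library and apply the
# threshold / ordering / truncation contract shared by both search modes
score_and_rank <- function(query_scaled, scaled, which_ids, config) {
  sel <- match(which_ids, scaled$ids)
  scores <- cpp_score_block(query_scaled$mz, query_scaled$a,
                            query_scaled$total,
                            scaled$mz[sel], scaled$a[sel], scaled$total[sel],
                            config$.tol_value)
  keep <- scores > config$score_threshold
  ids <- which_ids[keep]
  scores <- scores[keep]
  o <- order(-scores, ids)
  if (is.finite(config$top_n)) o <- head(o, config$top_n)
  data.frame(spectrum_id = ids[o], score = scores[o],
             rank = seq_along(o))
}

#' Exhaustive spectral library search
#'
#' Scores the query against every library spectrum with [similarity()]
#' and returns hits whose score strictly exceeds the threshold, sorted by
#' descending score with ties broken by ascending spectrum id, truncated
#' to `top_n`. This is the baseline the prescreened search is measured
#' against.
#'
#' @param query A [spectrum()].
#' @param library A [spectral_library()].
#' @param config A [search_config()].
#' @return A data frame of hits with columns `spectrum_id`, `score`,
#'   `rank`. Attribute `n_evaluations` records how many similarity scores
#'   were computed (always the library size here).
#' @export
full_search <- function(query, library, config = search_config()) {
  stopifnot(inherits(query, "Spectrum"), inherits(library, "SpectralLibrary"),
            inherits(config, "SearchConfig"))
  if (length(library$spectra) == 0L) stop("empty library", call. = FALSE)
  scaled <- scale_library(library)
  config$.tol_value <- resolve_tolerance(config, library)$value
  hits <- score_and_rank(scale_spectrum(query), scaled, scaled$ids, config)
  attr(hits, "n_evaluations") <- length(scaled$ids)
  hits
}

#' Two-stage spectral library search with prescreening
#'
#' First [prescreen()]s the library to a tiered candidate set (see
#' [select_candidates()]), then computes [similarity()] only for the
#' candidates. Thresholding, ordering and truncation are identical to
#' [full_search()], so the prescreening can only remove hits, never alter
#' a score.
#'
#' @inheritParams full_search
#' @return A data frame of hits (`spectrum_id`, `score`, `rank`) with
#'   attributes `n_evaluations` (similarity scores computed, the portable
#'   cost proxy for search speed) and `candidates` (the candidate id set).
#' @export
prescreened_search <- function(query, library, config = search_config()) {
  stopifnot(inherits(query, "Spectrum"), inherits(library, "SpectralLibrary"),
            inherits(config, "SearchConfig"))
  if (length(library$spectra) == 0L) stop("empty library", call. = FALSE)
  if (is.null(config$prescreen)) {
    stop("prescreening is disabled in this config; use full_search()",
         call. = FALSE)
  }
  tol <- resolve_tolerance(config, library)
  index <- build_index(library, config$prescreen$m)
  ranked <- prescreen(query, index, config$prescreen, tol)
  cand <- select_candidates(ranked, config$prescreen$r)
  config$.tol_value <- tol$value
  if (length(cand) == 0L) {
    hits <- data.frame(spectrum_id = character(0), score = numeric(0),
                       rank = integer(0))
  } else {
    scaled <- scale_library(library)
    hits <- score_and_rank(scale_spectrum(query), scaled, cand, config)
  }
  attr(hits, "n_evaluations") <- length(cand)
  attr(hits, "candidates") <- cand
  hits
}
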