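#' Inclusion rate of the prescreened search
#'
#' For each query, the top-N hits of the exhaustive search (score strictly
#' above the threshold) are enumerated; `M_orig(N)` is their total count
#' over all queries and `M_pre(N)` counts those same (query, library id)
#' matches that the prescreened search also returns, anywhere in its hit
#' list. The inclusion rate is the micro-averaged ratio
#' \deqn{InclusionRate(N) = M_{pre}(N) / M_{orig}(N),}
#' i.e. counts are summed over all queries before dividing. Because the
#' prescreening only removes candidates and never alters a score, the
#' prescreened hit list is exactly the full hit list restricted to the
#' candidate set; the implementation exploits this to score each query
#' against the library once.
#'
#' @param queries List of [spectrum()] queries.
#' @param library A [spectral_library()].
#' @param config A [search_config()] whose `prescreen` slot supplies the
#'   (n, m, R) triple under evaluation; `top_n` is ignored (the top-N
#'   cutoffs come from `Ns`).
#' @param Ns Integer vector of top-N cutoffs.
#' @return A data frame of class `InclusionReport` with columns `N`,
#'   `M_orig`, `M_pre`, `inclusion_rate`. When `M_orig(N) = 0` the rate is
#'   undefined and reported as `NA` with a warning. Attribute
#'   `mean_eval_count` gives the mean number of similarity evaluations
#'   per query performed by the prescreened search.
#' @export
inclusion_rate <- function(queries, library, config = search_config(),
                           Ns = c(1L, 3L, 10L, 50L)) {
  stopifnot(inherits(config, "SearchConfig"))
  if (is.null(config$prescreen)) {
    stop("config must carry prescreen parameters", call. = FALSE)
  }
  pp <- config$prescreen
  grid <- evaluate_grid(queries, library,
                        triples = data.frame(n = pp$n, m = pp$m, R = pp$r),
                        Ns = Ns, config = config)
  out <- data.frame(N = grid$N, M_orig = grid$M_orig, M_pre = grid$M_pre,
                    inclusion_rate = grid$inclusion_rate)
  attr(out, "mean_eval_count") <- grid$mean_eval_count[1L]
  class(out) <- c("InclusionReport", "data.frame")
  if (anyNA(out$inclusion_rate)) {
    warning("M_orig(N) = 0 for N in {",
            paste(out$N[is.na(out$inclusion_rate)], collapse = ", "),
            "}: inclusion rate undefined", call. = FALSE)
  }
  out
}

#' Inclusion rate and search cost across a parameter grid
#'
#' Runs the prescreening for every requested (n, m, R) triple and reports,
#' per triple and top-N cutoff, the inclusion rate relative to the
#' exhaustive search plus the mean number of similarity evaluations per
#' query (the portable cost proxy for search speed). Exhaustive-search
#' results are computed once per query and reused across all triples.
#'
#' The default grid crosses five equal-peak pairs (4,4), (6,6), (8,8),
#' (12,12), (16,16) and three graduated pairs (4,7), (6,11), (8,15) with
#' R in \{10, 50, 100, 500\}.
#'
#' @inheritParams inclusion_rate
#' @param triples Data frame with columns `n`, `m`, `R` (one row per
#'   parameter triple), or a list of length-3 vectors.
#' @param config A [search_config()] supplying tolerance and score
#'   threshold; its `prescreen` and `top_n` slots are ignored.
#' @return A `GridResult` data frame with one row per (triple, N):
#'   columns `n`, `m`, `R`, `N`, `M_orig`, `M_pre`, `inclusion_rate`,
#'   `mean_eval_count`.
#' @export
parameter_grid <- function(queries, library,
                           triples = default_parameter_grid(),
                           Ns = c(1L, 3L, 10L, 50L),
                           config = search_config()) {
  if (is.list(triples) && !is.data.frame(triples)) {
    triples <- as.data.frame(do.call(rbind, lapply(triples, function(t) {
      stats::setNames(as.integer(t[1:3]), c("n", "m", "R"))
    })))
  }
  stopifnot(is.data.frame(triples), all(c("n", "m", "R") %in% names(triples)),
            nrow(triples) > 0L)
  bad <- triples$n > triples$m
  if (any(bad)) {
    stop("invalid parameter triple(s): n > m in row(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  out <- evaluate_grid(queries, library, triples, Ns, config)
  class(out) <- c("GridResult", "data.frame")
  out
}

#' Default prescreening parameter grid
#'
#' @return Data frame of (n, m, R) triples: the five equal-peak pairs and
#'   three graduated pairs crossed with R in \{10, 50, 100, 500\}.
#' @export
default_parameter_grid <- function() {
  pairs <- rbind(
    data.frame(n = c(4L, 6L, 8L, 12L, 16L), m = c(4L, 6L, 8L, 12L, 16L)),
    data.frame(n = c(4L, 6L, 8L), m = c(7L, 11L, 15L))
  )
  grid <- merge(pairs, data.frame(R = c(10L, 50L, 100L, 500L)))
  grid <- grid[order(grid$n, grid$m, grid$R), c("n", "m", "R")]
  rownames(grid) <- NULL
  grid
}

# Shared engine: per query, rank the full library once; per (n, m) pair,
# prescreen once; per R, select candidates and tally top-N retention.
evaluate_grid <- function(queries, library, triples, Ns, config) {
  stopifnot(is.list(queries), length(queries) > 0L,
            inherits(library, "SpectralLibrary"))
  Ns <- sort(unique(as.integer(Ns)))
  stopifnot(all(Ns >= 1L))
  tol <- resolve_tolerance(config, library)
  scaled <- scale_library(library)
  cfg <- config
  cfg$top_n <- Inf
  cfg$.tol_value <- tol$value

  full_ids <- lapply(queries, function(q) {
    score_and_rank(scale_spectrum(q), scaled, scaled$ids, cfg)$spectrum_id
  })

  pair_key <- paste(triples$n, triples$m)
  out <- vector("list", nrow(triples))
  for (pk in unique(pair_key)) {
    rows <- which(pair_key == pk)
    n <- triples$n[rows[1L]]
    m <- triples$m[rows[1L]]
    pp_max <- prescreen_params(n, m, 1L)
    index <- build_index(library, m)
    ranked <- lapply(queries, prescreen, index = index, params = pp_max,
                     tol = tol)
    for (row in rows) {
      R <- triples$R[row]
      m_orig <- m_pre <- integer(length(Ns))
      evals <- 0L
      for (qi in seq_along(queries)) {
        cand <- select_candidates(ranked[[qi]], R)
        evals <- evals + length(cand)
        ids <- full_ids[[qi]]
        for (ni in seq_along(Ns)) {
          top <- head(ids, Ns[ni])
          m_orig[ni] <- m_orig[ni] + length(top)
          m_pre[ni] <- m_pre[ni] + sum(top %in% cand)
        }
      }
      out[[row]] <- data.frame(
        n = n, m = m, R = R, N = Ns, M_orig = m_orig, M_pre = m_pre,
        inclusion_rate = ifelse(m_orig > 0, m_pre / m_orig, NA_real_),
        mean_eval_count = evals / length(queries)
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a grid result to CSV
#'
#' @param grid A [parameter_grid()] result.
#' @param file Path to write.
#' @return Invisibly, `file`.
#' @export
write_grid_csv <- function(grid, file) {
  stopifnot(is.data.frame(grid))
  cols <- c("n", "m", "R", "N", "inclusion_rate", "mean_eval_count")
  write.csv(grid[, cols], file, row.names = FALSE)
  invisible(file)
}
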