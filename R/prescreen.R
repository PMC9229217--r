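#' Prescreening parameters
#'
#' The prescreening stage compares the `n` most intense query peaks
#' against a graduated number of library top peaks (up to `m`), ranks
#' library spectra by how many query peaks they match, and returns whole
#' tiers of top-ranked spectra until at least `R` candidates are
#' collected.
#'
#' @param n Number of query top peaks used (`1 <= n <= m`).
#' @param m Number of library top peaks used.
#' @param r Candidate-count threshold `R` (`>= 1`).
#' @return An object of class `PrescreenParams`.
#' @export
prescreen_params <- function(n = 8L, m = 15L, r = 50L) {
  n <- as.integer(n); m <- as.integer(m); r <- as.integer(r)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer", call. = FALSE)
  if (is.na(m) || m < n) stop("'m' must be an integer >= n", call. = FALSE)
  if (is.na(r) || r < 1L) stop("'r' must be a positive integer", call. = FALSE)
  structure(list(n = n, m = m, r = r), class = "PrescreenParams")
}

#' @export
print.PrescreenParams <- function(x, ...) {
  cat(sprintf("<PrescreenParams> n=%d query peaks, m=%d library peaks, R=%d\n",
              x$n, x$m, x$r))
  invisible(x)
}

# m/z values of the top peaks of a spectrum, ordered by descending raw
# intensity with ties broken by descending m/z. The identical rule is used
# for library top lists and query top peaks.
top_peak_mz <- function(spectrum, k) {
  pk <- spectrum$peaks
  o <- order(-pk$intensity, -pk$mz)
  pk$mz[head(o, k)]
}

#' Build the prescreening top-peak index for a library
#'
#' Per library spectrum, the m/z values of its (at most) `m` most intense
#' peaks, ordered by descending intensity with ties broken by descending
#' m/z. The graduated matching of [prescreen()] scans length-\eqn{d_k}
#' prefixes of these lists.
#'
#' @param library A [spectral_library()].
#' @param m Number of top peaks retained per spectrum.
#' @return An object of class `PrescreenIndex` holding one ordered m/z
#'   list per spectrum (and an `NA`-padded matrix view used internally).
#' @export
build_index <- function(library, m) {
  stopifnot(inherits(library, "SpectralLibrary"))
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("'m' must be a positive integer", call. = FALSE)
  tops <- lapply(library$spectra, top_peak_mz, k = m)
  mat <- matrix(NA_real_, nrow = length(tops), ncol = m)
  for (i in seq_along(tops)) {
    mat[i, seq_along(tops[[i]])] <- tops[[i]]
  }
  structure(list(ids = names(library$spectra), top = tops, m = m, mat = mat),
            class = "PrescreenIndex")
}

#' @export
print.PrescreenIndex <- function(x, ...) {
  cat(sprintf("<PrescreenIndex> %d spectra, top-%d peak lists\n",
              length(x$ids), x$m))
  invisible(x)
}

#' Graduated matching depth for the k-th query peak
#'
#' The k-th most intense query peak is compared against the `d_k` most
#' intense library peaks, with depth growing linearly from `n` (for the
#' largest query peak) to `m` (for the n-th): `d_1 = m` when `n = 1`, and
#' otherwise \eqn{d_k = n + \mathrm{round}((k-1)(m-n)/(n-1))}. For the
#' consecutive-increment family `m = 2n - 1` this is exactly
#' \eqn{d_k = n + k - 1}, and for `m = n` the depth is constant.
#'
#' @param k Query-peak rank(s), `1 <= k <= n` (vectorized).
#' @param params A [prescreen_params()].
#' @return Integer vector of depths.
#' @examples
#' match_depth(1:8, prescreen_params(n = 8, m = 15))  # 8, 9, ..., 15
#' @export
match_depth <- function(k, params) {
  stopifnot(inherits(params, "PrescreenParams"))
  k <- as.integer(k)
  if (anyNA(k) || any(k < 1L) || any(k > params$n)) {
    stop("'k' must lie in 1..n", call. = FALSE)
  }
  if (params$n == 1L) {
    return(rep(params$m, length(k)))
  }
  params$n + as.integer(floor((k - 1) * (params$m - params$n) /
                                (params$n - 1) + 0.5))
}

#' Rank library spectra by matched top-peak count
#'
#' For `k = 1 .. min(n, query peak count)`, the k-th most intense query
#' peak (intensity ordering as in [build_index()]) is looked up in the
#' first \eqn{d_k} entries of each library top list, using the absolute
#' m/z tolerance. A library spectrum's `matched_count` is the number of
#' query peaks that found at least one within-tolerance m/z in their
#' prefix. Spectra matching no query peak are excluded.
#'
#' @param query A [spectrum()].
#' @param index A [build_index()] result; its `m` must be at least
#'   `params$m`.
#' @param params A [prescreen_params()].
#' @param tol A [match_tolerance()] or bare number (Th).
#' @return A `RankedCandidates` data frame with columns `spectrum_id` and
#'   `matched_count`, sorted by descending count then ascending id.
#' @export
prescreen <- function(query, index, params, tol) {
  stopifnot(inherits(query, "Spectrum"), inherits(index, "PrescreenIndex"),
            inherits(params, "PrescreenParams"))
  tol <- as_tolerance(tol)
  if (index$m < params$m) {
    stop("index was built with m = ", index$m,
         " but params request m = ", params$m, call. = FALSE)
  }
  k_max <- min(params$n, n_peaks(query))
  q_top <- top_peak_mz(query, k_max)
  depths <- match_depth(seq_len(k_max), params)
  counts <- integer(length(index$ids))
  for (k in seq_len(k_max)) {
    d <- min(depths[k], ncol(index$mat))
    hit <- rowSums(abs(index$mat[, seq_len(d), drop = FALSE] - q_top[k])
                   <= tol$value, na.rm = TRUE) > 0L
    counts <- counts + hit
  }
  keep <- counts >= 1L
  out <- data.frame(spectrum_id = index$ids[keep],
                    matched_count = counts[keep])
  out <- out[order(-out$matched_count, out$spectrum_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("RankedCandidates", "data.frame")
  out
}

#' Select candidate spectra from a prescreening ranking
#'
#' Whole tiers (spectra with equal `matched_count`, taken in descending
#' count order) are appended until the cumulative candidate count reaches
#' the threshold `R`, or all ranked spectra are exhausted. A tier is never
#' split, so the result may exceed `R`. The first (highest-count) tier is
#' always included.
#'
#' @param ranked A [prescreen()] result.
#' @param r Candidate-count threshold `R`.
#' @return Character vector of selected `spectrum_id`s, in ranked order.
#' @export
select_candidates <- function(ranked, r) {
  stopifnot(inherits(ranked, "RankedCandidates") || is.data.frame(ranked))
  r <- as.integer(r)
  if (is.na(r) || r < 1L) stop("'r' must be a positive integer", call. = FALSE)
  if (nrow(ranked) == 0L) return(character(0))
  counts <- ranked$matched_count
  tier_sizes <- as.integer(table(factor(counts, levels = sort(unique(counts),
                                                              decreasing = TRUE))))
  cum <- cumsum(tier_sizes)
  n_tiers <- which(cum >= r)
  take <- if (length(n_tiers) == 0L) length(cum) else n_tiers[1L]
  ranked$spectrum_id[seq_len(cum[take])]
}
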