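#' Peak-matching tolerance
#'
#' An absolute half-width window on m/z: a query peak and a library peak
#' may be paired when their m/z values differ by at most `value` Th.
#'
#' @param value Positive half-width in Th.
#' @return An object of class `MatchTolerance`.
#' @export
match_tolerance <- function(value) {
  value <- as.numeric(value)
  if (length(value) != 1L || !is.finite(value) || value <= 0) {
    stop("tolerance must be a single positive number (Th)", call. = FALSE)
  }
  structure(list(mode = "absolute", value = value), class = "MatchTolerance")
}

#' Conventional matching tolerance for an acquisition regime
#'
#' 0.5 Th for unit-mass (low-resolution) spectra and 0.01 Th for
#' accurate-mass (high-resolution) spectra.
#'
#' @param resolution `"low"` or `"high"`.
#' @return A [match_tolerance()].
#' @export
default_tolerance <- function(resolution = c("low", "high")) {
  resolution <- match.arg(resolution)
  match_tolerance(if (resolution == "low") 0.5 else 0.01)
}

as_tolerance <- function(tol) {
  if (inherits(tol, "MatchTolerance")) tol else match_tolerance(tol)
}

#' Scale peak intensities for sqrt-cosine scoring
#'
#' Intensities are first normalized so the base peak equals 1:
#' \eqn{I_i \leftarrow I_i / \max_j I_j}. With total intensity
#' \eqn{I = \sum_i I_i}, a weighting factor \eqn{\omega = 1 / (I - 0.5)}
#' corrects spectra dominated by a single peak, and each peak is scaled to
#' \deqn{A_i = I_i \, mz_i / (1 + \omega I_i).}
#' Because the base peak contributes 1 to the total, \eqn{I \ge 1} always,
#' so \eqn{\omega \in (0, 2]} and the \eqn{I = 0.5} singularity cannot be
#' reached; this is asserted rather than handled.
#'
#' @param spectrum A [spectrum()] with at least one positive-intensity peak.
#' @return An object of class `ScaledSpectrum` with fields `spectrum_id`,
#'   `mz`, `a` (scaled intensities \eqn{A_i}) and `total`
#'   (\eqn{\sum_i A_i}, the precomputed total scaled intensity used as the
#'   similarity denominator).
#' @examples
#' scale_spectrum(spectrum("x", mz = c(50, 100), intensity = c(1, 0.5)))
#' @export
scale_spectrum <- function(spectrum) {
  stopifnot(inherits(spectrum, "Spectrum"))
  ii <- spectrum$peaks$intensity
  base <- max(ii)
  if (!is.finite(base) || base <= 0) {
    stop("spectrum '", spectrum$id, "': cannot base-peak normalize", call. = FALSE)
  }
  ii <- ii / base
  itot <- sum(ii)
  stopifnot(itot >= 1)          # base peak alone contributes 1
  omega <- 1 / (itot - 0.5)
  a <- ii * spectrum$peaks$mz / (1 + omega * ii)
  structure(
    list(spectrum_id = spectrum$id, mz = spectrum$peaks$mz, a = a,
         total = sum(a), omega = omega),
    class = "ScaledSpectrum"
  )
}

as_scaled <- function(x) {
  if (inherits(x, "ScaledSpectrum")) x else scale_spectrum(x)
}

#' @export
print.ScaledSpectrum <- function(x, ...) {
  cat(sprintf("<ScaledSpectrum> id=%s: %d peaks, total scaled intensity %.6g\n",
              x$spectrum_id, length(x$mz), x$total))
  invisible(x)
}

#' Pair query peaks with library peaks by m/z proximity
#'
#' One-to-one greedy assignment: candidate pairs within the tolerance
#' window are consumed in order of increasing absolute m/z difference
#' (ties broken toward the lower library m/z), and each peak participates
#' in at most one pair. An empty pairing is a valid result.
#'
#' @param query,library `ScaledSpectrum` objects (a plain [spectrum()] is
#'   scaled on the fly).
#' @param tol A [match_tolerance()] or a bare positive number (Th).
#' @return A data frame, sorted by query m/z, with columns `query_idx`,
#'   `library_idx` (peak positions in each spectrum), `query_mz`,
#'   `library_mz` and `mz_diff`.
#' @export
match_peaks <- function(query, library, tol) {
  query <- as_scaled(query)
  library <- as_scaled(library)
  tol <- as_tolerance(tol)
  m <- cpp_match_greedy(query$mz, library$mz, tol$value)
  data.frame(
    query_idx = m[, 1L],
    library_idx = m[, 2L],
    query_mz = query$mz[m[, 1L]],
    library_mz = library$mz[m[, 2L]],
    mz_diff = query$mz[m[, 1L]] - library$mz[m[, 2L]]
  )
}

#' Weighted sqrt-cosine similarity between two spectra
#'
#' With scaled intensities \eqn{A^u} (query) and \eqn{A^l} (library) from
#' [scale_spectrum()], and matched pairs from [match_peaks()],
#' \deqn{S(U, L) = \frac{\left(\sum_{matched} \sqrt{A_i^u A_i^l}\right)^2}
#'                      {\sum_i A_i^u \cdot \sum_i A_i^l}}
#' where each denominator sum runs over all peaks of the respective
#' spectrum. By Cauchy-Schwarz \eqn{0 \le S \le 1}, with \eqn{S = 1} for
#' identical spectra and \eqn{S = 0} when no peaks match.
#'
#' @inheritParams match_peaks
#' @return Similarity score in `[0, 1]`.
#' @examples
#' u <- spectrum("u", mz = c(50, 100), intensity = c(1, 0.5))
#' l <- spectrum("l", mz = 50, intensity = 1)
#' similarity(u, l, tol = 0.01)  # 3/7
#' @export
similarity <- function(query, library, tol) {
  query <- as_scaled(query)
  library <- as_scaled(library)
  tol <- as_tolerance(tol)
  cpp_score_block(query$mz, query$a, query$total,
                  list(library$mz), list(library$a), library$total,
                  tol$value)[[1L]]
}

# Precompute scaled peak lists for a whole library once per search session.
scale_library <- function(library) {
  stopifnot(inherits(library, "SpectralLibrary"))
  scaled <- lapply(library$spectra, scale_spectrum)
  list(
    ids = names(library$spectra),
    mz = lapply(scaled, `[[`, "mz"),
    a = lapply(scaled, `[[`, "a"),
    total = vapply(scaled, `[[`, numeric(1), "total")
  )
}
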