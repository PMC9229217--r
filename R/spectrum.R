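#' Construct a mass spectrum
#'
#' A `Spectrum` is the unit of search: an identified peak list (m/z,
#' intensity) plus minimal metadata. Construction enforces the invariants
#' every downstream operation relies on: peaks are sorted by ascending m/z,
#' duplicate m/z channels are merged by summing their intensities,
#' zero-intensity peaks are dropped, and at least one positive-intensity
#' peak must remain.
#'
#' @param id Unique identifier (single non-empty string).
#' @param mz Numeric vector of mass-to-charge ratios (Th), all positive.
#' @param intensity Numeric vector of abundances (arbitrary units),
#'   non-negative; zero-intensity peaks are silently dropped.
#' @param name Compound name or unknown label; defaults to `id`.
#' @param metadata Named list of opaque metadata fields (e.g. extra MSP
#'   header lines), preserved on write.
#' @param resolution Acquisition regime: `"low"` (unit-mass, integer-like
#'   m/z) or `"high"` (accurate-mass, fractional m/z).
#' @return An object of class `Spectrum`.
#' @examples
#' sp <- spectrum("demo", mz = c(100, 50), intensity = c(0.5, 1))
#' sp$peaks  # sorted by m/z
#' @export
spectrum <- function(id, mz, intensity, name = id, metadata = list(),
                     resolution = c("low", "high")) {
  resolution <- match.arg(resolution)
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("'id' must be a single non-empty string", call. = FALSE)
  }
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("spectrum '", id, "': mz and intensity lengths differ", call. = FALSE)
  }
  if (anyNA(mz) || anyNA(intensity) || any(!is.finite(mz)) ||
      any(!is.finite(intensity))) {
    stop("spectrum '", id, "': non-finite peak values", call. = FALSE)
  }
  if (any(mz <= 0)) {
    stop("spectrum '", id, "': m/z values must be positive", call. = FALSE)
  }
  if (any(intensity < 0)) {
    stop("spectrum '", id, "': negative intensities", call. = FALSE)
  }
  keep <- intensity > 0
  mz <- mz[keep]
  intensity <- intensity[keep]
  if (length(mz) == 0L) {
    stop("spectrum '", id, "': no peaks with positive intensity", call. = FALSE)
  }
  o <- order(mz)
  mz <- mz[o]
  intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    grp <- match(mz, unique(mz))
    intensity <- as.numeric(rowsum(intensity, grp))
    mz <- unique(mz)
  }
  structure(
    list(id = id, name = name,
         peaks = data.frame(mz = mz, intensity = intensity),
         metadata = metadata, resolution = resolution),
    class = "Spectrum"
  )
}

#' Number of peaks in a spectrum
#' @param x A `Spectrum`.
#' @return Integer peak count.
#' @export
n_peaks <- function(x) {
  stopifnot(inherits(x, "Spectrum"))
  nrow(x$peaks)
}

#' @export
print.Spectrum <- function(x, ...) {
  cat(sprintf("<Spectrum> id=%s (%s-res): %d peaks, m/z %.4g-%.4g\n",
              x$id, x$resolution, nrow(x$peaks),
              min(x$peaks$mz), max(x$peaks$mz)))
  invisible(x)
}

#' Construct a spectral library
#'
#' A keyed collection of [spectrum()] objects sharing one acquisition
#' regime. Spectrum ids must be unique; they key every search result.
#'
#' @param spectra List of `Spectrum` objects.
#' @param resolution Acquisition regime of the library; defaults to the
#'   regime of the first spectrum. All members must agree.
#' @return An object of class `SpectralLibrary`. Member spectra are
#'   accessible as `lib$spectra[[id]]`.
#' @export
spectral_library <- function(spectra, resolution = NULL) {
  if (!is.list(spectra) || length(spectra) == 0L) {
    stop("'spectra' must be a non-empty list of Spectrum objects", call. = FALSE)
  }
  ok <- vapply(spectra, inherits, logical(1), what = "Spectrum")
  if (!all(ok)) stop("all library members must be Spectrum objects", call. = FALSE)
  ids <- vapply(spectra, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate spectrum ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  res <- vapply(spectra, `[[`, character(1), "resolution")
  resolution <- resolution %||% res[[1L]]
  if (!all(res == resolution)) {
    stop("all member spectra must share the library resolution class '",
         resolution, "'", call. = FALSE)
  }
  names(spectra) <- ids
  structure(list(spectra = spectra, resolution = resolution),
            class = "SpectralLibrary")
}

#' @export
length.SpectralLibrary <- function(x) length(x$spectra)

#' @export
print.SpectralLibrary <- function(x, ...) {
  np <- vapply(x$spectra, n_peaks, integer(1))
  cat(sprintf("<SpectralLibrary> %d %s-resolution spectra, %d-%d peaks each\n",
              length(x$spectra), x$resolution, min(np), max(np)))
  invisible(x)
}

#' Ids of the spectra in a library
#' @param library A `SpectralLibrary`.
#' @return Character vector of spectrum ids, in library order.
#' @export
library_ids <- function(library) {
  stopifnot(inherits(library, "SpectralLibrary"))
  names(library$spectra)
}
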