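#' Read a spectral library from NIST MSP text
#'
#' Parses the MSP dialect used by NIST, MoNA and most GC-MS exporters:
#' records separated by blank lines, each with a `Name:` line, optional
#' further `Key: value` metadata lines, a `Num Peaks:` line, and then peak
#' lines holding whitespace- or semicolon-delimited m/z-intensity pairs
#' (several pairs per line are allowed). Metadata lines other than `Name`
#' and `Num Peaks` are preserved verbatim as opaque key-value pairs so a
#' read-write cycle is lossless.
#'
#' Zero-intensity peaks are dropped (the discrepancy is reported via
#' `message()`), and duplicate m/z values within a record are merged by
#' summing intensities. The number of listed pairs must equal the declared
#' `Num Peaks` value.
#'
#' @param file Path to an MSP file, or a connection.
#' @param resolution Acquisition regime of the library (`"low"` or
#'   `"high"`); MSP files do not record it.
#' @return A [spectral_library()]. Spectrum ids are taken from an `ID:`
#'   metadata line when present, otherwise from `Name:`; duplicate ids are
#'   made unique with numeric suffixes.
#' @seealso [write_msp()]
#' @export
read_msp <- function(file, resolution = c("low", "high")) {
  resolution <- match.arg(resolution)
  lines <- if (inherits(file, "connection")) readLines(file) else readLines(file)
  lines <- sub("\r$", "", lines)
  blank <- grepl("^\\s*$", lines)
  if (all(blank)) stop("MSP source contains no spectral records", call. = FALSE)
  rec_id <- cumsum(c(TRUE, blank[-length(blank)] & !blank[-1L]))
  rec_id[blank] <- NA
  recs <- split(seq_along(lines)[!blank], rec_id[!blank])
  spectra <- vector("list", length(recs))
  for (r in seq_along(recs)) {
    idx <- recs[[r]]
    spectra[[r]] <- parse_msp_record(lines[idx], r, idx[1L], resolution)
  }
  ids <- vapply(spectra, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    new_ids <- make.unique(ids, sep = "_")
    message("read_msp: ", sum(new_ids != ids),
            " duplicate id(s) made unique with numeric suffixes")
    for (r in which(new_ids != ids)) spectra[[r]]$id <- new_ids[r]
  }
  spectral_library(spectra, resolution = resolution)
}

parse_msp_record <- function(rec_lines, rec_index, first_line, resolution) {
  is_meta <- grepl("^[A-Za-z][^:]*:", rec_lines)
  np_line <- which(is_meta & grepl("^num\\s*peaks\\s*:", rec_lines,
                                   ignore.case = TRUE))
  if (length(np_line) == 0L) {
    stop(sprintf("record %d (line %d): missing 'Num Peaks:' line",
                 rec_index, first_line), call. = FALSE)
  }
  np_line <- np_line[1L]
  declared <- suppressWarnings(
    as.integer(sub("^[^:]*:\\s*", "", rec_lines[np_line]))
  )
  if (is.na(declared) || declared < 1L) {
    stop(sprintf("record %d (line %d): unparsable 'Num Peaks' value",
                 rec_index, first_line + np_line - 1L), call. = FALSE)
  }

  meta_idx <- which(is_meta[seq_len(np_line - 1L)])
  keys <- sub(":.*$", "", rec_lines[meta_idx])
  vals <- trimws(sub("^[^:]*:", "", rec_lines[meta_idx]))
  name_i <- which(tolower(keys) == "name")
  if (length(name_i) == 0L) {
    stop(sprintf("record %d (line %d): missing 'Name:' line",
                 rec_index, first_line), call. = FALSE)
  }
  nm <- vals[name_i[1L]]
  metadata <- as.list(vals[-name_i])
  names(metadata) <- keys[-name_i]
  id_i <- which(tolower(names(metadata)) == "id")
  id <- if (length(id_i) > 0L) metadata[[id_i[1L]]] else nm

  peak_lines <- rec_lines[seq.int(np_line + 1L, length.out = length(rec_lines) - np_line)]
  tokens <- unlist(strsplit(gsub("[;,]", " ", peak_lines), "\\s+"))
  tokens <- tokens[nzchar(tokens)]
  values <- suppressWarnings(as.numeric(tokens))
  if (anyNA(values)) {
    stop(sprintf("record %d ('%s'): unparsable peak token '%s'",
                 rec_index, nm, tokens[which(is.na(values))[1L]]),
         call. = FALSE)
  }
  if (length(values) %% 2L != 0L) {
    stop(sprintf("record %d ('%s'): odd number of peak values", rec_index, nm),
         call. = FALSE)
  }
  mz <- values[c(TRUE, FALSE)]
  intensity <- values[c(FALSE, TRUE)]
  if (length(mz) != declared) {
    stop(sprintf(
      "record %d ('%s'): declared Num Peaks %d but %d pair(s) listed",
      rec_index, nm, declared, length(mz)), call. = FALSE)
  }
  n_zero <- sum(intensity == 0)
  if (n_zero > 0L) {
    message(sprintf("record %d ('%s'): dropped %d zero-intensity peak(s)",
                    rec_index, nm, n_zero))
  }
  spectrum(id = id, mz = mz, intensity = intensity, name = nm,
           metadata = metadata, resolution = resolution)
}

#' Write a spectral library to NIST MSP text
#'
#' Emits one record per spectrum: `Name:`, any preserved metadata lines,
#' `Num Peaks:`, and peak pairs (five `mz intensity;` pairs per line).
#' m/z values are printed with 1 decimal for low-resolution libraries and
#' 4 decimals for high-resolution ones; intensities use 6 significant
#' digits. The output re-parses with [read_msp()] to the same peak content
#' at the printed precision.
#'
#' @param library A non-empty [spectral_library()].
#' @param file Path or connection to write to.
#' @return Invisibly, the character vector of lines written.
#' @export
write_msp <- function(library, file) {
  stopifnot(inherits(library, "SpectralLibrary"))
  if (length(library$spectra) == 0L) stop("empty library", call. = FALSE)
  out <- lapply(library$spectra, format_msp_record,
                mz_digits = if (library$resolution == "low") 1L else 4L)
  txt <- unlist(out, use.names = FALSE)
  writeLines(txt, file)
  invisible(txt)
}

format_msp_record <- function(sp, mz_digits) {
  if (nrow(sp$peaks) == 0L) {
    stop("spectrum '", sp$id, "' has no peaks", call. = FALSE)
  }
  hdr <- c(paste0("Name: ", sp$name))
  if (length(sp$metadata) > 0L) {
    hdr <- c(hdr, paste0(names(sp$metadata), ": ",
                         vapply(sp$metadata, as.character, character(1))))
  }
  if (!any(tolower(names(sp$metadata)) == "id") && !identical(sp$name, sp$id)) {
    hdr <- c(hdr, paste0("ID: ", sp$id))
  }
  pairs <- paste0(sprintf(paste0("%.", mz_digits, "f"), sp$peaks$mz), " ",
                  formatC(sp$peaks$intensity, digits = 6, format = "g"), ";")
  grp <- ceiling(seq_along(pairs) / 5)
  peak_lines <- vapply(split(pairs, grp), paste, character(1), collapse = " ")
  c(hdr, paste0("Num Peaks: ", nrow(sp$peaks)), unname(peak_lines), "")
}
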