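`%||%` <- function(x, y) if (is.null(x)) y else x

# Independent reference implementations used as oracles. These are kept
# deliberately naive (plain loops, exact binning) and share no code with
# the package internals they check.

# intensity scaling, re-derived from the formula
oracle_scale <- function(mz, intensity) {
  ii <- intensity / max(intensity)
  itot <- sum(ii)
  omega <- 1 / (itot - 0.5)
  ii * mz / (1 + omega * ii)
}

# sqrt-cosine similarity with exact m/z binning; valid whenever every
# within-tolerance match is an exact m/z coincidence (e.g. integer m/z at
# tolerance 0.5)
oracle_similarity_binned <- function(sp_u, sp_l) {
  au <- oracle_scale(sp_u$peaks$mz, sp_u$peaks$intensity)
  al <- oracle_scale(sp_l$peaks$mz, sp_l$peaks$intensity)
  common <- intersect(sp_u$peaks$mz, sp_l$peaks$mz)
  num <- 0
  for (mz in common) {
    num <- num + sqrt(au[sp_u$peaks$mz == mz] * al[sp_l$peaks$mz == mz])
  }
  num^2 / (sum(au) * sum(al))
}

# greedy minimum-distance one-to-one assignment, written as an explicit
# candidate enumeration
oracle_match_greedy <- function(qmz, lmz, tol) {
  cand <- expand.grid(i = seq_along(qmz), j = seq_along(lmz))
  cand$d <- abs(qmz[cand$i] - lmz[cand$j])
  cand <- cand[cand$d <= tol, , drop = FALSE]
  cand <- cand[order(cand$d, lmz[cand$j], qmz[cand$i]), , drop = FALSE]
  qused <- logical(length(qmz)); lused <- logical(length(lmz))
  pairs <- NULL
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (qused[i] || lused[j]) next
    qused[i] <- TRUE; lused[j] <- TRUE
    pairs <- rbind(pairs, c(i, j))
  }
  if (is.null(pairs)) return(matrix(integer(0), ncol = 2))
  pairs[order(qmz[pairs[, 1]]), , drop = FALSE]
}

# brute-force prescreening matched count for one library spectrum:
# literal prefix scan of the top-peak lists
oracle_matched_count <- function(query, lib_sp, n, m, tol) {
  top_of <- function(sp, k) {
    o <- order(-sp$peaks$intensity, -sp$peaks$mz)
    sp$peaks$mz[head(o, k)]
  }
  q_top <- top_of(query, min(n, nrow(query$peaks)))
  l_top <- top_of(lib_sp, min(m, nrow(lib_sp$peaks)))
  count <- 0L
  for (k in seq_along(q_top)) {
    d <- if (n == 1L) m else n + floor((k - 1) * (m - n) / (n - 1) + 0.5)
    prefix <- head(l_top, d)
    if (any(abs(prefix - q_top[k]) <= tol)) count <- count + 1L
  }
  count
}

# independently coded double-loop full search (scores every library
# spectrum with the binned-similarity oracle)
oracle_full_search <- function(query, library, threshold) {
  ids <- names(library$spectra)
  scores <- vapply(library$spectra, function(l) {
    oracle_similarity_binned(query, l)
  }, numeric(1))
  keep <- scores > threshold
  ids <- ids[keep]; scores <- unname(scores[keep])
  o <- order(-scores, ids)
  data.frame(spectrum_id = ids[o], score = scores[o], rank = seq_along(o))
}

# quick ad-hoc random spectra for property tests (independent of the
# package's fixture generator)
rand_spectrum_int <- function(id, n_peaks = 20L, mz_range = c(50L, 300L)) {
  mz <- sample(seq(mz_range[1], mz_range[2]), n_peaks)
  spectrum(id, mz = mz, intensity = runif(n_peaks, 0.01, 1))
}

rand_spectrum_real <- function(id, n_peaks = 15L, mz_range = c(50, 300)) {
  mz <- round(runif(n_peaks, mz_range[1], mz_range[2]), 4)
  mz <- unique(mz)
  spectrum(id, mz = mz, intensity = runif(length(mz), 0.01, 1),
           resolution = "high")
}

rand_library_int <- function(size, n_peaks_range = c(10L, 40L),
                             mz_range = c(50L, 300L)) {
  spectral_library(lapply(seq_len(size), function(s) {
    rand_spectrum_int(sprintf("S%03d", s),
                      sample(seq(n_peaks_range[1], n_peaks_range[2]), 1L),
                      mz_range)
  }))
}
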