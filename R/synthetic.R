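#' Configuration for synthetic spectra generation
#'
#' Describes a seeded generator that emulates the two GC-MS acquisition
#' regimes: unit-mass ("low") spectra with integer m/z values and many
#' peaks, and accurate-mass ("high") spectra with fractional m/z values
#' and fewer peaks. Peak intensities follow an exponential law (EI
#' fragment abundances are heavy-tailed) and are base-peak normalized.
#' Queries are perturbed copies of library spectra: peaks drop out
#' independently (the base peak is always kept), surviving intensities are
#' multiplied by log-normal noise, m/z values are jittered by centered
#' noise clamped to half the matching tolerance (so ground-truth matches
#' stay findable), and a few spurious low-intensity peaks are added.
#'
#' @param resolution `"low"` or `"high"`.
#' @param library_size Number of library spectra.
#' @param peak_count_range Length-2 integer range of peaks per spectrum;
#'   defaults to `c(30, 150)` for low resolution and `c(5, 30)` for high.
#' @param mz_range Length-2 m/z range (Th).
#' @param intensity_rate Rate of the exponential intensity law.
#' @param queries_per_spectrum Queries generated per library spectrum when
#'   [generate_queries()] is called without `n_queries`.
#' @param dropout Per-peak dropout probability for query perturbation.
#' @param intensity_sd SD of log-scale multiplicative intensity noise.
#' @param mz_jitter_sd SD (Th) of m/z jitter, clamped to half the default
#'   matching tolerance of the regime; defaults to a quarter of that
#'   tolerance.
#' @param spurious_range Length-2 range of spurious peaks added per query.
#' @param seed Integer seed; generation is fully reproducible from the
#'   config.
#' @return An object of class `FixtureConfig`.
#' @export
fixture_config <- function(resolution = c("low", "high"),
                           library_size = 100L,
                           peak_count_range = NULL,
                           mz_range = c(50, 500),
                           intensity_rate = 3,
                           queries_per_spectrum = 1L,
                           dropout = 0.2,
                           intensity_sd = 0.3,
                           mz_jitter_sd = NULL,
                           spurious_range = c(0L, 5L),
                           seed = 1L) {
  resolution <- match.arg(resolution)
  peak_count_range <- peak_count_range %||%
    (if (resolution == "low") c(30L, 150L) else c(5L, 30L))
  tol <- default_tolerance(resolution)$value
  mz_jitter_sd <- mz_jitter_sd %||% (tol / 4)
  stopifnot(library_size >= 1L, length(peak_count_range) == 2L,
            peak_count_range[1L] >= 1L,
            peak_count_range[1L] <= peak_count_range[2L],
            length(mz_range) == 2L, mz_range[1L] > 0,
            mz_range[1L] < mz_range[2L],
            intensity_rate > 0, queries_per_spectrum >= 1L,
            dropout >= 0, dropout < 1, intensity_sd >= 0,
            mz_jitter_sd >= 0, mz_jitter_sd <= tol / 2,
            length(spurious_range) == 2L, spurious_range[1L] >= 0L,
            spurious_range[1L] <= spurious_range[2L],
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (resolution == "low") {
    n_channels <- length(seq(ceiling(mz_range[1L]), floor(mz_range[2L])))
    if (peak_count_range[2L] > n_channels) {
      stop("peak_count_range exceeds the ", n_channels,
           " distinct integer m/z channels in mz_range", call. = FALSE)
    }
  }
  structure(list(resolution = resolution,
                 library_size = as.integer(library_size),
                 peak_count_range = as.integer(peak_count_range),
                 mz_range = as.numeric(mz_range),
                 intensity_rate = intensity_rate,
                 queries_per_spectrum = as.integer(queries_per_spectrum),
                 dropout = dropout, intensity_sd = intensity_sd,
                 mz_jitter_sd = mz_jitter_sd,
                 spurious_range = as.integer(spurious_range),
                 seed = as.integer(seed)),
            class = "FixtureConfig")
}

# sample k elements of x without the scalar-x surprise of sample()
sample_vec <- function(x, k, replace = FALSE) {
  x[sample.int(length(x), k, replace = replace)]
}

# one uniform integer draw from [a, b]
sample_int_range <- function(a, b) {
  if (a == b) return(a)
  sample_vec(seq.int(a, b), 1L)
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# distinct m/z positions for one spectrum; high-res positions are kept at
# least two tolerance windows apart so channels never overlap
draw_mz <- function(np, config) {
  if (config$resolution == "low") {
    channels <- seq(ceiling(config$mz_range[1L]), floor(config$mz_range[2L]))
    sort(sample_vec(channels, np))
  } else {
    min_gap <- 2 * default_tolerance("high")$value
    mz <- numeric(0)
    while (length(mz) < np) {
      cand <- round(runif(4L * np, config$mz_range[1L], config$mz_range[2L]), 4)
      mz <- sort(unique(c(mz, cand)))
      keep <- c(TRUE, diff(mz) > min_gap)
      mz <- mz[keep]
    }
    sort(sample_vec(mz, np))
  }
}

#' Generate a seeded synthetic spectral library
#'
#' Per spectrum, the peak count is drawn uniformly from the configured
#' range, m/z positions are drawn without collision from the m/z range
#' (integer channels for the low regime, 4-decimal reals kept at least two
#' tolerance windows apart for the high regime), and intensities are drawn
#' from the exponential law and base-peak normalized. Deterministic given
#' the config seed.
#'
#' @param config A [fixture_config()].
#' @return A [spectral_library()] with ids `LIB_0001`, `LIB_0002`, ...
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "FixtureConfig"))
  with_seed(config$seed, {
    spectra <- lapply(seq_len(config$library_size), function(s) {
      np <- sample_int_range(config$peak_count_range[1L],
                             config$peak_count_range[2L])
      mz <- draw_mz(np, config)
      ii <- rexp(np, rate = config$intensity_rate)
      ii <- ii / max(ii)
      spectrum(id = sprintf("LIB_%04d", s), mz = mz, intensity = ii,
               resolution = config$resolution)
    })
    spectral_library(spectra, resolution = config$resolution)
  })
}

#' Generate perturbed query spectra with ground truth
#'
#' Each query is a perturbed copy of a library spectrum (see
#' [fixture_config()] for the perturbation model). Every query is
#' guaranteed to share at least one within-tolerance peak with its source:
#' the base peak is never dropped and m/z jitter is clamped to half the
#' matching tolerance.
#'
#' @param library A [spectral_library()] from [generate_library()].
#' @param config The [fixture_config()] used to build the library.
#' @param n_queries If given, this many source spectra are sampled
#'   (without replacement when possible) and one query derived from each;
#'   otherwise every library spectrum yields `queries_per_spectrum`
#'   queries.
#' @return List with elements `queries` (list of [spectrum()], ids
#'   `Q_0001`, ...) and `truth` (data frame `query_id`, `source_id`).
#' @export
generate_queries <- function(library, config, n_queries = NULL) {
  stopifnot(inherits(library, "SpectralLibrary"),
            inherits(config, "FixtureConfig"))
  ids <- library_ids(library)
  with_seed(config$seed + 1L, {
    sources <- if (is.null(n_queries)) {
      rep(ids, each = config$queries_per_spectrum)
    } else {
      sample_vec(ids, n_queries, replace = n_queries > length(ids))
    }
    tol <- default_tolerance(config$resolution)$value
    queries <- vector("list", length(sources))
    for (i in seq_along(sources)) {
      queries[[i]] <- perturb_spectrum(library$spectra[[sources[i]]],
                                       sprintf("Q_%04d", i), config, tol)
      stopifnot(shares_peak(queries[[i]], library$spectra[[sources[i]]], tol))
    }
    list(queries = queries,
         truth = data.frame(query_id = vapply(queries, `[[`, character(1), "id"),
                            source_id = sources))
  })
}

perturb_spectrum <- function(src, id, config, tol) {
  mz <- src$peaks$mz
  ii <- src$peaks$intensity
  np <- length(mz)
  base_idx <- which.max(ii)
  keep <- runif(np) >= config$dropout
  keep[base_idx] <- TRUE
  mz <- mz[keep]
  ii <- ii[keep]
  if (config$intensity_sd > 0) {
    ii <- ii * exp(rnorm(length(ii), sd = config$intensity_sd))
  }
  if (config$mz_jitter_sd > 0) {
    jit <- rnorm(length(mz), sd = config$mz_jitter_sd)
    jit <- pmin(pmax(jit, -tol / 2), tol / 2)
    mz <- mz + jit
  }
  n_spur <- sample_int_range(config$spurious_range[1L], config$spurious_range[2L])
  if (n_spur > 0L) {
    spur_mz <- draw_spurious_mz(n_spur, src$peaks$mz, config, tol)
    n_spur <- length(spur_mz)
    if (n_spur > 0L) {
      mz <- c(mz, spur_mz)
      ii <- c(ii, runif(n_spur, 0.002, 0.05) * max(ii))
    }
  }
  spectrum(id = id, mz = mz, intensity = ii, resolution = config$resolution)
}

# spurious peaks are placed on channels well away from the source peaks so
# they perturb the ranking without ever aliasing a true peak
draw_spurious_mz <- function(n_spur, src_mz, config, tol) {
  if (config$resolution == "low") {
    channels <- seq(ceiling(config$mz_range[1L]), floor(config$mz_range[2L]))
    free <- setdiff(channels, round(src_mz))
    sample_vec(free, min(n_spur, length(free)))
  } else {
    out <- numeric(0)
    for (attempt in seq_len(20L)) {
      cand <- round(runif(n_spur, config$mz_range[1L], config$mz_range[2L]), 4)
      ok <- vapply(cand, function(x) all(abs(x - c(src_mz, out)) > 2 * tol),
                   logical(1))
      out <- c(out, cand[ok])
      if (length(out) >= n_spur) break
    }
    head(out, n_spur)
  }
}

shares_peak <- function(query, source, tol) {
  any(vapply(query$peaks$mz,
             function(x) any(abs(x - source$peaks$mz) <= tol), logical(1)))
}

#' Write a fixture set to disk
#'
#' Writes `library.msp`, `queries.msp` and `truth.csv` (columns
#' `query_id`, `source_id`) into a directory, keeping the MSP files
#' standard and the ground truth alongside.
#'
#' @param library A [spectral_library()].
#' @param queries,truth Output of [generate_queries()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named character vector of file paths.
#' @export
write_fixture_set <- function(library, queries, truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(library = file.path(dir, "library.msp"),
             queries = file.path(dir, "queries.msp"),
             truth = file.path(dir, "truth.csv"))
  write_msp(library, paths[["library"]])
  write_msp(spectral_library(queries, resolution = library$resolution),
            paths[["queries"]])
  write.csv(truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}
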