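test_that("build_index orders top peaks by intensity, ties by descending m/z", {
  sp <- spectrum("s", c(50, 73, 147), c(0.2, 1, 0.6))
  idx <- build_index(spectral_library(list(sp)), m = 2)
  expect_equal(idx$top[["s"]], c(73, 147))

  one <- spectrum("one", 120, 1)
  idx1 <- build_index(spectral_library(list(one)), m = 15)
  expect_equal(length(idx1$top[["one"]]), 1L)   # truncated to peak count

  tie <- spectrum("tie", c(100, 200, 150), c(0.5, 0.5, 1))
  idx2 <- build_index(spectral_library(list(tie)), m = 3)
  expect_equal(idx2$top[["tie"]], c(150, 200, 100))  # 200 before 100
})

test_that("build_index agrees with a brute-force stable sort on random spectra", {
  set.seed(707)
  for (i in 1:20) {
    sp <- rand_spectrum_int("s", n_peaks = sample(5:40, 1))
    m <- sample(1:20, 1)
    idx <- build_index(spectral_library(list(sp)), m)
    pk <- sp$peaks[order(-sp$peaks$intensity, -sp$peaks$mz), ]
    expect_equal(idx$top[["s"]], head(pk$mz, m))
  }
})

test_that("match_depth follows the graduated schedule", {
  expect_equal(match_depth(1:8, prescreen_params(8, 15)), 8:15)
  expect_equal(match_depth(1:4, prescreen_params(4, 7)), 4:7)
  expect_equal(match_depth(1:6, prescreen_params(6, 11)), 6:11)
  expect_equal(match_depth(1:4, prescreen_params(4, 4)), rep(4L, 4))
  expect_equal(match_depth(1, prescreen_params(1, 9)), 9L)
  expect_error(match_depth(0, prescreen_params(4, 7)), "1..n")
  expect_error(match_depth(5, prescreen_params(4, 7)), "1..n")
  # interpolation is monotone and hits both endpoints for any n < m
  for (n in c(2L, 5L, 9L)) {
    for (m in c(n, n + 3L, 2L * n - 1L, 3L * n)) {
      d <- match_depth(seq_len(n), prescreen_params(n, m))
      expect_equal(d[1], n)
      expect_equal(d[n], m)
      expect_true(all(diff(d) >= 0))
    }
  }
})

test_that("prescreen counts query peaks found in graduated prefixes", {
  # query top-2 = [100, 73]; library top-3 = [100, 73, 147]; depths (2, 3)
  q <- spectrum("q", c(73, 100), c(0.8, 1))
  l <- spectrum("L1", c(73, 100, 147), c(0.8, 1, 0.5))
  idx <- build_index(spectral_library(list(l)), m = 3)
  ranked <- prescreen(q, idx, prescreen_params(2, 3, 1), 0.01)
  expect_equal(ranked$spectrum_id, "L1")
  expect_equal(ranked$matched_count, 2L)

  # disjoint m/z: empty ranking
  far <- spectrum("far", c(300, 310), c(1, 1))
  expect_equal(nrow(prescreen(far, idx, prescreen_params(2, 3, 1), 0.01)), 0L)
})

test_that("a spectrum queried against itself attains the maximal count", {
  set.seed(808)
  lib <- rand_library_int(10)
  idx <- build_index(lib, m = 15)
  for (id in library_ids(lib)) {
    sp <- lib$spectra[[id]]
    n <- 8L
    ranked <- prescreen(sp, idx, prescreen_params(n, 15, 1), 0.5)
    self <- ranked[ranked$spectrum_id == id, ]
    expect_equal(self$matched_count, min(n, n_peaks(sp)))
  }
})

test_that("prescreen counts agree with the brute-force prefix-scan oracle", {
  set.seed(909)
  for (rep in 1:10) {
    lib <- rand_library_int(8, n_peaks_range = c(5L, 25L))
    q <- rand_spectrum_int("q", n_peaks = sample(5:25, 1))
    n <- sample(1:8, 1)
    m <- sample(n:16, 1)
    idx <- build_index(lib, m)
    ranked <- prescreen(q, idx, prescreen_params(n, m, 1), 0.5)
    for (id in library_ids(lib)) {
      want <- oracle_matched_count(q, lib$spectra[[id]], n, m, 0.5)
      got <- ranked$matched_count[ranked$spectrum_id == id]
      expect_equal(if (length(got) == 0L) 0L else got, want)
    }
    # ranking contract
    expect_true(all(ranked$matched_count >= 1L))
    expect_true(all(ranked$matched_count <= min(n, n_peaks(q))))
    expect_true(all(diff(ranked$matched_count) <= 0))
    expect_false(any(duplicated(ranked$spectrum_id)))
  }
})

test_that("select_candidates appends whole tiers until R is reached", {
  ranked <- structure(
    data.frame(spectrum_id = c("A", "B", "C"), matched_count = c(2L, 2L, 1L)),
    class = c("RankedCandidates", "data.frame"))
  expect_equal(select_candidates(ranked, 1), c("A", "B"))  # tier never split
  expect_equal(select_candidates(ranked, 3), c("A", "B", "C"))
  expect_equal(select_candidates(ranked, 100), c("A", "B", "C"))
  empty <- structure(
    data.frame(spectrum_id = character(0), matched_count = integer(0)),
    class = c("RankedCandidates", "data.frame"))
  expect_equal(select_candidates(empty, 5), character(0))
})

test_that("candidate sets are nested as R grows", {
  set.seed(1010)
  for (rep in 1:20) {
    k <- sample(3:30, 1)
    ranked <- structure(
      data.frame(spectrum_id = sprintf("S%02d", seq_len(k)),
                 matched_count = sort(sample(1:8, k, replace = TRUE),
                                      decreasing = TRUE)),
      class = c("RankedCandidates", "data.frame"))
    rs <- sort(sample(1:40, 4))
    sets <- lapply(rs, function(r) select_candidates(ranked, r))
    for (i in seq_len(length(sets) - 1)) {
      expect_true(all(sets[[i]] %in% sets[[i + 1]]))
    }
  }
})

test_that("matched counts never decrease as m grows", {
  set.seed(1111)
  lib <- rand_library_int(15)
  q <- rand_spectrum_int("q", 20)
  n <- 6L
  prev <- NULL
  for (m in c(6L, 9L, 12L, 20L)) {
    ranked <- prescreen(q, build_index(lib, m), prescreen_params(n, m, 1), 0.5)
    counts <- setNames(ranked$matched_count, ranked$spectrum_id)
    if (!is.null(prev)) {
      common <- names(prev)
      grown <- counts[common]
      grown[is.na(grown)] <- 0L
      expect_true(all(grown >= prev))
    }
    prev <- counts
  }
})

test_that("exhaustive parameters recover every spectrum sharing a peak", {
  set.seed(1212)
  for (rep in 1:5) {
    lib <- rand_library_int(20, n_peaks_range = c(5L, 20L))
    q <- rand_spectrum_int("q", 15)
    max_lib_peaks <- max(vapply(lib$spectra, n_peaks, integer(1)))
    n <- n_peaks(q)
    m <- max(n, max_lib_peaks)
    ranked <- prescreen(q, build_index(lib, m), prescreen_params(n, m, 1), 0.5)
    cand <- select_candidates(ranked, length(lib))
    shares <- vapply(lib$spectra, function(sp) {
      any(vapply(q$peaks$mz, function(x) any(abs(x - sp$peaks$mz) <= 0.5),
                 logical(1)))
    }, logical(1))
    expect_setequal(cand, library_ids(lib)[shares])
  }
})

test_that("prescreen_params validates its arguments", {
  expect_error(prescreen_params(0, 5), "positive")
  expect_error(prescreen_params(8, 7), ">= n")
  expect_error(prescreen_params(4, 7, 0), "positive")
  expect_error(prescreen(spectrum("q", 50, 1),
                         build_index(spectral_library(list(spectrum("a", 50, 1))), 3),
                         prescreen_params(2, 5, 1), 0.5),
               "index was built with m = 3")
})
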