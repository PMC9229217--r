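test_that("inclusion rate is 1 at exhaustive prescreening parameters", {
  set.seed(1818)
  lib <- rand_library_int(25, n_peaks_range = c(5L, 20L))
  queries <- lapply(1:6, function(i) rand_spectrum_int(sprintf("q%d", i), 15))
  cfg <- search_config(prescreen = prescreen_params(20, 20, length(lib)),
                       score_threshold = 0)
  rep <- inclusion_rate(queries, lib, cfg, Ns = c(1, 3, 10))
  expect_equal(rep$inclusion_rate, rep(1, 3))
  expect_true(all(rep$M_pre <= rep$M_orig))
})

test_that("inclusion rate equals a direct two-search recomputation", {
  set.seed(1919)
  lib <- rand_library_int(40)
  queries <- lapply(1:8, function(i) {
    sp <- lib$spectra[[sample(length(lib), 1)]]
    spectrum(sprintf("q%d", i), sp$peaks$mz,
             sp$peaks$intensity * exp(rnorm(n_peaks(sp), sd = 0.6)))
  })
  cfg <- search_config(prescreen = prescreen_params(3, 3, 2),
                       score_threshold = 0.3)
  Ns <- c(1, 3, 10)
  rep <- inclusion_rate(queries, lib, cfg, Ns = Ns)

  # independent route: literally run both searches per query and count
  m_orig <- m_pre <- setNames(numeric(length(Ns)), Ns)
  for (q in queries) {
    full <- full_search(q, lib, cfg)
    pre <- prescreened_search(q, lib, cfg)
    for (j in seq_along(Ns)) {
      top <- head(full$spectrum_id, Ns[j])
      m_orig[j] <- m_orig[j] + length(top)
      m_pre[j] <- m_pre[j] + sum(top %in% pre$spectrum_id)
    }
  }
  expect_equal(rep$M_orig, unname(m_orig))
  expect_equal(rep$M_pre, unname(m_pre))
  expect_equal(rep$inclusion_rate, unname(m_pre / m_orig))
})

test_that("an undefined 0/0 inclusion rate is surfaced as NA with a warning", {
  lib <- spectral_library(list(spectrum("a", c(50, 60), c(1, 1))))
  queries <- list(spectrum("q", c(200, 210), c(1, 1)))
  expect_warning(
    rep <- inclusion_rate(queries, lib, search_config(), Ns = 1),
    "undefined")
  expect_true(is.na(rep$inclusion_rate))
  expect_equal(rep$M_orig, 0L)
})

test_that("the default grid has 8 pairs x 4 R values and rejects n > m", {
  grid <- default_parameter_grid()
  expect_equal(nrow(grid), 32L)
  expect_equal(sort(unique(grid$R)), c(10L, 50L, 100L, 500L))
  expect_true(all(grid$n <= grid$m))

  set.seed(2020)
  lib <- rand_library_int(5)
  q <- list(rand_spectrum_int("q", 10))
  expect_error(parameter_grid(q, lib, triples = data.frame(n = 8, m = 7, R = 5)),
               "n > m")
})

test_that("inclusion rate and cost are monotone non-decreasing in R", {
  set.seed(2121)
  cfg <- fixture_config("low", library_size = 120, seed = 31L)
  lib <- generate_library(cfg)
  qs <- generate_queries(lib, cfg, n_queries = 15)
  triples <- data.frame(n = 6L, m = 11L, R = c(5L, 20L, 60L, 120L))
  grid <- parameter_grid(qs$queries, lib, triples = triples, Ns = c(1, 3, 10))
  for (N in c(1, 3, 10)) {
    rows <- grid[grid$N == N, ]
    rows <- rows[order(rows$R), ]
    expect_true(all(diff(rows$inclusion_rate) >= 0))
    expect_true(all(diff(rows$mean_eval_count) >= 0))
  }
})

test_that("grid rows agree with per-triple inclusion_rate runs", {
  set.seed(2222)
  cfg <- fixture_config("low", library_size = 60, seed = 17L)
  lib <- generate_library(cfg)
  qs <- generate_queries(lib, cfg, n_queries = 10)
  triples <- data.frame(n = c(4L, 8L), m = c(7L, 15L), R = c(10L, 50L))
  grid <- parameter_grid(qs$queries, lib, triples = triples, Ns = c(1, 3))
  for (i in seq_len(nrow(triples))) {
    cfg_i <- search_config(prescreen = prescreen_params(triples$n[i],
                                                        triples$m[i],
                                                        triples$R[i]))
    rep_i <- inclusion_rate(qs$queries, lib, cfg_i, Ns = c(1, 3))
    sub <- grid[grid$n == triples$n[i] & grid$R == triples$R[i], ]
    expect_equal(sub$inclusion_rate, rep_i$inclusion_rate)
    expect_equal(sub$mean_eval_count[1], attr(rep_i, "mean_eval_count"))
  }
})

test_that("write_grid_csv emits the documented columns", {
  set.seed(2323)
  lib <- rand_library_int(10)
  q <- list(rand_spectrum_int("q", 10))
  grid <- parameter_grid(q, lib, triples = data.frame(n = 4, m = 7, R = 5),
                         Ns = c(1, 3),
                         config = search_config(score_threshold = 0))
  f <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(grid, f)
  got <- read.csv(f)
  expect_equal(names(got),
               c("n", "m", "R", "N", "inclusion_rate", "mean_eval_count"))
  expect_equal(nrow(got), 2L)
})
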