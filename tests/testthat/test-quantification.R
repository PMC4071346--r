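# a tiny map with features at known coordinates
tiny_map <- function(mz, rt, intensity = rep(100, length(mz)),
                     env = NULL) {
  map <- data.frame(mz = mz, rt = rt, intensity = intensity)
  if (is.null(env)) env <- lapply(intensity, function(i) i * c(1, 0.5, 0.15))
  map$envelope <- I(env)
  map
}

tiny_ids <- function(mz_pred, rt_pred,
                     env = list(c(1, 0.5, 0.15))) {
  data.frame(peptide_id = paste0("pep", seq_along(mz_pred)), charge = 1L,
             mz_pred = mz_pred, rt_pred = rt_pred,
             envelope = I(rep(env, length(mz_pred))),
             stringsAsFactors = FALSE)
}

test_that("match_pass tags exact features and reports misses as absent", {
  ids <- tiny_ids(500.25, 30)
  map <- tiny_map(500.25, 30)
  got <- match_pass(ids, map, 10, 3, 0.9)
  expect_equal(nrow(got), 1)
  expect_equal(got$mz_dev_ppm, 0)
  expect_equal(got$rt_dev_min, 0)
  expect_equal(got$env_score, 1.0, tolerance = 1e-12)
  # empty map: no matches, no error
  empty <- tiny_map(numeric(0), numeric(0), numeric(0), list())
  expect_equal(nrow(match_pass(ids, empty, 10, 3, 0.9)), 0)
  expect_error(match_pass(ids[0, ], map, 10, 3, 0.9), "empty")
})

test_that("straddling candidates resolve to the minimum normalized distance", {
  set.seed(21)
  for (i in 1:20) {
    mz0 <- runif(1, 400, 1200); rt0 <- runif(1, 10, 90)
    n_cand <- sample(2:5, 1)
    dmz <- runif(n_cand, -8, 8)    # ppm
    drt <- runif(n_cand, -2.5, 2.5)
    map <- tiny_map(mz0 * (1 + dmz * 1e-6), rt0 + drt)
    got <- match_pass(tiny_ids(mz0, rt0), map, 10, 3, 0.9)
    d <- sqrt((dmz / 10)^2 + (drt / 3)^2)
    expect_equal(got$feature_idx, which.min(d))
  }
})

test_that("pass-1 match sets grow monotonically with tolerance", {
  cc <- fast_cohort(seed = 4)
  cd <- generate_cohort(cc)
  ids <- build_id_list(cc$panel, cd$truth$ref_rt, cc$charges)
  narrow <- match_pass(ids, cd$maps[[1]], 4, 1, 0.9)
  wide <- match_pass(ids, cd$maps[[1]], 10, 3, 0.9)
  expect_true(all(paste(narrow$peptide_id, narrow$charge) %in%
                    paste(wide$peptide_id, wide$charge)))
  expect_gt(nrow(wide), 0)
})

test_that("LOESS calibration recovers flat, constant and smooth drifts", {
  x <- seq(100, 1100, length.out = 200)
  f0 <- fit_calibration(x, rep(0, 200))
  expect_true(all(abs(f0(x)) < 1e-9))
  f2 <- fit_calibration(x, rep(2, 200))
  expect_true(all(abs(f2(x) - 2) < 1e-6))
  # injected smooth quadratic drift, noise-free
  drift <- 3 * ((x - 600) / 500)^2 - 1.5
  fq <- fit_calibration(x, drift)
  rms <- sqrt(mean((fq(x) - drift)^2))
  expect_lt(rms, 0.02 * 3)  # residual RMS < 2% of the amplitude
  # too few points: median fallback with warning
  expect_warning(ff <- fit_calibration(1:4, c(1, 1.2, 0.9, 1.1)), "too few")
  expect_equal(ff(10), median(c(1, 1.2, 0.9, 1.1)))
})

test_that("calibration is idempotent on an already calibrated map", {
  set.seed(33)
  x <- sort(runif(150, 0, 100))
  drift <- 1.5 * sin(x / 20)
  f1 <- fit_calibration(x, drift)
  resid1 <- drift - f1(x)
  f2 <- fit_calibration(x, resid1)
  resid2 <- resid1 - f2(x)
  expect_lt(sqrt(mean(resid2^2)) - sqrt(mean(resid1^2)), 1e-6)
})

test_that("two-pass extraction is a no-op on drift-free maps", {
  cc <- fast_cohort(seed = 8, mz_drift_ppm = 0, rt_drift_min = 0,
                    envelope_cv = 0)
  cd <- generate_cohort(cc)
  ids <- build_id_list(cc$panel, cd$truth$ref_rt, cc$charges)
  res <- two_pass_extract(ids, cd$maps[[1]], match_config())
  p1 <- res$pass1[order(res$pass1$peptide_id, res$pass1$charge), ]
  tags <- res$tags[order(res$tags$peptide_id, res$tags$charge), ]
  expect_equal(p1$feature_idx, tags$feature_idx)
  expect_equal(nrow(p1), nrow(tags))
})

test_that("features shifted beyond pass-1 tolerance yield an empty result", {
  ids <- tiny_ids(500, 30)
  map <- tiny_map(500 * (1 + 50e-6), 30)  # 50 ppm away
  expect_warning(res <- two_pass_extract(ids, map, match_config()),
                 "calibration not fitted")
  expect_equal(nrow(res$tags), 0)
})

test_that("no tag violates its pass tolerance or envelope contract", {
  cc <- fast_cohort(seed = 14)
  cd <- generate_cohort(cc)
  ids <- build_id_list(cc$panel, cd$truth$ref_rt, cc$charges)
  cfg <- match_config()
  for (s in names(cd$maps)[1:4]) {
    res <- two_pass_extract(ids, cd$maps[[s]], cfg)
    t1 <- res$tags[res$tags$pass == 1, ]
    expect_true(all(abs(t1$mz_dev_ppm) <= cfg$mz_tol_ppm))
    expect_true(all(abs(t1$rt_dev_min) <= cfg$rt_tol_min))
    expect_true(all(t1$env_score >= cfg$env_min_pass1))
    t2 <- res$tags[res$tags$pass == 2, ]
    expect_true(all(abs(t2$mz_dev_ppm) <= res$calibration$mz_tol2 + 1e-9))
    expect_true(all(abs(t2$rt_dev_min) <= res$calibration$rt_tol2 + 1e-9))
    expect_true(all(t2$env_score >= cfg$env_min_pass2))
    expect_lte(res$calibration$mz_tol2, cfg$mz_tol_ppm)
    expect_lte(res$calibration$rt_tol2, cfg$rt_tol_min)
  }
})

test_that("abundance extraction takes prominent peaks and sums charges", {
  tags <- data.frame(peptide_id = c("a", "a"), charge = c(1L, 2L),
                     feature_idx = 1:2, mz_dev_ppm = 0, rt_dev_min = 0,
                     env_score = 1, intensity = c(100, 40))
  expect_equal(unname(extract_abundance(tags)), 140)
  expect_equal(unname(extract_abundance(tags, sum_charges = FALSE)), 100)
  # centroid feature intensity is the most prominent envelope peak
  env <- list(c(100, 55, 18))
  map <- tiny_map(500, 30, intensity = 100, env = env)
  expect_equal(map$intensity[1], max(env[[1]]))
})

test_that("the 2-D Gaussian fit recovers a known peak height", {
  grid <- expand.grid(mz = seq(499.98, 500.02, by = 0.002),
                      rt = seq(29.0, 31.0, by = 0.1))
  A <- 5000
  grid$intensity <- A * exp(-0.5 * (((grid$mz - 500) / 0.005)^2 +
                                      ((grid$rt - 30) / 0.3)^2))
  h <- fit_peak_height(grid)
  expect_equal(h, A, tolerance = 0.01)
})

test_that("median normalization divides by the sample median", {
  expect_equal(normalize_sample(c(2, 4, 6)), c(0.5, 1, 1.5))
  x <- c(1.2, NA, 3.4, 0.7, 9.1)
  n1 <- normalize_sample(x)
  n2 <- normalize_sample(x * 17)
  expect_equal(n1, n2)
  expect_true(is.na(n1[2]))
  expect_equal(median(n1, na.rm = TRUE), 1.0)
  expect_error(normalize_sample(c(NA_real_, NA_real_)), "missing")
})
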