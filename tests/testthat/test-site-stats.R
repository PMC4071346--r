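test_that("site intensity follows the rescale-and-median rule", {
  ab <- rbind(p1 = c(2, 4, 6), p2 = c(1, 2, 3))
  colnames(ab) <- paste0("s", 1:3)
  got <- site_modification_intensity(ab, c("p1", "p2"))
  # r = (4, 2), L = 3, both rescale to (1.5, 3, 4.5)
  expect_equal(unname(got), c(1.5, 3, 4.5))
  # single contributing peptide: identity
  one <- site_modification_intensity(ab, "p1")
  expect_equal(unname(one), c(2, 4, 6))
  # no contributing peptides: unquantifiable, not an error
  expect_null(site_modification_intensity(ab, "absent"))
})

test_that("site intensity absorbs per-peptide scale up to a common level", {
  # rescaling one peptide's whole row leaves the between-sample profile
  # unchanged; only the arbitrary common level (the median of the peptide
  # reference levels) can shift, which cancels in every downstream ratio
  set.seed(3)
  for (i in 1:10) {
    ab <- matrix(rlnorm(12), 3, 4,
                 dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
    ab[sample(length(ab), 2)] <- NA
    base <- site_modification_intensity(ab, rownames(ab))
    ab2 <- ab
    ab2[2, ] <- ab2[2, ] * runif(1, 0.1, 10)
    got <- site_modification_intensity(ab2, rownames(ab2))
    ratio <- got / base
    expect_lt(diff(range(ratio[is.finite(ratio)])), 1e-12)
  }
})

test_that("multiply-modified peptides are excluded from site aggregation", {
  meta <- data.frame(peptide_id = c("p1", "p2"), histone = "H3",
                     site = "K27", mod = "Acetyl (K)",
                     sequence = "X", start = 1L, mass = 1,
                     n_var_mods = c(1L, 2L))
  ab <- rbind(p1 = c(2, 4), p2 = c(100, 100))
  colnames(ab) <- c("a", "b")
  samples <- data.frame(sample_id = c("a", "b"), pair = c(1L, 1L),
                        group = c("tumour", "normal"))
  sm <- site_intensity_matrix(ab, meta, samples)
  expect_equal(sort(sm$intensity), c(2, 4))  # p2 never contributes
  expect_equal(unique(sm$n_peptides), 1L)
})

test_that("the exhaustive sign-flip paired t test matches hand enumeration", {
  res <- resampling_paired_t(c(1, 2, 3))
  expect_equal(abs(res$statistic), 3.464, tolerance = 1e-3)
  expect_equal(res$p_value, 0.25)
  expect_equal(res$method, "exhaustive")
  # degenerate all-zero differences
  expect_equal(resampling_paired_t(c(0, 0, 0))$p_value, 1.0)
  # sign symmetry
  d <- c(0.3, -1.2, 2.2, 0.7, -0.1)
  expect_equal(resampling_paired_t(d)$p_value,
               resampling_paired_t(-d)$p_value)
  expect_error(resampling_paired_t(c(1, 2)), "3 complete pairs")
})

test_that("Monte-Carlo p-values converge to the exhaustive enumeration", {
  set.seed(17)
  for (i in 1:5) {
    n <- sample(8:12, 1)
    d <- rnorm(n, mean = 0.4)
    ex <- resampling_paired_t(d)
    mc <- resampling_paired_t(d, n_resamples = 4000L, seed = 100 + i,
                              exhaustive_limit = 2)
    se <- sqrt(ex$p_value * (1 - ex$p_value) / 4000)
    expect_lt(abs(mc$p_value - ex$p_value), 3 * se + 2 / 4000)
  }
})

test_that("Wilcoxon signed-rank matches exhaustive sign enumeration", {
  # all-positive differences: one-sided exact p = 1/32
  res_g <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), alternative = "greater")
  expect_equal(res_g$statistic, 15)  # W- = 0 <=> V = n(n+1)/2
  expect_equal(res_g$p_value, 1 / 32)
  # exhaustive two-sided oracle over all sign vectors, distinct magnitudes
  set.seed(29)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    d <- sample(seq(0.5, 20, by = 0.5), n)  # distinct |d|, no zeros
    got <- wilcoxon_signed_rank(d)
    r <- rank(abs(d))
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.numeric(signs %*% r)  # W+ under all sign assignments
    M <- n * (n + 1) / 2
    w <- sum(r[d > 0])
    lo <- min(w, M - w); hi <- max(w, M - w)
    oracle <- min(1, mean(w_all <= lo) + mean(w_all >= hi))
    expect_equal(got$p_value, oracle, tolerance = 1e-12)
  }
  # symmetric degenerate input
  expect_equal(wilcoxon_signed_rank(c(0, 0))$p_value, 1)
})

test_that("the differential table flags injected effects and reports FC", {
  set.seed(41)
  n <- 12
  nor <- rlnorm(n, log(10), 0.15)
  tum <- nor * 1.54 * exp(rnorm(n, 0, 0.1))
  sm <- toy_site_matrix(tum, nor)
  res <- differential_table(sm, seed = 1)
  expect_equal(res$table$fc, mean(tum) / mean(nor))
  expect_true(res$table$significant)
  expect_equal(res$table$n_pairs, n)
  # mean-of-ratios option
  res2 <- differential_table(sm, fc_method = "mean_of_ratios", seed = 1)
  expect_equal(res2$table$fc, mean(tum / nor))
})

test_that("sites with too few complete pairs are excluded with a reason", {
  tum <- c(1.2, 1.4, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA)
  nor <- c(1.0, 1.1, 1.0, NA, NA, NA, NA, NA, NA, NA, NA, NA)
  sm <- toy_site_matrix(tum, nor)
  res <- differential_table(sm)
  expect_equal(nrow(res$table), 0)
  expect_equal(res$excluded$reason, "insufficient pairs")
  expect_equal(res$excluded$n_pairs, 2L)
})

test_that("labelling-index summaries report group means and a paired p", {
  li <- h3k27ac_labelling_index()
  res <- labelling_index_summary(li$crc, li$normal, seed = 1)
  expect_equal(res$mean_case, 69.01)
  expect_equal(res$mean_control, 52.66)
  expect_lt(res$p_value, 0.05)
  # identical columns: equal means, p = 1
  same <- labelling_index_summary(li$crc, li$crc)
  expect_equal(same$mean_case, same$mean_control)
  expect_equal(same$p_value, 1.0)
  expect_error(labelling_index_summary(1:3, 1:4), "same length")
})
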