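test_that("target-decoy q-values match the worked example and the oracle", {
  psms <- data.frame(score = c(10, 9, 8, 7, 6, 8.5, 6.5),
                     is_decoy = c(rep(FALSE, 5), TRUE, TRUE))
  q <- compute_qvalues(psms)
  expect_equal(q$q_value[1:5], c(0, 0, 0.25, 0.25, 0.4))
  expect_true(all(q$q_value[q$is_decoy] == 1))
  # no decoys: all zero
  q0 <- compute_qvalues(data.frame(score = c(3, 2, 1), is_decoy = FALSE))
  expect_equal(q0$q_value, c(0, 0, 0))
  # all decoys outscore all targets: capped at 1
  q1 <- compute_qvalues(data.frame(score = c(1, 2, 3, 11, 12, 13),
                                   is_decoy = rep(c(FALSE, TRUE), each = 3)))
  expect_equal(q1$q_value[1:3], c(1, 1, 1))
  expect_error(compute_qvalues(data.frame(score = 1, is_decoy = TRUE)),
               "no target")
})

test_that("q-values equal the brute-force oracle on random toy sets", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    psms <- data.frame(score = round(runif(n, 0, 10), 1),
                       is_decoy = runif(n) < 0.4)
    if (!any(!psms$is_decoy)) psms$is_decoy[1] <- FALSE
    got <- compute_qvalues(psms)
    want <- qvalue_oracle(psms$score, psms$is_decoy)
    expect_equal(got$q_value[!psms$is_decoy], want[!psms$is_decoy],
                 tolerance = 1e-12)
  }
})

test_that("q-values are monotone non-increasing with score", {
  set.seed(11)
  psms <- data.frame(score = rnorm(200), is_decoy = runif(200) < 0.5)
  q <- compute_qvalues(psms)
  tg <- q[!q$is_decoy, ]
  o <- order(tg$score, decreasing = TRUE)
  expect_true(all(diff(tg$q_value[o]) >= -1e-12))
})

test_that("site localization resolves isomers by matched fragments", {
  reg <- klysine_registry()
  iso_a <- modified_peptide("KSAPATGGVK", data.frame(pos = 1,
                                                     name = "Acetyl (K)"),
                            registry = reg, apply_fixed = FALSE)
  iso_b <- modified_peptide("KSAPATGGVK", data.frame(pos = 10,
                                                     name = "Acetyl (K)"),
                            registry = reg, apply_fixed = FALSE)
  # single candidate
  loc1 <- localize_site(list(iso_a), make_fragment_spectrum(iso_a, seed = 1),
                        registry = reg)
  expect_equal(loc1$best_probability, 1.0)
  # full-coverage spectrum of isomer A
  spec_a <- make_fragment_spectrum(iso_a, coverage = 1.0, seed = 2)
  loc <- localize_site(list(iso_a, iso_b), spec_a, registry = reg)
  expect_equal(loc$best_site, 1L)
  expect_gt(loc$best_probability, 0.99)
  # binomial-tail oracle agreement on the per-isomer scores
  tol <- 0.02
  span <- diff(range(spec_a))
  p_match <- min(0.999, length(spec_a) * 2 * tol / span)
  for (i in 1:2) {
    ions <- fragment_ions(list(iso_a, iso_b)[[i]], registry = reg)
    k <- sum(vapply(ions$mz, function(m) any(abs(spec_a - m) <= tol),
                    logical(1)))
    oracle <- sum(dbinom(k:nrow(ions), nrow(ions), p_match))
    expect_equal(loc$tail_pvalues[i], oracle, tolerance = 1e-9)
  }
  # spectrum matching nothing: symmetric 0.5/0.5
  loc_n <- localize_site(list(iso_a, iso_b), c(5000, 6000), registry = reg)
  expect_equal(unname(loc_n$probabilities), c(0.5, 0.5))
  expect_error(localize_site(list(iso_a), numeric(0), registry = reg),
               "empty")
})

test_that("artifact filters partition peptides with machine-readable reasons", {
  reg <- default_modifications()
  mk <- function(seq, pos, name) {
    modified_peptide(seq, data.frame(pos = pos, name = name), registry = reg)
  }
  peps <- list(
    mk("SAPATGGVK", 9, "Methyl (K)"),        # C-terminal methyl-K
    mk("KSAPDTGGVR", 1, "Methyl (K)"),       # methyl-K with internal D
    mk("KSAPETGGVR", 1, "Trimethyl (K)"),    # trimethyl-K with internal E
    mk("SAPATGGVR", 9, "Deamidated (R)"),    # C-terminal deamidated R
    mk("KSAPATGGVK", 1, "Acetyl (K)"),       # retained control
    mk("KSAPATGGVR", 1, "Methyl (K)"),       # methyl-K, no acidic: retained
    mk("DEAPATGGVK", 10, "Acetyl (K)")       # acetyl with acidics: retained
  )
  res <- filter_artifacts(peps)
  expect_equal(res$rejected$reason,
               c("cterm_methyl_k", "acidic_context_methyl",
                 "acidic_context_methyl", "cterm_deamidated_r"))
  expect_length(res$retained, 3)
  # partition and idempotence
  expect_equal(length(res$retained) + nrow(res$rejected), length(peps))
  res2 <- filter_artifacts(res$retained)
  expect_equal(nrow(res2$rejected), 0)
  expect_length(res2$retained, length(res$retained))
})

test_that("protein grouping merges identical sets and drops subsets", {
  inc <- list(A = c("p1", "p2"), B = c("p1", "p2"))
  cl <- group_proteins(inc)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$members, c("A", "B"))
  cl2 <- group_proteins(list(A = c("p1", "p2", "p3"), B = c("p1", "p2")))
  expect_length(cl2, 1)
  expect_equal(cl2[[1]]$members, "A")
  expect_length(group_proteins(list(A = "p1")), 0)
  expect_error(group_proteins(list()), "empty")
})

test_that("protein grouping matches a brute-force oracle and ignores order", {
  set.seed(13)
  peps <- paste0("p", 1:6)
  for (rep in 1:20) {
    n_prot <- sample(3:8, 1)
    inc <- lapply(seq_len(n_prot), function(i) {
      sample(peps, sample(1:5, 1))
    })
    names(inc) <- paste0("prot", seq_len(n_prot))
    got <- group_proteins(inc)
    # oracle: pairwise subset/equality checks
    sets <- lapply(inc, function(x) sort(unique(x)))
    keep <- names(sets)[vapply(names(sets), function(a) {
      if (length(sets[[a]]) < 2) return(FALSE)
      !any(vapply(names(sets), function(b) {
        a != b && all(sets[[a]] %in% sets[[b]]) &&
          length(sets[[a]]) < length(sets[[b]])
      }, logical(1)))
    }, logical(1))]
    expect_setequal(unlist(lapply(got, `[[`, "members")), keep)
    # order invariance
    perm <- sample(names(inc))
    got_p <- group_proteins(inc[perm])
    expect_equal(lapply(got, `[[`, "members"),
                 lapply(got_p, `[[`, "members"))
  }
})
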