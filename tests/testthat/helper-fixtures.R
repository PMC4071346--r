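# Shared fixtures for the test suite. Everything is built in code.

# registry restricted to lysine modifications (no fixed mods)
klysine_registry <- function() {
  specs <- list(
    modification_spec("Acetyl (K)", "K", "C2H2O"),
    modification_spec("Methyl (K)", "K", "CH2"),
    modification_spec("Dimethyl (K)", "K", "C2H4"),
    modification_spec("Trimethyl (K)", "K", "C3H6")
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

# atom-by-atom polynomial-expansion oracle for isotopic envelopes,
# independent of the package's binary-exponentiation convolution
envelope_oracle <- function(comp, floor = 1e-3) {
  iso <- list(
    C = list(offset = c(0, 1), ab = c(0.9893, 0.0107)),
    H = list(offset = c(0, 1), ab = c(0.999885, 0.000115)),
    N = list(offset = c(0, 1), ab = c(0.99636, 0.00364)),
    O = list(offset = c(0, 1, 2), ab = c(0.99757, 0.00038, 0.00205)),
    S = list(offset = c(0, 1, 2, 4), ab = c(0.9499, 0.0075, 0.0425, 0.0001)),
    P = list(offset = 0, ab = 1)
  )
  dist <- 1
  for (el in names(comp)) {
    base <- numeric(max(iso[[el]]$offset) + 1)
    base[iso[[el]]$offset + 1] <- iso[[el]]$ab
    for (atom in seq_len(comp[[el]])) {  # one atom at a time
      out <- numeric(length(dist) + length(base) - 1)
      for (i in seq_along(dist)) {
        out[i:(i + length(base) - 1)] <-
          out[i:(i + length(base) - 1)] + dist[i] * base
      }
      dist <- out[seq_len(min(length(out), 64))]
    }
  }
  dist <- dist / max(dist)
  dist[seq_len(max(which(dist >= floor)))]
}

# brute-force target-decoy q-value oracle: FDR at every distinct score
# threshold, then monotonized from the least significant rank upward
qvalue_oracle <- function(score, is_decoy) {
  thresholds <- sort(unique(score), decreasing = TRUE)
  fdr <- vapply(thresholds, function(th) {
    min(1, sum(is_decoy & score >= th) / max(1, sum(!is_decoy & score >= th)))
  }, numeric(1))
  q_at <- rev(cummin(rev(fdr)))
  out <- rep(1, length(score))
  for (i in which(!is_decoy)) {
    out[i] <- q_at[match(score[i], thresholds)]
  }
  out
}

# a small paired site-intensity table in the long format
toy_site_matrix <- function(tum, nor, histone = "H3", site = "K27",
                            mod = "Acetyl (K)") {
  n <- length(tum)
  data.frame(
    histone = histone, site = site, mod = mod,
    sample_id = c(sprintf("P%02d_T", 1:n), sprintf("P%02d_N", 1:n)),
    pair = c(1:n, 1:n),
    group = rep(c("tumour", "normal"), each = n),
    intensity = c(tum, nor), n_peptides = 1L,
    stringsAsFactors = FALSE
  )
}

# small cohort config for fast tests
fast_cohort <- function(seed = 1L, ...) {
  cohort_config(n_pairs = 4L, seed = seed, ...)
}
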