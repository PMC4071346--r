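# Seeded generator of paired tumour/normal LC-MS cohorts with full ground
# truth: feature maps with systematic m/z and retention-time drift, log-normal
# intensity noise, missing features, a target/decoy PSM score table and
# fragment spectra for localization.

#' Configuration of a synthetic paired cohort
#'
#' Defaults emulate the study conditions: 12 tumour/normal pairs, site fold
#' changes 1.67 (H3 K27me3), 1.54 (H3 K27ac), 1.24 (H2B S64ph) and 0.83
#' (H3 K79ac), 20\% log-normal intensity noise, a smooth m/z drift of up to
#' 3 ppm (inside the 5 ppm search tolerance), a smooth retention-time drift of
#' up to 1.5 min over a 100 min gradient, and 10\% missing features.
#'
#' @param n_pairs number of tumour/normal pairs (>= 2).
#' @param panel modified-peptide panel (default \code{\link{default_panel}}).
#' @param fold_changes named numeric vector of multiplicative tumour/normal
#'   factors, names \code{"histone|site|mod"}; sites not listed have factor 1.
#' @param intensity_cv coefficient of variation of the per-sample
#'   multiplicative log-normal intensity noise.
#' @param mz_drift_ppm maximum amplitude of the smooth per-sample m/z drift.
#' @param rt_drift_min maximum amplitude of the smooth per-sample RT drift.
#' @param missingness probability that an emitted feature is dropped.
#' @param envelope_cv multiplicative noise on individual envelope peak
#'   intensities (keeps envelope-fit acceptance non-trivial).
#' @param charges charge states emitted per peptide.
#' @param rt_window retention-time window (min) over which reference RTs are
#'   drawn uniformly.
#' @param seed integer seed; the cohort is a deterministic function of
#'   (config, seed).
#' @return a list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_pairs = 12L,
                          panel = default_panel(),
                          fold_changes = c("H3|K27|Trimethyl (K)" = 1.67,
                                           "H3|K27|Acetyl (K)"    = 1.54,
                                           "H2B|S64|Phospho (ST)" = 1.24,
                                           "H3|K79|Acetyl (K)"    = 0.83),
                          intensity_cv = 0.20,
                          mz_drift_ppm = 3.0,
                          rt_drift_min = 1.5,
                          missingness = 0.10,
                          envelope_cv = 0.05,
                          charges = 1:3,
                          rt_window = c(0, 100),
                          seed = 1L) {
  if (n_pairs < 2) stop("need at least 2 pairs")
  if (any(fold_changes <= 0)) stop("fold changes must be positive")
  if (intensity_cv < 0) stop("intensity CV must be >= 0")
  if (missingness < 0 || missingness >= 1) stop("missingness must be in [0, 1)")
  if (mz_drift_ppm < 0 || rt_drift_min < 0) stop("drift amplitudes must be >= 0")
  structure(list(n_pairs = as.integer(n_pairs), panel = panel,
                 fold_changes = fold_changes, intensity_cv = intensity_cv,
                 mz_drift_ppm = mz_drift_ppm, rt_drift_min = rt_drift_min,
                 missingness = missingness, envelope_cv = envelope_cv,
                 charges = as.integer(charges), rt_window = rt_window,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# smooth random cubic on [lo, hi] scaled to max |f| = amplitude
.random_smooth_drift <- function(lo, hi, amplitude) {
  coef <- stats::runif(4, -1, 1)
  f_raw <- function(x) {
    z <- 2 * (x - lo) / max(hi - lo, 1e-9) - 1  # scale to [-1, 1]
    coef[1] + coef[2] * z + coef[3] * z^2 + coef[4] * z^3
  }
  grid <- seq(lo, hi, length.out = 201)
  m <- max(abs(f_raw(grid)))
  scale <- if (m > 0) amplitude / m else 0
  list(coef = coef, lo = lo, hi = hi, scale = scale,
       f = function(x) f_raw(x) * scale)
}

.drift_fun <- function(d) d$f

#' Generate a synthetic paired tumour/normal cohort
#'
#' Each panel peptide receives a log-normal base abundance and a uniform
#' reference retention time; tumour abundances of peptides covering a
#' differential site are multiplied by the site's fold change; per-sample
#' log-normal noise with the configured CV is applied. Every (peptide, charge)
#' is emitted as an isotopic-envelope feature at its theoretical m/z perturbed
#' by the sample's smooth ppm-scale m/z drift and at the reference RT
#' perturbed by the sample's smooth RT drift; features are dropped at the
#' missingness rate. A PSM score table with decoys drawn from the null score
#' distribution and targets shifted upward accompanies the maps.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return list with \code{maps} (named list of per-sample feature data
#'   frames: \code{mz}, \code{rt}, \code{intensity}, \code{envelope}
#'   list-column), \code{samples} (sample table: \code{sample_id},
#'   \code{pair}, \code{group}), \code{psms} (target/decoy score table) and
#'   \code{truth} (ground truth: true abundances, reference RTs, drift
#'   functions, differential sites, envelopes, config).
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  panel <- config$panel
  meta <- panel_meta(panel)
  n_pep <- nrow(meta)
  site_key <- paste(meta$histone, meta$site, meta$mod, sep = "|")
  fc <- config$fold_changes[site_key]
  fc[is.na(fc)] <- 1
  names(fc) <- meta$peptide_id

  samples <- data.frame(
    sample_id = as.vector(rbind(sprintf("P%02d_T", seq_len(config$n_pairs)),
                                sprintf("P%02d_N", seq_len(config$n_pairs)))),
    pair = rep(seq_len(config$n_pairs), each = 2),
    group = rep(c("tumour", "normal"), config$n_pairs),
    stringsAsFactors = FALSE
  )

  ref_rt <- stats::runif(n_pep, config$rt_window[1] + 2,
                         config$rt_window[2] - 2)
  names(ref_rt) <- meta$peptide_id
  base_abundance <- stats::rlnorm(n_pep, meanlog = log(1e6), sdlog = 1)
  names(base_abundance) <- meta$peptide_id
  sigma <- sqrt(log(1 + config$intensity_cv^2))

  true_abundance <- matrix(NA_real_, n_pep, nrow(samples),
                           dimnames = list(meta$peptide_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    mult <- if (samples$group[j] == "tumour") fc else rep(1, n_pep)
    noise <- if (sigma > 0) exp(stats::rnorm(n_pep, -sigma^2 / 2, sigma))
             else rep(1, n_pep)
    true_abundance[, j] <- base_abundance * mult * noise
  }

  envelopes <- lapply(panel, function(p) peptide_envelope(p$peptide))
  names(envelopes) <- meta$peptide_id
  charge_w <- c(0.2, 0.5, 0.3)[seq_along(config$charges)]
  charge_w <- charge_w / sum(charge_w)

  mz_lo <- min(vapply(seq_len(n_pep), function(i) {
    min(peptide_mz(meta$mass[i], max(config$charges)))
  }, numeric(1)))
  mz_hi <- max(vapply(seq_len(n_pep), function(i) {
    peptide_mz(meta$mass[i], min(config$charges))
  }, numeric(1)))

  # (peptide, charge) emission grid, shared across samples
  n_ch <- length(config$charges)
  grid_pep <- rep(seq_len(n_pep), each = n_ch)
  grid_ci <- rep(seq_len(n_ch), n_pep)
  grid_mz <- peptide_mz(rep(meta$mass, each = n_ch),
                        config$charges[grid_ci])
  env_rel_list <- lapply(envelopes, `[[`, "abundances")
  env_len <- lengths(env_rel_list)[grid_pep]
  env_sigma <- if (config$envelope_cv > 0) {
    sqrt(log(1 + config$envelope_cv^2))
  } else 0

  maps <- vector("list", nrow(samples))
  names(maps) <- samples$sample_id
  feature_ids <- vector("list", nrow(samples))
  names(feature_ids) <- samples$sample_id
  mz_drift <- vector("list", nrow(samples))
  rt_drift <- vector("list", nrow(samples))
  for (j in seq_len(nrow(samples))) {
    mz_drift[[j]] <- .random_smooth_drift(mz_lo, mz_hi, config$mz_drift_ppm)
    rt_drift[[j]] <- .random_smooth_drift(config$rt_window[1],
                                          config$rt_window[2],
                                          config$rt_drift_min)
    keep <- stats::runif(length(grid_pep)) >= config$missingness
    pep_k <- grid_pep[keep]
    mz_obs <- grid_mz[keep] * (1 + mz_drift[[j]]$f(grid_mz[keep]) * 1e-6)
    rt_obs <- ref_rt[pep_k] + rt_drift[[j]]$f(ref_rt[pep_k])
    height <- true_abundance[cbind(pep_k, j)] * charge_w[grid_ci[keep]]
    len_k <- env_len[keep]
    noise <- if (env_sigma > 0) {
      exp(stats::rnorm(sum(len_k), 0, env_sigma))
    } else rep(1, sum(len_k))
    noise_split <- split(noise, rep(seq_along(len_k), len_k))
    env_int <- lapply(seq_along(pep_k), function(k) {
      env_rel_list[[pep_k[k]]] * height[k] * noise_split[[k]]
    })
    map <- data.frame(mz = mz_obs, rt = unname(rt_obs),
                      intensity = vapply(env_int, max, numeric(1)),
                      stringsAsFactors = FALSE)
    map$envelope <- I(env_int)
    maps[[j]] <- map
    feature_ids[[j]] <- data.frame(peptide_id = meta$peptide_id[pep_k],
                                   charge = config$charges[grid_ci[keep]],
                                   stringsAsFactors = FALSE)
  }

  # PSM score table: one target PSM per panel peptide and an equal number of
  # decoys; decoy scores are the null distribution, targets shifted upward.
  psms <- data.frame(
    spectrum_id = c(sprintf("spec_t%03d", seq_len(n_pep)),
                    sprintf("spec_d%03d", seq_len(n_pep))),
    peptide_id = c(meta$peptide_id, sprintf("DECOY_%03d", seq_len(n_pep))),
    score = c(stats::rnorm(n_pep, 35, 5), stats::rnorm(n_pep, 12, 5)),
    is_decoy = rep(c(FALSE, TRUE), each = n_pep),
    stringsAsFactors = FALSE
  )

  truth <- list(
    true_abundance = true_abundance, ref_rt = ref_rt,
    base_abundance = base_abundance, fold_change = fc,
    differential_sites = names(config$fold_changes)[config$fold_changes != 1],
    mz_drift = mz_drift, rt_drift = rt_drift,
    envelopes = envelopes, feature_ids = feature_ids, config = config
  )
  list(maps = maps, samples = samples, psms = psms, truth = truth)
}

#' Synthesize a fragment spectrum for a modified peptide
#'
#' Emits a stated fraction of the theoretical singly charged b/y ions at
#' exact m/z, plus uniformly scattered noise peaks.
#'
#' @param peptide a \code{modified_peptide}.
#' @param coverage fraction of theoretical ions to emit, in (0, 1].
#' @param noise_peaks number of uniformly scattered noise peaks.
#' @param seed optional seed for reproducible ion sampling.
#' @param registry modification registry.
#' @return numeric vector of fragment m/z values.
#' @export
make_fragment_spectrum <- function(peptide, coverage = 1.0, noise_peaks = 0L,
                                   seed = NULL,
                                   registry = default_modifications()) {
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  ions <- fragment_ions(peptide, registry = registry)
  n_keep <- max(1L, round(coverage * nrow(ions)))
  keep <- if (n_keep >= nrow(ions)) seq_len(nrow(ions))
          else sort(sample.int(nrow(ions), n_keep))
  peaks <- ions$mz[keep]
  if (noise_peaks > 0) {
    lo <- min(ions$mz) * 0.5
    hi <- max(ions$mz) * 1.1
    peaks <- c(peaks, stats::runif(noise_peaks, lo, hi))
  }
  sort(peaks)
}
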