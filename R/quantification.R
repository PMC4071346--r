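# Identification-directed two-pass feature extraction: wide-tolerance tagging
# with strict envelope fits, LOESS m/z and RT calibration, narrowed-tolerance
# re-tagging with relaxed fits, abundance extraction and median normalization.

#' Matching configuration for two-pass feature extraction
#'
#' @param mz_tol_ppm pass-1 m/z tolerance (ppm).
#' @param rt_tol_min pass-1 retention-time tolerance (min).
#' @param env_min_pass1 pass-1 (strict) minimum envelope cosine score.
#' @param env_min_pass2 pass-2 (relaxed) minimum envelope cosine score.
#' @param pass2_multiplier fixed narrowing factor applied to the pass-1
#'   tolerances when \code{adaptive = FALSE}.
#' @param adaptive derive the pass-2 tolerances per sample as
#'   max(floor, 3 * MAD of pass-1 calibrated residuals), capped at the pass-1
#'   tolerance.
#' @param mz_floor_ppm,rt_floor_min floors for the adaptive pass-2 tolerances.
#' @param loess_span LOESS span for the calibration fits.
#' @param sum_charges sum abundances over matched charge states (otherwise
#'   the most intense charge only).
#' @return a list of class \code{"match_config"}.
#' @export
match_config <- function(mz_tol_ppm = 10, rt_tol_min = 3,
                         env_min_pass1 = 0.95, env_min_pass2 = 0.80,
                         pass2_multiplier = 0.5, adaptive = TRUE,
                         mz_floor_ppm = 2, rt_floor_min = 0.3,
                         loess_span = 0.4, sum_charges = TRUE) {
  stopifnot(mz_tol_ppm > 0, rt_tol_min > 0,
            env_min_pass2 <= env_min_pass1,
            pass2_multiplier > 0, pass2_multiplier <= 1)
  structure(list(mz_tol_ppm = mz_tol_ppm, rt_tol_min = rt_tol_min,
                 env_min_pass1 = env_min_pass1, env_min_pass2 = env_min_pass2,
                 pass2_multiplier = pass2_multiplier, adaptive = adaptive,
                 mz_floor_ppm = mz_floor_ppm, rt_floor_min = rt_floor_min,
                 loess_span = loess_span, sum_charges = sum_charges),
            class = "match_config")
}

#' Build the identification-directed target list
#'
#' Expands a modified-peptide panel into one row per (peptide, charge) with
#' the predicted m/z and retention time used to tag features.
#'
#' @param panel list of panel entries (see \code{\link{default_panel}}).
#' @param ref_rt named numeric vector of predicted retention times per
#'   \code{peptide_id}.
#' @param charges charge states to search.
#' @return data frame with columns \code{peptide_id}, \code{charge},
#'   \code{mz_pred}, \code{rt_pred} and a list-column \code{envelope} of
#'   theoretical relative abundances.
#' @export
build_id_list <- function(panel, ref_rt, charges = 1:3) {
  meta <- panel_meta(panel)
  envs <- lapply(panel, function(p) peptide_envelope(p$peptide)$abundances)
  out <- do.call(rbind, lapply(seq_len(nrow(meta)), function(i) {
    data.frame(peptide_id = meta$peptide_id[i], charge = charges,
               mz_pred = vapply(charges, function(z) {
                 peptide_mz(meta$mass[i], z)
               }, numeric(1)),
               rt_pred = unname(ref_rt[meta$peptide_id[i]]),
               envelope = I(rep(list(envs[[i]]), length(charges))),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Tag features in one LC-MS map against a target list (one pass)
#'
#' Each (peptide, charge) is matched to at most one feature: candidates must
#' lie within the m/z and RT tolerance windows and reach the minimum envelope
#' cosine score; ties are broken by the smallest normalized distance
#' sqrt((dmz/tol_mz)^2 + (drt/tol_rt)^2).
#'
#' @param ids target list from \code{\link{build_id_list}}.
#' @param map feature data frame (\code{mz}, \code{rt}, \code{intensity},
#'   list-column \code{envelope}).
#' @param mz_tol_ppm,rt_tol_min tolerance windows.
#' @param env_min minimum envelope cosine score.
#' @return data frame of tagged features: \code{peptide_id}, \code{charge},
#'   \code{feature_idx}, \code{mz_dev_ppm}, \code{rt_dev_min},
#'   \code{env_score}, \code{intensity}; unmatched ids are absent.
#' @export
match_pass <- function(ids, map, mz_tol_ppm, rt_tol_min, env_min) {
  n_ids <- nrow(ids)
  if (n_ids == 0) stop("empty identification list")
  hit <- integer(n_ids)
  hit_dmz <- numeric(n_ids); hit_drt <- numeric(n_ids)
  hit_env <- numeric(n_ids)
  if (nrow(map) > 0) {
    ord <- order(map$mz)
    mz_sorted <- map$mz[ord]
    for (k in seq_len(n_ids)) {
      tol_da <- mz_tol_ppm * 1e-6 * ids$mz_pred[k]
      lo <- findInterval(ids$mz_pred[k] - tol_da, mz_sorted) + 1L
      hi <- findInterval(ids$mz_pred[k] + tol_da, mz_sorted)
      if (hi < lo) next
      cand <- ord[lo:hi]
      drt <- map$rt[cand] - ids$rt_pred[k]
      cand <- cand[abs(drt) <= rt_tol_min]
      if (length(cand) == 0) next
      scores <- vapply(cand, function(ci) {
        envelope_similarity(ids$envelope[[k]], map$envelope[[ci]])
      }, numeric(1))
      cand <- cand[scores >= env_min]
      scores <- scores[scores >= env_min]
      if (length(cand) == 0) next
      dmz_ppm <- (map$mz[cand] - ids$mz_pred[k]) / ids$mz_pred[k] * 1e6
      drt <- map$rt[cand] - ids$rt_pred[k]
      d <- sqrt((dmz_ppm / mz_tol_ppm)^2 + (drt / rt_tol_min)^2)
      best <- which.min(d)
      hit[k] <- cand[best]
      hit_dmz[k] <- dmz_ppm[best]; hit_drt[k] <- drt[best]
      hit_env[k] <- scores[best]
    }
  }
  m <- which(hit > 0)
  data.frame(
    peptide_id = ids$peptide_id[m], charge = ids$charge[m],
    feature_idx = hit[m], mz_dev_ppm = hit_dmz[m], rt_dev_min = hit_drt[m],
    env_score = hit_env[m], intensity = map$intensity[hit[m]],
    stringsAsFactors = FALSE
  )
}

#' Fit a nonlinear calibration function to observed deviations
#'
#' Locally weighted linear regression (LOESS, tricube weights, robustifying
#' iterations) of deviation against coordinate. The returned function gives
#' the expected deviation at a coordinate; calibration is applied by
#' subtracting it. With fewer than \code{max(6, span * n)} points the fit
#' falls back to a global median offset with a warning.
#'
#' @param coordinate numeric vector (m/z or RT of the matched features).
#' @param deviation numeric vector of observed deviations.
#' @param span LOESS span.
#' @return a function \code{f(x)} returning the fitted deviation (predictions
#'   outside the fitted range are clamped to the range edges).
#' @export
fit_calibration <- function(coordinate, deviation, span = 0.4) {
  stopifnot(length(coordinate) == length(deviation))
  n <- length(coordinate)
  if (n < max(6, ceiling(span * n))) {
    offset <- if (n > 0) stats::median(deviation) else 0
    warning("too few points for LOESS calibration (n = ", n,
            "); falling back to a global median offset")
    return(function(x) rep(offset, length(x)))
  }
  # a (near-)constant deviation defeats the robustness reweighting (MAD = 0);
  # return the constant directly
  med <- stats::median(deviation)
  if (max(abs(deviation - med)) < 1e-9 * max(1, abs(med))) {
    return(function(x) rep(med, length(x)))
  }
  # locally quadratic: a locally linear smoother leaves several percent of
  # residual bias on curvature-dominated drifts at any usable span
  fit <- try(stats::loess(deviation ~ coordinate,
                          data = data.frame(coordinate = coordinate,
                                            deviation = deviation),
                          span = span, degree = 2, family = "symmetric",
                          control = stats::loess.control(surface = "direct",
                                                         iterations = 3)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    fit <- try(stats::loess(deviation ~ coordinate,
                            data = data.frame(coordinate = coordinate,
                                              deviation = deviation),
                            span = span, degree = 1, family = "gaussian",
                            control = stats::loess.control(surface = "direct")),
               silent = TRUE)
  }
  if (inherits(fit, "try-error")) {
    warning("LOESS calibration failed; falling back to a global median offset")
    return(function(x) rep(med, length(x)))
  }
  lo <- min(coordinate); hi <- max(coordinate)
  function(x) {
    xc <- pmin(pmax(x, lo), hi)
    as.numeric(stats::predict(fit, newdata = data.frame(coordinate = xc)))
  }
}

#' Two-pass identification-directed feature extraction
#'
#' Pass 1 tags features with wide tolerances and a strict envelope-fit
#' requirement; LOESS m/z (ppm vs m/z) and RT (min vs RT) calibration
#' functions are fitted to the pass-1 deviations and applied to the map; pass
#' 2 repeats the search with narrowed tolerances (adaptive per-sample:
#' max(floor, 3 * MAD of the calibrated pass-1 residuals), capped at the
#' pass-1 tolerance) and a relaxed envelope requirement. Peptides matched in
#' pass 1 but not re-matched in pass 2 retain their pass-1 match.
#'
#' @param ids target list from \code{\link{build_id_list}}.
#' @param map feature data frame for one sample.
#' @param config a \code{\link{match_config}}.
#' @return list with \code{tags} (tagged-feature data frame with a
#'   \code{pass} column), \code{calibration} (the fitted m/z and RT functions
#'   and the pass-2 tolerances) and \code{pass1} (the pass-1 tag set).
#' @export
two_pass_extract <- function(ids, map, config = match_config()) {
  p1 <- match_pass(ids, map, config$mz_tol_ppm, config$rt_tol_min,
                   config$env_min_pass1)
  if (nrow(p1) == 0) {
    warning("calibration not fitted: no pass-1 matches")
    p1$pass <- integer(0)
    return(list(tags = p1, calibration = NULL, pass1 = p1))
  }
  mz_obs <- map$mz[p1$feature_idx]
  rt_obs <- map$rt[p1$feature_idx]
  f_mz <- fit_calibration(mz_obs, p1$mz_dev_ppm, span = config$loess_span)
  f_rt <- fit_calibration(rt_obs, p1$rt_dev_min, span = config$loess_span)

  cal_map <- map
  cal_map$mz <- map$mz / (1 + f_mz(map$mz) * 1e-6)
  cal_map$rt <- map$rt - f_rt(map$rt)

  res_mz <- p1$mz_dev_ppm - f_mz(mz_obs)
  res_rt <- p1$rt_dev_min - f_rt(rt_obs)
  if (config$adaptive) {
    mz_tol2 <- min(config$mz_tol_ppm,
                   max(config$mz_floor_ppm, 3 * stats::mad(res_mz)))
    rt_tol2 <- min(config$rt_tol_min,
                   max(config$rt_floor_min, 3 * stats::mad(res_rt)))
  } else {
    mz_tol2 <- config$mz_tol_ppm * config$pass2_multiplier
    rt_tol2 <- config$rt_tol_min * config$pass2_multiplier
  }

  p2 <- match_pass(ids, cal_map, mz_tol2, rt_tol2, config$env_min_pass2)
  p2$pass <- rep(2L, nrow(p2))
  p1$pass <- rep(1L, nrow(p1))
  key2 <- paste(p2$peptide_id, p2$charge)
  key1 <- paste(p1$peptide_id, p1$charge)
  keep1 <- p1[!(key1 %in% key2), , drop = FALSE]
  tags <- rbind(p2, keep1)
  rownames(tags) <- NULL
  list(tags = tags,
       calibration = list(f_mz = f_mz, f_rt = f_rt,
                          mz_tol2 = mz_tol2, rt_tol2 = rt_tol2),
       pass1 = p1)
}

#' Fit the height of a 2-D elliptical Gaussian peak
#'
#' For profile-mode data: fits height, center, widths and a flat baseline to
#' a local (m/z, RT, intensity) neighborhood and returns the fitted height.
#' Falls back to the maximum raw intensity with a warning if the fit does not
#' converge to finite parameters.
#'
#' @param profile data frame with columns \code{mz}, \code{rt},
#'   \code{intensity}.
#' @return fitted peak height.
#' @export
fit_peak_height <- function(profile) {
  stopifnot(all(c("mz", "rt", "intensity") %in% names(profile)))
  i0 <- which.max(profile$intensity)
  start <- c(h = max(profile$intensity), mz0 = profile$mz[i0],
             rt0 = profile$rt[i0],
             lsz_mz = log(max(stats::sd(profile$mz), 1e-4)),
             lsz_rt = log(max(stats::sd(profile$rt), 1e-3)),
             base = min(profile$intensity))
  obj <- function(p) {
    mu <- p["base"] + p["h"] * exp(-0.5 * (
      ((profile$mz - p["mz0"]) / exp(p["lsz_mz"]))^2 +
      ((profile$rt - p["rt0"]) / exp(p["lsz_rt"]))^2))
    sum((profile$intensity - mu)^2)
  }
  fit <- try(stats::optim(start, obj, method = "BFGS",
                          control = list(maxit = 500)), silent = TRUE)
  if (inherits(fit, "try-error") || !all(is.finite(fit$par))) {
    warning("2-D peak fit failed; returning raw maximum intensity")
    return(max(profile$intensity))
  }
  unname(fit$par["h"])
}

#' Extract a per-peptide abundance from its tagged features
#'
#' For centroided maps the abundance of one charge state is the intensity of
#' the most prominent envelope peak (the stored feature intensity); the
#' peptide abundance is the sum over matched charge states, or the most
#' intense single charge when \code{sum_charges} is FALSE.
#'
#' @param tags tagged-feature data frame for one sample.
#' @param sum_charges sum over charges (default) or take the maximum.
#' @return named numeric vector of abundances per \code{peptide_id}.
#' @export
extract_abundance <- function(tags, sum_charges = TRUE) {
  if (nrow(tags) == 0) return(stats::setNames(numeric(0), character(0)))
  agg <- if (sum_charges) {
    tapply(tags$intensity, tags$peptide_id, sum)
  } else {
    tapply(tags$intensity, tags$peptide_id, max)
  }
  stats::setNames(as.numeric(agg), names(agg))
}

#' Median-normalize the abundances of one sample
#'
#' Every abundance is divided by the median of the detected (non-missing)
#' abundances of the sample, so the median of the normalized detected values
#' is 1.
#'
#' @param abundances numeric vector (may contain NA for missing peptides).
#' @return normalized vector; missing values stay missing.
#' @export
normalize_sample <- function(abundances) {
  detected <- abundances[is.finite(abundances)]
  if (length(detected) == 0) stop("all abundances missing")
  abundances / stats::median(detected)
}

#' Run two-pass extraction and normalization over a whole cohort
#'
#' @param panel modified-peptide panel.
#' @param maps named list of per-sample feature data frames.
#' @param ref_rt predicted retention times per peptide_id.
#' @param config a \code{\link{match_config}}.
#' @param charges charge states searched.
#' @return list with \code{abundance} (peptide x sample matrix of
#'   median-normalized abundances, NA where missing), \code{raw} (same before
#'   normalization), \code{tags} (per-sample tag sets) and
#'   \code{calibration} (per-sample calibration info).
#' @export
quantify_cohort <- function(panel, maps, ref_rt, config = match_config(),
                            charges = 1:3) {
  ids <- build_id_list(panel, ref_rt, charges = charges)
  meta <- panel_meta(panel)
  raw <- matrix(NA_real_, nrow(meta), length(maps),
                dimnames = list(meta$peptide_id, names(maps)))
  tags_by_sample <- vector("list", length(maps))
  names(tags_by_sample) <- names(maps)
  cal_by_sample <- vector("list", length(maps))
  names(cal_by_sample) <- names(maps)
  for (s in names(maps)) {
    res <- two_pass_extract(ids, maps[[s]], config)
    tags_by_sample[[s]] <- res$tags
    cal_by_sample[[s]] <- res$calibration
    ab <- extract_abundance(res$tags, sum_charges = config$sum_charges)
    raw[names(ab), s] <- ab
  }
  norm <- apply(raw, 2, normalize_sample)
  dimnames(norm) <- dimnames(raw)
  list(abundance = norm, raw = raw, tags = tags_by_sample,
       calibration = cal_by_sample)
}
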