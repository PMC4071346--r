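# Site-level modification intensities and paired differential statistics:
# rescale-and-median aggregation of single-modified peptides, a sign-flip
# resampling paired-t test, Wilcoxon signed-rank, and labelling-index
# summaries.

#' Site modification intensity from single-modified peptide abundances
#'
#' Contributing peptides are the single-modified peptides covering the site
#' with the given modification type. Each contributing peptide is rescaled to
#' a common level: with r_p the median of peptide p's abundances over the
#' samples where it was detected and L the median of the r_p over peptides,
#' abundances are multiplied by L / r_p. The per-sample intensity is the
#' median over contributing peptides of the rescaled abundances (over the
#' peptides detected in that sample).
#'
#' @param abundance matrix peptide_id x sample of normalized abundances (NA =
#'   missing).
#' @param peptide_ids character vector naming the contributing peptides
#'   (rows of \code{abundance}).
#' @return named numeric vector of per-sample intensities (NA where no
#'   contributing peptide was detected), or NULL if there are no contributing
#'   peptides with at least one quantified sample.
#' @export
site_modification_intensity <- function(abundance, peptide_ids) {
  peptide_ids <- intersect(peptide_ids, rownames(abundance))
  sub <- abundance[peptide_ids, , drop = FALSE]
  sub <- sub[rowSums(is.finite(sub)) > 0, , drop = FALSE]
  if (nrow(sub) == 0) return(NULL)
  r <- apply(sub, 1, function(x) stats::median(x[is.finite(x)]))
  L <- stats::median(r)
  rescaled <- sub * (L / r)
  out <- apply(rescaled, 2, function(x) {
    if (any(is.finite(x))) stats::median(x[is.finite(x)]) else NA_real_
  })
  out
}

#' Build the site intensity matrix for a cohort
#'
#' Aggregates a peptide abundance matrix into one intensity row per
#' (histone, site, modification type), using only single-modified peptides.
#'
#' @param abundance peptide_id x sample matrix of normalized abundances.
#' @param meta peptide metadata (\code{\link{panel_meta}}-style data frame
#'   with \code{peptide_id}, \code{histone}, \code{site}, \code{mod},
#'   \code{n_var_mods}).
#' @param samples sample table (\code{sample_id}, \code{pair}, \code{group}).
#' @return long-format data frame: \code{histone}, \code{site}, \code{mod},
#'   \code{sample_id}, \code{pair}, \code{group}, \code{intensity},
#'   \code{n_peptides}.
#' @export
site_intensity_matrix <- function(abundance, meta, samples) {
  meta <- meta[meta$n_var_mods == 1L & !is.na(meta$site) &
                 meta$mod != "none", , drop = FALSE]
  keys <- unique(meta[, c("histone", "site", "mod")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- meta$histone == keys$histone[i] & meta$site == keys$site[i] &
      meta$mod == keys$mod[i]
    ids <- meta$peptide_id[sel]
    intensity <- site_modification_intensity(abundance, ids)
    if (is.null(intensity)) next
    rows[[length(rows) + 1L]] <- data.frame(
      histone = keys$histone[i], site = keys$site[i], mod = keys$mod[i],
      sample_id = samples$sample_id, pair = samples$pair,
      group = samples$group,
      intensity = unname(intensity[samples$sample_id]),
      n_peptides = length(ids), stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    return(data.frame(histone = character(0), site = character(0),
                      mod = character(0), sample_id = character(0),
                      pair = integer(0), group = character(0),
                      intensity = numeric(0), n_peptides = integer(0)))
  }
  do.call(rbind, rows)
}

#' Sign-flip resampling paired-t test
#'
#' The observed statistic is t = mean(d) / (sd(d) / sqrt(n)) on the paired
#' differences d. The null distribution is generated by flipping the signs of
#' the differences: exhaustively over all 2^n assignments when 2^n <=
#' \code{exhaustive_limit}, otherwise by Monte-Carlo sampling. The two-sided
#' p-value is the exact proportion of |t*| >= |t| for the exhaustive null and
#' (count + 1) / (N + 1) for Monte-Carlo.
#'
#' @param x paired differences, or the first member of each pair if \code{y}
#'   is given.
#' @param y optional second member of each pair (d = x - y).
#' @param n_resamples Monte-Carlo resamples when exhaustive enumeration is
#'   not used.
#' @param seed optional seed for the Monte-Carlo draw.
#' @param exhaustive_limit largest 2^n for which all sign assignments are
#'   enumerated (default 65536, i.e. up to n = 16 pairs).
#' @return list with \code{statistic} (observed t), \code{p_value},
#'   \code{n} (pairs used) and \code{method} ("exhaustive" or "monte-carlo").
#' @export
resampling_paired_t <- function(x, y = NULL, n_resamples = 10000L,
                                seed = NULL, exhaustive_limit = 65536) {
  d <- if (is.null(y)) x else x - y
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 3) stop("need at least 3 complete pairs")
  if (all(d == 0)) {
    return(list(statistic = 0, p_value = 1, n = n, method = "degenerate"))
  }
  t_stat <- function(m, ss) {
    # sd from the sign-flip-invariant sum of squares: var = (ss - n m^2)/(n-1)
    v <- (ss - n * m^2) / (n - 1)
    ifelse(v <= 0, sign(m) * Inf, m / sqrt(v / n))
  }
  ss <- sum(d^2)
  t_obs <- t_stat(mean(d), ss)
  eps <- 1e-12 * max(1, abs(t_obs))
  if (2^n <= exhaustive_limit) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    m_star <- as.numeric(signs %*% d) / n
    t_star <- t_stat(m_star, ss)
    p <- mean(abs(t_star) >= abs(t_obs) - eps)
    method <- "exhaustive"
  } else {
    if (!is.null(seed)) set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_resamples * n, replace = TRUE),
                    n_resamples, n)
    m_star <- as.numeric(signs %*% d) / n
    t_star <- t_stat(m_star, ss)
    p <- (sum(abs(t_star) >= abs(t_obs) - eps) + 1) / (n_resamples + 1)
    method <- "monte-carlo"
  }
  list(statistic = t_obs, p_value = p, n = n, method = method)
}

#' Wilcoxon signed-rank test for paired values
#'
#' Zero differences are dropped; the exact distribution is used for n <= 20
#' without ties, the normal approximation with continuity correction
#' otherwise (the standard \code{stats::wilcox.test} behavior).
#'
#' @param x paired differences, or the first member if \code{y} is given.
#' @param y optional second member of each pair.
#' @param alternative test sidedness (default two-sided).
#' @return list with \code{statistic} (V, the positive-rank sum),
#'   \code{p_value} and \code{n} (non-zero differences used).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else x - y
  d <- d[is.finite(d)]
  nz <- d[d != 0]
  if (length(nz) == 0) {
    return(list(statistic = 0, p_value = 1, n = 0L))
  }
  res <- suppressWarnings(stats::wilcox.test(nz, alternative = alternative,
                                             mu = 0, exact = length(nz) <= 20,
                                             correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       n = length(nz))
}

#' Paired tumour-vs-normal differential table of site modification intensities
#'
#' Per site row: complete pairs are those with both tumour and normal
#' intensity present; the fold change is the ratio of means (tumour over
#' normal) across complete pairs; the p-value comes from the sign-flip
#' resampling paired-t test on the (by default natural-log) intensities.
#' Rows supported by fewer than \code{min_pairs} complete pairs are reported
#' separately as excluded. A Benjamini-Hochberg adjusted p-value is emitted
#' alongside but does not gate the \code{significant} flag.
#'
#' @param site_matrix long-format intensity table from
#'   \code{\link{site_intensity_matrix}}.
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @param min_pairs minimum complete pairs for a quantifiable site (default
#'   6, i.e. half of a 12-pair cohort).
#' @param log_scale test on log intensities (default) or the raw scale.
#' @param fc_method \code{"ratio_of_means"} (default) or
#'   \code{"mean_of_ratios"}.
#' @param n_resamples,seed forwarded to \code{\link{resampling_paired_t}}.
#' @return list with \code{table} (data frame sorted by p-value: histone,
#'   site, mod, n_pairs, fc, p_value, p_adj, significant) and \code{excluded}
#'   (data frame with a reason column).
#' @export
differential_table <- function(site_matrix, alpha = 0.05, min_pairs = 6L,
                               log_scale = TRUE,
                               fc_method = c("ratio_of_means",
                                             "mean_of_ratios"),
                               n_resamples = 10000L, seed = NULL) {
  fc_method <- match.arg(fc_method)
  keys <- unique(site_matrix[, c("histone", "site", "mod")])
  rows <- list(); excl <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- site_matrix[site_matrix$histone == keys$histone[i] &
                       site_matrix$site == keys$site[i] &
                       site_matrix$mod == keys$mod[i], , drop = FALSE]
    wide_t <- sub$intensity[sub$group == "tumour"][order(sub$pair[sub$group == "tumour"])]
    wide_n <- sub$intensity[sub$group == "normal"][order(sub$pair[sub$group == "normal"])]
    ok <- is.finite(wide_t) & is.finite(wide_n)
    n_ok <- sum(ok)
    if (n_ok < max(3L, min_pairs)) {
      excl[[length(excl) + 1L]] <- data.frame(
        histone = keys$histone[i], site = keys$site[i], mod = keys$mod[i],
        n_pairs = n_ok, reason = "insufficient pairs",
        stringsAsFactors = FALSE)
      next
    }
    tt <- wide_t[ok]; nn <- wide_n[ok]
    fc <- if (fc_method == "ratio_of_means") mean(tt) / mean(nn)
          else mean(tt / nn)
    d <- if (log_scale) log(tt) - log(nn) else tt - nn
    test <- resampling_paired_t(d, n_resamples = n_resamples, seed = seed)
    rows[[length(rows) + 1L]] <- data.frame(
      histone = keys$histone[i], site = keys$site[i], mod = keys$mod[i],
      n_pairs = n_ok, fc = fc, p_value = test$p_value,
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(histone = character(0), site = character(0),
               mod = character(0), n_pairs = integer(0), fc = numeric(0),
               p_value = numeric(0))
  if (nrow(tab) > 0) {
    tab$p_adj <- stats::p.adjust(tab$p_value, method = "BH")
    tab$significant <- tab$p_value <= alpha
    tab <- tab[order(tab$p_value), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab$p_adj <- numeric(0)
    tab$significant <- logical(0)
  }
  excluded <- if (length(excl) > 0) do.call(rbind, excl) else
    data.frame(histone = character(0), site = character(0),
               mod = character(0), n_pairs = integer(0),
               reason = character(0))
  list(table = tab, excluded = excluded)
}

#' Summarize a paired labelling-index table
#'
#' Arithmetic group means of the paired percentages and a paired two-sided
#' test of the difference (sign-flip resampling paired-t by default, Wilcoxon
#' signed-rank optionally).
#'
#' @param case,control paired percentage vectors (e.g. tumour and normal
#'   labelling indices).
#' @param test \code{"resampling"} (default) or \code{"wilcoxon"}.
#' @param n_resamples,seed forwarded to the resampling test.
#' @return list with \code{mean_case}, \code{mean_control}, \code{p_value},
#'   \code{n}.
#' @export
labelling_index_summary <- function(case, control,
                                    test = c("resampling", "wilcoxon"),
                                    n_resamples = 10000L, seed = NULL) {
  test <- match.arg(test)
  if (length(case) != length(control)) {
    stop("case and control must have the same length (paired design)")
  }
  d <- case - control
  p <- if (all(d == 0)) 1.0
       else if (test == "resampling") {
         resampling_paired_t(d, n_resamples = n_resamples, seed = seed)$p_value
       } else {
         wilcoxon_signed_rank(d)$p_value
       }
  list(mean_case = mean(case), mean_control = mean(control), p_value = p,
       n = length(case))
}

#' The H3K27ac immunohistochemistry labelling-index table
#'
#' Ten matched tumour/normal pairs of labelling indices (percentage of
#' immunopositive nuclei) bundled with the package as a worked example for
#' \code{\link{labelling_index_summary}}.
#'
#' @return data frame with columns \code{sample_id}, \code{crc},
#'   \code{normal}.
#' @export
h3k27ac_labelling_index <- function() {
  path <- system.file("extdata", "h3k27ac_labelling_index.tsv",
                      package = "histoneLFQ", mustWork = TRUE)
  utils::read.delim(path, colClasses = c("character", "numeric", "numeric"))
}
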