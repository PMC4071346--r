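# Confidence filtering of modified-peptide identifications: target-decoy
# q-values, binomial PTM site localization, artifact rejection rules and
# protein grouping.

#' Assign target-decoy q-values to peptide-spectrum matches
#'
#' PSMs are ranked by score (descending, ties sharing the worst rank); the
#' FDR at each score threshold is estimated as #decoys / max(1, #targets) at
#' or above the threshold, and target q-values are the running minimum of the
#' estimated FDR from the least significant rank upward, capped at 1. Decoys
#' receive q = 1. The estimator does not apply a +1 correction to the decoy
#' count; set \code{plus_one = TRUE} for the conservative variant.
#'
#' @param psms data frame with columns \code{score} (finite numeric) and
#'   \code{is_decoy} (logical); other columns are passed through.
#' @param plus_one add 1 to the decoy count (conservative estimator).
#' @return the input data frame with a \code{q_value} column, original order
#'   preserved.
#' @export
compute_qvalues <- function(psms, plus_one = FALSE) {
  stopifnot(is.data.frame(psms), all(c("score", "is_decoy") %in% names(psms)))
  if (!any(!psms$is_decoy)) stop("no target PSMs present")
  if (any(!is.finite(psms$score))) stop("PSM scores must be finite")
  ord <- order(psms$score, decreasing = TRUE)
  sc <- psms$score[ord]
  dec <- psms$is_decoy[ord]
  n_dec <- cumsum(dec)
  n_tgt <- cumsum(!dec)
  # ties share the worst (largest cumulative-count) rank
  r <- rle(sc)
  worst <- rep(cumsum(r$lengths), r$lengths)
  fdr <- pmin(1, (n_dec + as.integer(plus_one)) / pmax(1L, n_tgt))[worst]
  q <- rev(cummin(rev(fdr)))
  q[dec] <- 1
  out <- psms
  out$q_value <- NA_real_
  out$q_value[ord] <- q
  out
}

#' Localize a modification among positional isomers by binomial scoring
#'
#' For each candidate isomer the theoretical singly charged b/y ions are
#' matched against the spectrum within \code{tolerance}; each isomer is scored
#' by the binomial tail probability of observing at least that many matches
#' out of its theoretical ions under a uniform per-peak chance match
#' probability p = (#peaks * 2 * tolerance) / spectrum m/z span. Isomer
#' probabilities are the normalized reciprocals of those tail p-values.
#'
#' @param isomers list of \code{modified_peptide} positional isomers
#'   (same sequence, same modification, different site).
#' @param spectrum numeric vector of fragment peak m/z values.
#' @param tolerance fragment match tolerance in Da (default 0.02).
#' @param registry modification registry.
#' @return a list of class \code{"site_localization"}: \code{sites} (the
#'   variable-modification position of each isomer), \code{probabilities}
#'   (summing to 1), \code{best_site}, \code{best_probability},
#'   \code{matches} (matched ion counts).
#' @export
localize_site <- function(isomers, spectrum, tolerance = 0.02,
                          registry = default_modifications()) {
  stopifnot(length(isomers) >= 1)
  if (length(spectrum) == 0) stop("empty fragment spectrum")
  span <- diff(range(spectrum))
  if (span <= 0) span <- max(spectrum)  # single-peak spectrum
  p_match <- min(0.999, length(spectrum) * 2 * tolerance / span)
  scores <- vapply(isomers, function(iso) {
    ions <- fragment_ions(iso, registry = registry)
    if (nrow(ions) == 0) stop("peptide has no theoretical fragment ions")
    k <- sum(vapply(ions$mz, function(m) any(abs(spectrum - m) <= tolerance),
                    logical(1)))
    n <- nrow(ions)
    stats::pbinom(k - 1L, n, p_match, lower.tail = FALSE)  # P(X >= k)
  }, numeric(1))
  sites <- vapply(isomers, function(iso) {
    var_mods <- iso$mods[!vapply(iso$mods$name, function(nm) {
      isTRUE(registry[[nm]]$fixed)
    }, logical(1)), , drop = FALSE]
    if (nrow(var_mods) > 0) var_mods$pos[1] else NA_integer_
  }, integer(1))
  w <- 1 / pmax(scores, .Machine$double.xmin)
  prob <- w / sum(w)
  best <- which.max(prob)
  structure(list(sites = sites, probabilities = prob,
                 best_site = sites[best], best_probability = prob[best],
                 tail_pvalues = scores,
                 matches = NULL),
            class = "site_localization")
}

#' Reject likely artifact modifications
#'
#' A peptide is rejected when (a) a mono-, di- or tri-methylated lysine sits
#' on its C-terminal residue, (b) a methylated lysine co-occurs with any
#' aspartate or glutamate in the peptide (possible methyl-esterification
#' artifact), or (c) a deamidated arginine sits on the C-terminal residue
#' (tryptic cleavage after a deamidated arginine is highly unlikely).
#'
#' @param peptides list of \code{modified_peptide} objects.
#' @return list with \code{retained} (list of peptides) and \code{rejected}
#'   (data frame with columns \code{sequence}, \code{mods}, \code{reason};
#'   reasons are \code{cterm_methyl_k}, \code{acidic_context_methyl},
#'   \code{cterm_deamidated_r}).
#' @export
filter_artifacts <- function(peptides) {
  methyl_k <- c("Methyl (K)", "Dimethyl (K)", "Trimethyl (K)")
  reasons <- vapply(peptides, function(p) {
    n <- nchar(p$sequence)
    m <- p$mods
    has_acidic <- grepl("[DE]", p$sequence)
    if (any(m$name %in% methyl_k & m$pos == n)) return("cterm_methyl_k")
    if (has_acidic && any(m$name %in% methyl_k)) return("acidic_context_methyl")
    if (any(m$name == "Deamidated (R)" & m$pos == n)) return("cterm_deamidated_r")
    ""
  }, character(1))
  rejected_idx <- which(reasons != "")
  rejected <- data.frame(
    sequence = vapply(peptides[rejected_idx], `[[`, character(1), "sequence"),
    mods = vapply(peptides[rejected_idx], function(p) {
      paste(sprintf("%s@%d", p$mods$name, p$mods$pos), collapse = ";")
    }, character(1)),
    reason = reasons[rejected_idx],
    stringsAsFactors = FALSE
  )
  list(retained = peptides[reasons == ""], rejected = rejected)
}

#' Group proteins by shared peptide evidence
#'
#' Proteins supported by fewer than two peptides are dropped; a protein whose
#' peptide set is a strict subset of another's is dropped; proteins matching
#' exactly the same peptide set are merged into one cluster.
#'
#' @param incidence named list: protein id -> character vector of peptide ids.
#' @return list of clusters, each a list with \code{members} (protein ids,
#'   sorted), \code{peptides} (sorted peptide ids) and \code{representative}
#'   (first member alphabetically). Clusters are sorted by representative.
#' @export
group_proteins <- function(incidence) {
  if (length(incidence) == 0) stop("empty protein-peptide incidence map")
  sets <- lapply(incidence, function(x) sort(unique(x)))
  keep <- names(sets)[lengths(sets) >= 2]
  sets <- sets[keep]
  if (length(sets) == 0) return(list())
  # drop strict subsets
  is_subset <- vapply(names(sets), function(a) {
    any(vapply(names(sets), function(b) {
      if (a == b) return(FALSE)
      all(sets[[a]] %in% sets[[b]]) && length(sets[[a]]) < length(sets[[b]])
    }, logical(1)))
  }, logical(1))
  sets <- sets[!is_subset]
  key <- vapply(sets, paste, character(1), collapse = "\x1f")
  clusters <- lapply(split(names(sets), key), function(members) {
    members <- sort(members)
    list(members = members, peptides = sets[[members[1]]],
         representative = members[1])
  })
  clusters <- unname(clusters)
  clusters[order(vapply(clusters, `[[`, character(1), "representative"))]
}
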