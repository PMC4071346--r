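# Human core histone sequences (mature proteins, initiator methionine
# removed, matching the usual histone site nomenclature where H3 "K27" is
# residue 27 of the mature chain) and the default modified-peptide panel.

#' Mature sequences of the four human core histones
#'
#' H3 (H3.1), H4, H2A (type 1) and H2B (type 1), without the initiator
#' methionine, so that site labels such as "K27" use the conventional
#' mature-protein numbering.
#'
#' @return named character vector of sequences.
#' @export
core_histones <- function() {
  c(
    H3  = paste0("ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRPGTVALREIRRYQ",
                 "KSTELLIRKLPFQRLVREIAQDFKTDLRFQSSAVMALQEACEAYLVGLFEDTNLC",
                 "AIHAKRVTIMPKDIQLARRIRGERA"),
    H4  = paste0("SGRGKGGKGLGKGGAKRHRKVLRDNIQGITKPAIRRLARRGGVKRISGLIYEETR",
                 "GVLKVFLENVIRDAVTYTEHAKRKTVTAMDVVYALKRQGRTLYGFGG"),
    H2A = paste0("SGRGKQGGKARAKAKTRSSRAGLQFPVGRVHRLLRKGNYAERVGAGAPVYLAAVL",
                 "EYLTAEILELAGNAARDNKKTRIIPRHLQLAIRNDEELNKLLGKVTIAQGGVLPN",
                 "IQAVLLPKKTESHHKAKGK"),
    H2B = paste0("PEPAKSAPAPKKGSKKAVTKAQKKDGKKRKRSRKESYSVYVYKVLKQVHPDTGIS",
                 "SKAMGIMNSFVNDIFERIAGEASRLAHYNKRSTITSREIQTAVRLLLPGELAKHA",
                 "VSEGTKAVTKYTSSK")
  )
}

# one panel entry: a single-modified tryptic peptide covering one site, or an
# unmodified background peptide (mod = "none")
.panel_entry <- function(histone, start, end, pos_in_pep = NA_integer_,
                         mod = "none", registry = default_modifications()) {
  seqs <- core_histones()
  pep_seq <- substr(seqs[[histone]], start, end)
  if (identical(mod, "none")) {
    pep <- modified_peptide(pep_seq, protein_id = histone, start = start,
                            registry = registry)
    return(list(peptide = pep, histone = histone, site = NA_character_,
                mod = "none",
                peptide_id = sprintf("%s_%d-%d", histone, start, end)))
  }
  residue <- substr(pep_seq, pos_in_pep, pos_in_pep)
  site <- paste0(residue, start + pos_in_pep - 1L)
  pep <- modified_peptide(pep_seq,
                          mods = data.frame(pos = pos_in_pep, name = mod,
                                            stringsAsFactors = FALSE),
                          protein_id = histone, start = start,
                          registry = registry)
  list(peptide = pep, histone = histone, site = site, mod = mod,
       peptide_id = sprintf("%s_%d-%d_%s@%d", histone, start, end, mod,
                            pos_in_pep))
}

# unmodified tryptic background peptides of the four core histones; in real
# maps the unmodified peptidome dominates the per-sample normalization median
.background_peptides <- function(registry = default_modifications()) {
  seqs <- core_histones()
  cfg <- digest_config(enzyme = "tryptic", missed_cleavages = 1L,
                       min_length = 6L, max_length = 30L)
  out <- list()
  seen <- character(0)
  for (h in names(seqs)) {
    d <- digest(seqs[[h]], cfg)
    for (i in seq_len(nrow(d))) {
      if (d$sequence[i] %in% seen) next
      seen <- c(seen, d$sequence[i])
      out[[length(out) + 1L]] <- .panel_entry(h, d$start[i], d$end[i],
                                             registry = registry)
    }
  }
  out
}

#' Default modified-peptide panel for synthetic cohorts
#'
#' Single-modified tryptic peptides (up to one missed cleavage) covering PTM
#' sites across the four core histones. The four sites reported as
#' differential in colorectal tumours — H3 K27me3, H3 K27ac, H2B S64ph and
#' H3 K79ac — are each present, H3 K27 with two supporting peptides (with and
#' without a missed cleavage) so that the rescale-and-median site aggregation
#' is exercised; the remaining ~27 site/modification rows act as null
#' background.
#'
#' In addition, the unmodified tryptic peptides of the four histones (up to
#' one missed cleavage, 6-30 residues) are included as an unmodified
#' background: real feature maps are dominated by the unmodified peptidome,
#' and the per-sample median used for normalization is computed over all
#' detected peptides.
#'
#' @param registry modification registry.
#' @param background include the unmodified background peptides (default
#'   TRUE).
#' @return list of panel entries; each has \code{peptide}
#'   (\code{modified_peptide}), \code{histone}, \code{site} (NA for
#'   unmodified background), \code{mod} ("none" for background),
#'   \code{peptide_id}.
#' @export
default_panel <- function(registry = default_modifications(),
                          background = TRUE) {
  if (missing(registry)) {  # cache the default-registry panel
    key <- if (background) "bg" else "nobg"
    cached <- .panel_cache[[key]]
    if (!is.null(cached)) return(cached)
  }
  e <- function(...) .panel_entry(..., registry = registry)
  modified <- list(
    # --- differential sites ---
    e("H3", 27, 36, 1, "Trimethyl (K)"),    # H3 K27me3 (KSAPATGGVK)
    e("H3", 27, 40, 1, "Trimethyl (K)"),    # missed-cleavage support
    e("H3", 27, 36, 1, "Acetyl (K)"),       # H3 K27ac
    e("H3", 27, 40, 1, "Acetyl (K)"),       # missed-cleavage support
    e("H2B", 58, 72, 7, "Phospho (ST)"),    # H2B S64ph (AMGIMNSFVNDIFER)
    e("H3", 73, 83, 7, "Acetyl (K)"),       # H3 K79ac (EIAQDFKTDLR)
    # --- null background: H3 ---
    e("H3", 3, 8, 2, "Acetyl (K)"),         # K4ac
    e("H3", 9, 17, 1, "Acetyl (K)"),        # K9ac
    e("H3", 9, 17, 6, "Acetyl (K)"),        # K14ac
    e("H3", 18, 26, 1, "Acetyl (K)"),       # K18ac
    e("H3", 18, 26, 6, "Acetyl (K)"),       # K23ac
    e("H3", 41, 49, 5, "Phospho (ST)"),     # T45ph
    e("H3", 54, 63, 3, "Acetyl (K)"),       # K56ac
    e("H3", 64, 69, 1, "Methyl (K)"),       # K64me (no acidic residues)
    e("H3", 84, 115, 7, "Oxidation (M)"),   # M90ox
    e("H3", 117, 128, 4, "Oxidation (M)"),  # M120ox
    e("H3", 117, 128, 6, "Acetyl (K)"),     # K122ac
    # --- null background: H4 ---
    e("H4", 24, 35, 8, "Acetyl (K)"),       # K31ac
    e("H4", 24, 35, 7, "Phospho (ST)"),     # T30ph
    e("H4", 46, 55, 2, "Phospho (ST)"),     # S47ph
    e("H4", 56, 67, 4, "Acetyl (K)"),       # K59ac
    e("H4", 79, 91, 1, "Acetyl (K)"),       # K79ac (H4)
    e("H4", 79, 91, 6, "Oxidation (M)"),    # M84ox
    e("H4", 79, 91, 2, "Phospho (ST)"),     # T80ph
    # --- null background: H2A ---
    e("H2A", 12, 17, 2, "Acetyl (K)"),      # K13ac
    e("H2A", 89, 99, 7, "Acetyl (K)"),      # K95ac
    e("H2A", 100, 118, 2, "Phospho (ST)"),  # T101ph
    # --- null background: H2B ---
    e("H2B", 58, 72, 2, "Oxidation (M)"),   # M59ox
    e("H2B", 73, 79, 6, "Phospho (ST)"),    # S78ph
    e("H2B", 87, 92, 1, "Phospho (ST)"),    # S87ph
    e("H2B", 100, 108, 9, "Acetyl (K)"),    # K108ac
    e("H2B", 109, 116, 4, "Phospho (ST)"),  # S112ph
    e("H2B", 117, 125, 4, "Acetyl (K)")     # K120ac
  )
  out <- if (background) c(modified, .background_peptides(registry))
         else modified
  if (missing(registry)) {
    .panel_cache[[if (background) "bg" else "nobg"]] <- out
  }
  out
}

.panel_cache <- new.env(parent = emptyenv())

#' Panel metadata as a data frame
#'
#' @param panel a panel as returned by \code{\link{default_panel}}.
#' @return data frame with one row per panel peptide: \code{peptide_id},
#'   \code{histone}, \code{site}, \code{mod}, \code{sequence}, \code{start},
#'   \code{mass}, \code{n_var_mods}.
#' @export
panel_meta <- function(panel) {
  data.frame(
    peptide_id = vapply(panel, `[[`, character(1), "peptide_id"),
    histone = vapply(panel, `[[`, character(1), "histone"),
    site = vapply(panel, `[[`, character(1), "site"),
    mod = vapply(panel, `[[`, character(1), "mod"),
    sequence = vapply(panel, function(p) p$peptide$sequence, character(1)),
    start = vapply(panel, function(p) p$peptide$start, integer(1)),
    mass = vapply(panel, function(p) p$peptide$mass, numeric(1)),
    n_var_mods = vapply(panel, function(p) {
      if (identical(p$mod, "none")) 0L else 1L
    }, integer(1)),
    stringsAsFactors = FALSE
  )
}
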