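# Modification registry and modified peptides.

#' Define a modification specification
#'
#' @param name modification name, e.g. \code{"Acetyl (K)"}.
#' @param targets string of 1-letter residue codes the modification may occupy
#'   (e.g. \code{"K"}, \code{"ST"}).
#' @param formula_add formula string of atoms added (may be \code{""}).
#' @param formula_remove formula string of atoms removed (may be \code{""}).
#' @param fixed logical; fixed modifications are applied unconditionally to
#'   every eligible residue.
#' @return a list of class \code{"modification_spec"} with the delta
#'   monoisotopic mass precomputed.
#' @export
modification_spec <- function(name, targets, formula_add, formula_remove = "",
                              fixed = FALSE) {
  add <- parse_formula(formula_add)
  rem <- parse_formula(formula_remove)
  delta <- monoisotopic_mass(add) - monoisotopic_mass(rem)
  structure(list(name = name, targets = strsplit(targets, "")[[1]],
                 formula_add = formula_add, formula_remove = formula_remove,
                 delta_mass = delta, fixed = fixed),
            class = "modification_spec")
}

#' The default histone-search modification registry
#'
#' Carbamidomethylation of cysteine as the fixed modification, and the
#' variable set used for histone PTM searches: acetylation and mono-, di-,
#' tri-methylation of lysine, mono- and di-methylation of arginine,
#' deamidation (citrullination) of arginine, phosphorylation of serine and
#' threonine, and oxidation of methionine. Deamidation is modelled as
#' \code{+O -NH} (delta +0.984016 Da).
#'
#' @return a named list of \code{modification_spec} objects.
#' @export
default_modifications <- function() {
  specs <- list(
    modification_spec("Carbamidomethyl (C)", "C",  "C2H3NO", fixed = TRUE),
    modification_spec("Acetyl (K)",          "K",  "C2H2O"),
    modification_spec("Methyl (K)",          "K",  "CH2"),
    modification_spec("Dimethyl (K)",        "K",  "C2H4"),
    modification_spec("Trimethyl (K)",       "K",  "C3H6"),
    modification_spec("Methyl (R)",          "R",  "CH2"),
    modification_spec("Dimethyl (R)",        "R",  "C2H4"),
    modification_spec("Deamidated (R)",      "R",  "O", "NH"),
    modification_spec("Phospho (ST)",        "ST", "HPO3"),
    modification_spec("Oxidation (M)",       "M",  "O")
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Write a modification registry to a plain-text key-value table
#'
#' @param registry a named list of \code{modification_spec}s.
#' @param path output path (tab-separated, one modification per row).
#' @export
write_modification_registry <- function(registry, path) {
  df <- data.frame(
    name = vapply(registry, `[[`, character(1), "name"),
    targets = vapply(registry, function(m) paste(m$targets, collapse = ""),
                     character(1)),
    formula_add = vapply(registry, `[[`, character(1), "formula_add"),
    formula_remove = vapply(registry, `[[`, character(1), "formula_remove"),
    delta_mass = sprintf("%.6f", vapply(registry, `[[`, numeric(1),
                                        "delta_mass")),
    fixed = vapply(registry, `[[`, logical(1), "fixed"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a modification registry written by \code{write_modification_registry}
#'
#' The stored delta mass is checked against the mass recomputed from the
#' formulas (tolerance 1e-5 Da).
#'
#' @param path path to the registry table.
#' @return a named list of \code{modification_spec}s.
#' @export
read_modification_registry <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  specs <- lapply(seq_len(nrow(df)), function(i) {
    m <- modification_spec(df$name[i], df$targets[i], df$formula_add[i],
                           df$formula_remove[i], df$fixed[i])
    if (abs(m$delta_mass - as.numeric(df$delta_mass[i])) > 1e-5) {
      stop("stored delta mass disagrees with formula for ", df$name[i])
    }
    m
  })
  names(specs) <- df$name
  specs
}

#' Construct a modified peptide
#'
#' @param sequence peptide sequence (1-letter codes).
#' @param mods data frame with columns \code{pos} (1-based position within the
#'   peptide) and \code{name} (registry modification name); may be empty.
#' @param protein_id parent protein identifier.
#' @param start 1-based start position of the peptide within the parent.
#' @param registry modification registry (default \code{default_modifications()}).
#' @param apply_fixed apply fixed modifications (carbamidomethyl-C) to every
#'   eligible residue not already modified; default TRUE.
#' @return a list of class \code{"modified_peptide"} with fields
#'   \code{sequence}, \code{protein_id}, \code{start}, \code{mods} and the
#'   precomputed \code{mass} (monoisotopic, Da).
#' @export
modified_peptide <- function(sequence, mods = NULL, protein_id = NA_character_,
                             start = NA_integer_,
                             registry = default_modifications(),
                             apply_fixed = TRUE) {
  if (nchar(sequence) == 0) stop("empty peptide sequence")
  if (is.null(mods)) {
    mods <- data.frame(pos = integer(0), name = character(0),
                       stringsAsFactors = FALSE)
  }
  mods <- mods[, c("pos", "name")]
  mods$pos <- as.integer(mods$pos)
  aa <- strsplit(sequence, "")[[1]]
  if (anyDuplicated(mods$pos)) stop("at most one modification per position")
  for (i in seq_len(nrow(mods))) {
    spec <- registry[[mods$name[i]]]
    if (is.null(spec)) stop("unknown modification: ", mods$name[i])
    p <- mods$pos[i]
    if (p < 1 || p > length(aa)) stop("modification position out of range: ", p)
    if (!(aa[p] %in% spec$targets)) {
      stop("modification ", mods$name[i], " not allowed on residue ", aa[p],
           " at position ", p)
    }
  }
  if (apply_fixed) {
    for (spec in registry[vapply(registry, `[[`, logical(1), "fixed")]) {
      eligible <- which(aa %in% spec$targets)
      eligible <- setdiff(eligible, mods$pos)
      if (length(eligible) > 0) {
        mods <- rbind(mods, data.frame(pos = eligible, name = spec$name,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  mods <- mods[order(mods$pos), , drop = FALSE]
  rownames(mods) <- NULL
  pep <- structure(list(sequence = sequence, protein_id = protein_id,
                        start = as.integer(start), mods = mods, mass = NA_real_),
                   class = "modified_peptide")
  pep$mass <- peptide_mass(pep, registry = registry)
  pep
}

#' Monoisotopic mass of a (modified) peptide
#'
#' Residue masses plus water plus the sum of modification deltas.
#'
#' @param peptide a \code{modified_peptide}, or a plain sequence string.
#' @param registry modification registry used to resolve modification names.
#' @return mass in Da.
#' @export
peptide_mass <- function(peptide, registry = default_modifications()) {
  if (is.character(peptide)) {
    return(monoisotopic_mass(peptide_composition(peptide)))
  }
  stopifnot(inherits(peptide, "modified_peptide"))
  m <- monoisotopic_mass(peptide_composition(peptide$sequence))
  for (nm in peptide$mods$name) {
    spec <- registry[[nm]]
    if (is.null(spec)) stop("unknown modification: ", nm)
    m <- m + spec$delta_mass
  }
  m
}

#' Elemental composition of a modified peptide (with modification deltas)
#'
#' @param peptide a \code{modified_peptide}.
#' @param registry modification registry.
#' @return a \code{composition}.
#' @export
modified_peptide_composition <- function(peptide,
                                         registry = default_modifications()) {
  stopifnot(inherits(peptide, "modified_peptide"))
  comp <- peptide_composition(peptide$sequence)
  for (nm in peptide$mods$name) {
    spec <- registry[[nm]]
    comp <- comp_add(comp, parse_formula(spec$formula_add))
    if (nchar(spec$formula_remove) > 0) {
      comp <- comp_subtract(comp, parse_formula(spec$formula_remove))
    }
  }
  comp
}

#' Theoretical isotopic envelope of a modified peptide (cached)
#'
#' @param peptide a \code{modified_peptide}.
#' @param registry modification registry.
#' @param floor envelope truncation floor.
#' @return an \code{isotope_envelope}.
#' @export
peptide_envelope <- function(peptide, registry = default_modifications(),
                             floor = 1e-3) {
  key <- paste(peptide$sequence,
               paste(peptide$mods$pos, peptide$mods$name, collapse = ","),
               floor, sep = "|")
  cached <- .peptide_env_cache[[key]]
  if (!is.null(cached)) return(cached)
  out <- isotope_distribution(modified_peptide_composition(peptide, registry),
                              floor = floor)
  .peptide_env_cache[[key]] <- out
  out
}

.peptide_env_cache <- new.env(parent = emptyenv())

#' m/z of a peptide ion at a given charge
#'
#' @param mass neutral monoisotopic mass (Da) or a \code{modified_peptide}.
#' @param charge positive integer charge state.
#' @return m/z in Thomson.
#' @export
peptide_mz <- function(mass, charge) {
  if (inherits(mass, "modified_peptide")) mass <- mass$mass
  stopifnot(charge >= 1)
  (mass + charge * PROTON_MASS) / charge
}

#' Singly charged b- and y-ion m/z values of a modified peptide
#'
#' Modification deltas are carried by the fragment containing the modified
#' residue.
#'
#' @param peptide a \code{modified_peptide}.
#' @param registry modification registry.
#' @return data frame with columns \code{ion} (e.g. "b3", "y5"), \code{type},
#'   \code{index}, \code{mz}.
#' @export
fragment_ions <- function(peptide, registry = default_modifications()) {
  aa <- strsplit(peptide$sequence, "")[[1]]
  n <- length(aa)
  res_mass <- vapply(aa, function(r) {
    monoisotopic_mass(parse_formula(.RESIDUE_FORMULA[[r]]))
  }, numeric(1))
  delta <- numeric(n)
  for (i in seq_len(nrow(peptide$mods))) {
    spec <- registry[[peptide$mods$name[i]]]
    delta[peptide$mods$pos[i]] <- delta[peptide$mods$pos[i]] + spec$delta_mass
  }
  res_mass <- res_mass + delta
  water <- monoisotopic_mass(parse_formula("H2O"))
  b_idx <- seq_len(n - 1)
  b_mz <- cumsum(res_mass)[b_idx] + PROTON_MASS
  # y_i contains the C-terminal i residues
  y_idx <- seq_len(n - 1)
  y_mz <- cumsum(rev(res_mass))[y_idx] + water + PROTON_MASS
  data.frame(
    ion = c(paste0("b", b_idx), paste0("y", y_idx)),
    type = rep(c("b", "y"), each = n - 1),
    index = c(b_idx, y_idx),
    mz = c(b_mz, y_mz),
    stringsAsFactors = FALSE
  )
}
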