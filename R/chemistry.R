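# Elemental data, compositions, monoisotopic masses and isotopic envelopes.
#
# Atomic masses are NIST/CODATA monoisotopic values; isotope abundances are
# IUPAC representative natural abundances. Only the elements occurring in
# peptides and the modification registry are carried (C, H, N, O, S, P).

# Per-element isotope tables: nucleon offset from the lightest isotope,
# exact mass, natural abundance. The lightest isotope comes first.
.ELEMENTS <- list(
  C = list(mass = c(12.0, 13.00335483778),
           offset = c(0L, 1L),
           abundance = c(0.9893, 0.0107)),
  H = list(mass = c(1.00782503207, 2.01410177785),
           offset = c(0L, 1L),
           abundance = c(0.999885, 0.000115)),
  N = list(mass = c(14.0030740048, 15.0001088989),
           offset = c(0L, 1L),
           abundance = c(0.99636, 0.00364)),
  O = list(mass = c(15.9949146196, 16.99913170, 17.99916107),
           offset = c(0L, 1L, 2L),
           abundance = c(0.99757, 0.00038, 0.00205)),
  S = list(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
           offset = c(0L, 1L, 2L, 4L),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  P = list(mass = 30.97376163,
           offset = 0L,
           abundance = 1.0)
)

#' Mass of a proton (Da)
#' @keywords internal
PROTON_MASS <- 1.00727646688

#' Average spacing between adjacent isotopologue peaks (Da), i.e. the
#' 13C - 12C mass difference used for envelope m/z spacing.
#' @keywords internal
NEUTRON_SPACING <- 1.00335483778

# Monoisotopic residue compositions of the 20 standard amino acids.
.RESIDUE_FORMULA <- c(
  G = "C2H3NO",   A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",   T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO",  N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3",  M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",   R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

#' Create an elemental composition
#'
#' An elemental composition is a named integer vector of non-negative atom
#' counts over the element symbols C, H, N, O, S, P.
#'
#' @param ... named atom counts, e.g. \code{composition(C = 2, H = 2, O = 1)}.
#' @return a named integer vector of class \code{"composition"}.
#' @examples
#' composition(C = 2, H = 2, O = 1)  # acetyl delta
#' @export
composition <- function(...) {
  counts <- c(...)
  if (length(counts) == 0) {
    x <- integer(0)
    names(x) <- character(0)
    class(x) <- "composition"
    return(x)
  }
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("all composition entries must be named by element symbol")
  }
  unknown <- setdiff(names(counts), names(.ELEMENTS))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(counts < 0)) stop("atom counts must be non-negative")
  if (any(counts != round(counts))) stop("atom counts must be integers")
  x <- as.integer(counts)
  names(x) <- names(counts)
  # collapse duplicated symbols
  x <- vapply(split(x, names(x)), sum, integer(1))
  x <- x[x > 0]
  class(x) <- "composition"
  x
}

#' Parse a molecular formula string into a composition
#'
#' @param formula a Hill-style formula such as \code{"C2H3NO"}; an empty
#'   string yields the empty composition.
#' @return a \code{composition}.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  if (nchar(formula) == 0) return(composition())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  syms <- sub("[0-9]*$", "", parts)
  cnts <- sub("^[A-Za-z]+", "", parts)
  cnts <- ifelse(cnts == "", 1L, as.integer(cnts))
  names(cnts) <- syms
  do.call(composition, as.list(cnts))
}

#' Add two compositions element-wise
#' @param a,b compositions.
#' @return a \code{composition}.
#' @export
comp_add <- function(a, b) {
  syms <- union(names(a), names(b))
  x <- vapply(syms, function(s) {
    sum(unclass(a)[s], unclass(b)[s], na.rm = TRUE)
  }, numeric(1))
  do.call(composition, as.list(x))
}

#' Subtract one composition from another
#'
#' Errors if any resulting count would be negative.
#' @param a,b compositions; returns \code{a - b}.
#' @return a \code{composition}.
#' @export
comp_subtract <- function(a, b) {
  syms <- union(names(a), names(b))
  av <- vapply(syms, function(s) sum(unclass(a)[s], na.rm = TRUE), numeric(1))
  bv <- vapply(syms, function(s) sum(unclass(b)[s], na.rm = TRUE), numeric(1))
  d <- av - bv
  if (any(d < 0)) {
    stop("composition subtraction would yield negative count for: ",
         paste(syms[d < 0], collapse = ", "))
  }
  do.call(composition, as.list(d))
}

#' Monoisotopic mass of an elemental composition
#'
#' Sum over elements of atom count times the mass of the lightest isotope.
#'
#' @param comp a \code{composition}.
#' @return mass in Da.
#' @examples
#' monoisotopic_mass(parse_formula("C2H2O"))  # 42.010565, the acetyl delta
#' @export
monoisotopic_mass <- function(comp) {
  if (length(comp) == 0) return(0.0)
  unknown <- setdiff(names(comp), names(.ELEMENTS))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  sum(vapply(names(comp), function(s) {
    unclass(comp)[[s]] * .ELEMENTS[[s]]$mass[1]
  }, numeric(1)))
}

#' Elemental composition of a peptide
#'
#' Residue compositions plus one water; fixed/variable modification deltas are
#' applied for a \code{modified_peptide} (see \code{\link{modified_peptide}}).
#'
#' @param sequence a string over the 20-letter amino acid alphabet.
#' @return a \code{composition} (residues + H2O).
#' @export
peptide_composition <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) == 0) stop("empty peptide sequence")
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, names(.RESIDUE_FORMULA))
  if (length(bad) > 0) {
    stop("non-standard residue(s): ", paste(unique(bad), collapse = ", "))
  }
  comp <- parse_formula("H2O")
  tab <- table(aa)
  for (r in names(tab)) {
    rc <- parse_formula(.RESIDUE_FORMULA[[r]])
    rc <- do.call(composition, as.list(unclass(rc) * as.integer(tab[[r]])))
    comp <- comp_add(comp, rc)
  }
  comp
}

# single-convolution helper on nucleon-offset grids
.convolve_dist <- function(a, b, maxlen = 64L) {
  n <- min(maxlen, length(a) + length(b) - 1L)
  out <- numeric(n)
  for (i in seq_along(a)) {
    jmax <- min(length(b), n - i + 1L)
    if (jmax >= 1) {
      idx <- i:(i + jmax - 1L)
      out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
    }
  }
  out
}

# distribution of n atoms of one element, by binary exponentiation
.element_power <- function(sym, n, maxlen = 64L) {
  el <- .ELEMENTS[[sym]]
  base <- numeric(max(el$offset) + 1L)
  base[el$offset + 1L] <- el$abundance
  result <- 1.0
  while (n > 0) {
    if (n %% 2 == 1) result <- .convolve_dist(result, base, maxlen)
    n <- n %/% 2
    if (n > 0) base <- .convolve_dist(base, base, maxlen)
  }
  result
}

#' Predict the isotopic envelope of a composition
#'
#' Isotopologue relative abundances are obtained by iterated convolution of
#' per-element natural isotope distributions on the nucleon-offset grid
#' (aggregated-isotope approximation), normalized so the most abundant peak
#' equals 1, and truncated where the relative abundance drops below
#' \code{floor}.
#'
#' @param comp a non-empty \code{composition}.
#' @param floor truncation threshold for trailing peaks, in (0, 1).
#' @return an object of class \code{"isotope_envelope"}: a list with
#'   \code{abundances} (A0..Ak, max = 1) and \code{spacing} (the Da spacing of
#'   adjacent isotopologues for a singly charged ion; divide by z for charge z).
#' @export
isotope_distribution <- function(comp, floor = 1e-3) {
  if (length(comp) == 0) stop("empty composition")
  if (!is.numeric(floor) || length(floor) != 1 || floor <= 0 || floor >= 1) {
    stop("floor must be a single number in (0, 1)")
  }
  key <- paste0(paste0(names(comp), unclass(comp), collapse = ""), "@", floor)
  cached <- .envelope_cache[[key]]
  if (!is.null(cached)) return(cached)
  dist <- 1.0
  for (s in names(comp)) {
    dist <- .convolve_dist(dist, .element_power(s, unclass(comp)[[s]]))
  }
  dist <- dist / max(dist)
  keep <- max(which(dist >= floor))
  out <- structure(list(abundances = dist[seq_len(keep)],
                        spacing = NEUTRON_SPACING),
                   class = "isotope_envelope")
  .envelope_cache[[key]] <- out
  out
}

# deterministic per-session cache (envelope prediction is pure)
.envelope_cache <- new.env(parent = emptyenv())

#' Cosine similarity between a theoretical envelope and observed peaks
#'
#' Vectors are aligned by isotopologue index, zero-padded to a common length,
#' and compared by the normalized dot product; the score is invariant to
#' positive scaling of either argument.
#'
#' @param theoretical an \code{isotope_envelope} or a numeric abundance vector.
#' @param observed numeric vector of observed peak intensities (A0 first).
#' @return similarity in [0, 1].
#' @export
envelope_similarity <- function(theoretical, observed) {
  th <- if (inherits(theoretical, "isotope_envelope")) theoretical$abundances
        else as.numeric(theoretical)
  ob <- as.numeric(observed)
  if (length(th) < 1 || length(ob) < 1) stop("need at least one peak in each")
  if (all(ob == 0)) stop("observed intensity vector is all zero")
  if (all(th == 0)) stop("theoretical abundance vector is all zero")
  n <- max(length(th), length(ob))
  th <- c(th, numeric(n - length(th)))
  ob <- c(ob, numeric(n - length(ob)))
  s <- sum(th * ob) / sqrt(sum(th^2) * sum(ob^2))
  min(max(s, 0), 1)
}
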