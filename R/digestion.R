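# In-silico proteolysis and enumeration of modified peptide forms.

#' Digestion configuration
#'
#' @param enzyme \code{"tryptic"} (cleave C-terminal to K/R unless followed by
#'   P) or \code{"semitryptic"} (every tryptic peptide plus all prefixes and
#'   suffixes retaining one tryptic terminus).
#' @param missed_cleavages maximum number of missed cleavage sites.
#' @param min_length,max_length peptide length bounds (residues).
#' @param max_var_mods maximum number of variable modifications per peptide.
#' @param max_forms combinatorial guard for \code{enumerate_modified_forms}.
#' @return a list of class \code{"digest_config"}.
#' @export
digest_config <- function(enzyme = c("tryptic", "semitryptic"),
                          missed_cleavages = 2L, min_length = 5L,
                          max_length = 35L, max_var_mods = 4L,
                          max_forms = 10000L) {
  enzyme <- match.arg(enzyme)
  stopifnot(missed_cleavages >= 0, min_length > 0, max_length >= min_length,
            max_var_mods >= 0)
  structure(list(enzyme = enzyme, missed_cleavages = as.integer(missed_cleavages),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 max_var_mods = as.integer(max_var_mods),
                 max_forms = as.integer(max_forms)),
            class = "digest_config")
}

#' Digest a protein sequence in silico
#'
#' Trypsin cleaves C-terminal to K or R except when the next residue is P.
#' Semitryptic digestion additionally emits every prefix and suffix of each
#' fully tryptic peptide (one tryptic terminus retained). Peptides are
#' deduplicated by protein coordinates and filtered to the configured length
#' bounds.
#'
#' @param sequence protein sequence string.
#' @param config a \code{digest_config}.
#' @return data frame with columns \code{sequence}, \code{start}, \code{end}
#'   (1-based inclusive protein coordinates).
#' @export
digest <- function(sequence, config = digest_config()) {
  if (nchar(sequence) == 0) stop("empty protein sequence")
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  # cleavage sites: position i means a cut between residues i and i+1
  sites <- if (n > 1) which(aa[-n] %in% c("K", "R") & aa[-1] != "P")
           else integer(0)
  bounds <- c(0L, sites, n)  # fully tryptic segment boundaries
  starts <- integer(0); ends <- integer(0)
  nb <- length(bounds)
  for (i in seq_len(nb - 1)) {
    for (j in (i + 1):min(nb, i + 1 + config$missed_cleavages)) {
      starts <- c(starts, bounds[i] + 1L)
      ends <- c(ends, bounds[j])
    }
  }
  if (config$enzyme == "semitryptic") {
    semi_s <- integer(0); semi_e <- integer(0)
    for (k in seq_along(starts)) {
      s <- starts[k]; e <- ends[k]
      if (e > s) {
        # prefixes keep the tryptic N-terminus, suffixes the C-terminus
        semi_s <- c(semi_s, rep(s, e - s), (s + 1L):e)
        semi_e <- c(semi_e, s:(e - 1L), rep(e, e - s))
      }
    }
    starts <- c(starts, semi_s)
    ends <- c(ends, semi_e)
  }
  keep <- !duplicated(paste(starts, ends))
  starts <- starts[keep]; ends <- ends[keep]
  len <- ends - starts + 1L
  ok <- len >= config$min_length & len <= config$max_length
  starts <- starts[ok]; ends <- ends[ok]
  o <- order(starts, ends)
  data.frame(
    sequence = vapply(seq_along(starts), function(k) {
      paste(aa[starts[o[k]]:ends[o[k]]], collapse = "")
    }, character(1)),
    start = starts[o], end = ends[o], stringsAsFactors = FALSE
  )
}

#' Enumerate modified forms of a peptide
#'
#' All combinations of at most \code{max_var_mods} variable modifications over
#' the eligible residues; fixed modifications are always applied. Each site
#' carries at most one modification.
#'
#' @param sequence peptide sequence string.
#' @param registry modification registry.
#' @param config a \code{digest_config} (for \code{max_var_mods} and the
#'   \code{max_forms} combinatorial guard).
#' @param protein_id,start parent coordinates forwarded to the peptides.
#' @return list of \code{modified_peptide} objects (the unmodified/fixed-only
#'   form first).
#' @export
enumerate_modified_forms <- function(sequence,
                                     registry = default_modifications(),
                                     config = digest_config(),
                                     protein_id = NA_character_,
                                     start = NA_integer_) {
  aa <- strsplit(sequence, "")[[1]]
  variable <- registry[!vapply(registry, `[[`, logical(1), "fixed")]
  # options per position: list of applicable variable mod names
  site_opts <- lapply(seq_along(aa), function(i) {
    names(variable)[vapply(variable, function(m) aa[i] %in% m$targets,
                           logical(1))]
  })
  sites <- which(lengths(site_opts) > 0)
  # guard: count forms by summing products over site subsets of size <= cap
  counts <- lengths(site_opts)[sites]
  total <- 1
  if (length(sites) > 0) {
    # generating polynomial prod(1 + c_i x), truncated at max_var_mods
    poly <- 1
    for (ci in counts) poly <- .convolve_dist(poly, c(1, ci))
    total <- sum(poly[seq_len(min(length(poly), config$max_var_mods + 1L))])
  }
  if (total > config$max_forms) {
    stop("modified-form count ", total, " exceeds cap ", config$max_forms)
  }
  forms <- list(data.frame(pos = integer(0), name = character(0),
                           stringsAsFactors = FALSE))
  for (s in sites) {
    new_forms <- forms
    for (f in forms) {
      if (nrow(f) < config$max_var_mods) {
        for (opt in site_opts[[s]]) {
          new_forms[[length(new_forms) + 1L]] <-
            rbind(f, data.frame(pos = s, name = opt, stringsAsFactors = FALSE))
        }
      }
    }
    forms <- new_forms
  }
  lapply(forms, function(f) {
    modified_peptide(sequence, mods = f, protein_id = protein_id,
                     start = start, registry = registry)
  })
}
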