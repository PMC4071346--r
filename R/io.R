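# Readers/writers for the on-disk formats (FASTA, TSV feature maps and
# tables, JSON ground truth and manifest) and pipeline orchestration.
#
# All tabular outputs are tab-separated UTF-8 with one header row; metadata
# lines are '#'-prefixed. Masses are serialized with 6 decimal places, other
# floats with 6 significant digits.

.AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                  "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read a multi-record FASTA file of protein sequences
#'
#' Wrapped sequence lines are concatenated, sequences are upper-cased and
#' whitespace is stripped. Records containing characters outside the
#' 20-letter amino acid alphabet are rejected with an error naming the
#' character and the record.
#'
#' @param path path to the FASTA file.
#' @return data frame with columns \code{id}, \code{description},
#'   \code{sequence}; zero rows for an empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nchar(trimws(lines)) > 0]
  if (length(lines) == 0) {
    return(data.frame(id = character(0), description = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  if (!startsWith(lines[1], ">")) {
    stop("malformed FASTA: line 1 does not start with '>'")
  }
  hdr_idx <- which(startsWith(lines, ">"))
  recs <- lapply(seq_along(hdr_idx), function(i) {
    from <- hdr_idx[i] + 1L
    to <- if (i < length(hdr_idx)) hdr_idx[i + 1L] - 1L else length(lines)
    header <- sub("^>", "", lines[hdr_idx[i]])
    if (nchar(trimws(header)) == 0) {
      stop("malformed FASTA: empty header at line ", hdr_idx[i])
    }
    id <- strsplit(trimws(header), "\\s+")[[1]][1]
    description <- trimws(sub("^\\S+\\s*", "", trimws(header)))
    seq <- toupper(gsub("\\s", "", paste(lines[seq(from, length.out =
                                                     max(0, to - from + 1L))],
                                         collapse = "")))
    bad <- setdiff(unique(strsplit(seq, "")[[1]]), .AA_ALPHABET)
    if (length(bad) > 0) {
      stop("record '", id, "' contains non-amino-acid character(s): ",
           paste(bad, collapse = ", "))
    }
    data.frame(id = id, description = description, sequence = seq,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

.fmt_num <- function(x) formatC(x, format = "g", digits = 6)

.write_tsv <- function(df, path, meta = character(0)) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

#' Write a feature map to TSV
#'
#' Columns: sample_id, mz (6 decimal places), rt, intensity, envelope
#' (semicolon-joined peak intensities).
#'
#' @param map feature data frame (\code{mz}, \code{rt}, \code{intensity},
#'   list-column \code{envelope}).
#' @param sample_id sample identifier written into the first column.
#' @param path output path.
#' @export
write_feature_map <- function(map, sample_id, path) {
  df <- data.frame(
    sample_id = rep(sample_id, nrow(map)),
    mz = sprintf("%.6f", map$mz),
    rt = .fmt_num(map$rt),
    intensity = .fmt_num(map$intensity),
    envelope = vapply(map$envelope, function(e) {
      paste(.fmt_num(e), collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  .write_tsv(df, path)
}

#' Read a feature map written by \code{\link{write_feature_map}}
#'
#' @param path path to the TSV.
#' @return feature data frame with the envelope restored as a list-column.
#' @export
read_feature_map <- function(path) {
  df <- .read_tsv(path, colClasses = "character")
  out <- data.frame(mz = as.numeric(df$mz), rt = as.numeric(df$rt),
                    intensity = as.numeric(df$intensity),
                    stringsAsFactors = FALSE)
  out$envelope <- I(lapply(strsplit(df$envelope, ";"), as.numeric))
  attr(out, "sample_id") <- if (nrow(df) > 0) df$sample_id[1] else NA_character_
  out
}

.truth_to_json <- function(truth) {
  cfg <- truth$config
  list(
    true_abundance = as.data.frame(truth$true_abundance),
    peptide_id = rownames(truth$true_abundance),
    ref_rt = as.list(truth$ref_rt),
    fold_change = as.list(truth$fold_change),
    differential_sites = truth$differential_sites,
    mz_drift = lapply(truth$mz_drift, function(d) d[c("coef", "lo", "hi",
                                                      "scale")]),
    rt_drift = lapply(truth$rt_drift, function(d) d[c("coef", "lo", "hi",
                                                      "scale")]),
    config = list(n_pairs = cfg$n_pairs, intensity_cv = cfg$intensity_cv,
                  mz_drift_ppm = cfg$mz_drift_ppm,
                  rt_drift_min = cfg$rt_drift_min,
                  missingness = cfg$missingness,
                  envelope_cv = cfg$envelope_cv, charges = cfg$charges,
                  rt_window = cfg$rt_window, seed = cfg$seed,
                  fold_changes = as.list(cfg$fold_changes))
  )
}

#' Run the full analysis chain in memory on a synthetic cohort
#'
#' Convenience wrapper chaining cohort generation, q-value filtering,
#' artifact rejection, two-pass quantification, site aggregation and the
#' differential test without touching the disk; used for repeated-seed
#' simulation studies. \code{\link{run_pipeline}} is the file-writing
#' equivalent.
#'
#' @param cohort a \code{\link{cohort_config}}.
#' @param match a \code{\link{match_config}}.
#' @param qvalue_max PSM q-value acceptance threshold.
#' @param alpha,min_pairs,n_resamples statistics settings.
#' @return list with \code{cohort} (the generated data), \code{quant}
#'   (abundance matrices and tags), \code{site_matrix} and
#'   \code{differential}.
#' @export
analyze_cohort <- function(cohort = cohort_config(), match = match_config(),
                           qvalue_max = 0.01, alpha = 0.05, min_pairs = 6L,
                           n_resamples = 10000L) {
  cd <- generate_cohort(cohort)
  psms <- compute_qvalues(cd$psms)
  accepted <- psms$peptide_id[!psms$is_decoy & psms$q_value <= qvalue_max]
  panel_ok <- cohort$panel[vapply(cohort$panel, `[[`, character(1),
                                  "peptide_id") %in% accepted]
  filt <- filter_artifacts(lapply(panel_ok, `[[`, "peptide"))
  keep <- vapply(panel_ok, function(p) {
    !(p$peptide$sequence %in% filt$rejected$sequence)
  }, logical(1))
  panel_retained <- panel_ok[keep]
  quant <- quantify_cohort(panel_retained, cd$maps, cd$truth$ref_rt, match,
                           charges = cohort$charges)
  site_mat <- site_intensity_matrix(quant$abundance,
                                    panel_meta(panel_retained), cd$samples)
  diff <- differential_table(site_mat, alpha = alpha, min_pairs = min_pairs,
                             n_resamples = n_resamples, seed = cohort$seed)
  list(cohort = cd, psms = psms, panel_retained = panel_retained,
       quant = quant, site_matrix = site_mat, differential = diff)
}

#' Run the histone PTM quantification pipeline
#'
#' Modes: \code{simulate} writes a synthetic cohort directory (feature map
#' TSVs, PSM TSV, sample table, ground-truth JSON); \code{identify} performs
#' q-value filtering and artifact rejection and writes the retained peptide
#' list and rejection report; \code{quantify} runs two-pass extraction,
#' normalization and site aggregation and writes the tagged features and the
#' site intensity matrix; \code{stats} writes the differential table;
#' \code{all} chains everything. Every run writes a JSON manifest (settings,
#' seed, package version, stage counts).
#'
#' @param out_dir output directory (created if needed).
#' @param mode one of \code{"all"}, \code{"simulate"}, \code{"identify"},
#'   \code{"quantify"}, \code{"stats"}; modes other than \code{simulate}/
#'   \code{all} consume the files a previous \code{simulate} wrote into
#'   \code{out_dir}.
#' @param cohort a \code{\link{cohort_config}}.
#' @param match a \code{\link{match_config}}.
#' @param qvalue_max PSM q-value acceptance threshold (default 0.01).
#' @param alpha,min_pairs,n_resamples statistics settings (see
#'   \code{\link{differential_table}}).
#' @param verbose log stage counts to stderr.
#' @return invisibly, a list with the stage results that were computed.
#' @export
run_pipeline <- function(out_dir,
                         mode = c("all", "simulate", "identify", "quantify",
                                  "stats"),
                         cohort = cohort_config(), match = match_config(),
                         qvalue_max = 0.01, alpha = 0.05, min_pairs = 6L,
                         n_resamples = 10000L, verbose = TRUE) {
  mode <- match.arg(mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[histoneLFQ] ", ...)
  results <- list()

  if (mode %in% c("all", "simulate")) {
    cohort_data <- generate_cohort(cohort)
    dir.create(file.path(out_dir, "maps"), showWarnings = FALSE)
    for (s in names(cohort_data$maps)) {
      write_feature_map(cohort_data$maps[[s]], s,
                        file.path(out_dir, "maps", paste0(s, ".tsv")))
    }
    .write_tsv(cohort_data$samples, file.path(out_dir, "samples.tsv"))
    .write_tsv(cohort_data$psms, file.path(out_dir, "psms.tsv"))
    jsonlite::write_json(.truth_to_json(cohort_data$truth),
                         file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    say("simulate: ", length(cohort_data$maps), " maps, ",
        nrow(cohort_data$psms), " PSMs")
    results$cohort <- cohort_data
  }
  if (mode == "simulate") {
    .write_manifest(out_dir, cohort, match, qvalue_max, alpha, min_pairs,
                    n_resamples, results)
    return(invisible(results))
  }

  if (mode %in% c("identify", "quantify", "all")) {
    if (is.null(results$cohort)) {
      psms <- .read_tsv(file.path(out_dir, "psms.tsv"))
      samples <- .read_tsv(file.path(out_dir, "samples.tsv"))
      map_files <- list.files(file.path(out_dir, "maps"), full.names = TRUE)
      maps <- lapply(map_files, read_feature_map)
      names(maps) <- sub("\\.tsv$", "", basename(map_files))
      maps <- maps[samples$sample_id]
      gt <- jsonlite::read_json(file.path(out_dir, "ground_truth.json"),
                                simplifyVector = TRUE)
      ref_rt <- unlist(gt$ref_rt)
      results$cohort <- list(maps = maps, samples = samples, psms = psms,
                             truth = list(ref_rt = ref_rt))
    }
    cd <- results$cohort
    psms <- compute_qvalues(cd$psms)
    accepted_ids <- psms$peptide_id[!psms$is_decoy &
                                      psms$q_value <= qvalue_max]
    panel_ok <- cohort$panel[vapply(cohort$panel, `[[`, character(1),
                                    "peptide_id") %in% accepted_ids]
    filt <- filter_artifacts(lapply(panel_ok, `[[`, "peptide"))
    retained_idx <- vapply(panel_ok, function(p) {
      !(p$peptide$sequence %in% filt$rejected$sequence)
    }, logical(1))
    panel_retained <- panel_ok[retained_idx]
    meta_ret <- panel_meta(panel_retained)
    .write_tsv(psms, file.path(out_dir, "psms_qvalues.tsv"))
    .write_tsv(cbind(meta_ret,
                     mass = sprintf("%.6f", meta_ret$mass))[,
                       c("peptide_id", "histone", "site", "mod", "sequence",
                         "start")],
               file.path(out_dir, "peptides_retained.tsv"))
    .write_tsv(filt$rejected, file.path(out_dir, "peptides_rejected.tsv"))
    say("identify: ", length(accepted_ids), "/", sum(!psms$is_decoy),
        " PSMs accepted at q <= ", qvalue_max, "; ",
        length(panel_retained), " peptides retained, ",
        nrow(filt$rejected), " rejected as artifacts")
    results$psms <- psms
    results$panel_retained <- panel_retained
  }
  if (mode == "identify") {
    .write_manifest(out_dir, cohort, match, qvalue_max, alpha, min_pairs,
                    n_resamples, results)
    return(invisible(results))
  }

  if (mode %in% c("quantify", "all")) {
    cd <- results$cohort
    quant <- quantify_cohort(results$panel_retained, cd$maps,
                             cd$truth$ref_rt, match,
                             charges = cohort$charges)
    meta_ret <- panel_meta(results$panel_retained)
    site_mat <- site_intensity_matrix(quant$abundance, meta_ret, cd$samples)
    tag_rows <- do.call(rbind, lapply(names(quant$tags), function(s) {
      t <- quant$tags[[s]]
      if (nrow(t) == 0) return(NULL)
      cbind(sample_id = s, t)
    }))
    if (!is.null(tag_rows)) {
      .write_tsv(tag_rows, file.path(out_dir, "tagged_features.tsv"))
    }
    .write_tsv(site_mat, file.path(out_dir, "site_intensity_matrix.tsv"))
    say("quantify: ", sum(is.finite(quant$abundance)), " peptide abundances, ",
        length(unique(paste(site_mat$histone, site_mat$site, site_mat$mod))),
        " sites quantified")
    results$quant <- quant
    results$site_matrix <- site_mat
  }
  if (mode == "quantify") {
    .write_manifest(out_dir, cohort, match, qvalue_max, alpha, min_pairs,
                    n_resamples, results)
    return(invisible(results))
  }

  if (mode %in% c("stats", "all")) {
    site_mat <- results$site_matrix
    if (is.null(site_mat)) {
      site_mat <- .read_tsv(file.path(out_dir, "site_intensity_matrix.tsv"))
    }
    if (nrow(site_mat) == 0) stop("no quantifiable sites")
    diff <- differential_table(site_mat, alpha = alpha,
                               min_pairs = min_pairs,
                               n_resamples = n_resamples,
                               seed = cohort$seed)
    .write_tsv(within(diff$table, {
      fc <- .fmt_num(fc); p_value <- .fmt_num(p_value)
      p_adj <- .fmt_num(p_adj)
    }), file.path(out_dir, "differential_sites.tsv"))
    .write_tsv(diff$excluded, file.path(out_dir, "excluded_sites.tsv"))
    say("stats: ", nrow(diff$table), " sites tested, ",
        sum(diff$table$significant), " significant at alpha = ", alpha)
    results$differential <- diff
  }
  .write_manifest(out_dir, cohort, match, qvalue_max, alpha, min_pairs,
                  n_resamples, results)
  invisible(results)
}

.write_manifest <- function(out_dir, cohort, match, qvalue_max, alpha,
                            min_pairs, n_resamples, results) {
  manifest <- list(
    package = "histoneLFQ",
    version = as.character(utils::packageVersion("histoneLFQ")),
    seed = cohort$seed,
    cohort = list(n_pairs = cohort$n_pairs,
                  intensity_cv = cohort$intensity_cv,
                  mz_drift_ppm = cohort$mz_drift_ppm,
                  rt_drift_min = cohort$rt_drift_min,
                  missingness = cohort$missingness,
                  envelope_cv = cohort$envelope_cv,
                  charges = cohort$charges,
                  fold_changes = as.list(cohort$fold_changes),
                  n_panel_peptides = length(cohort$panel)),
    match = unclass(match),
    statistics = list(qvalue_max = qvalue_max, alpha = alpha,
                      min_pairs = min_pairs, n_resamples = n_resamples),
    counts = list(
      n_maps = length(results$cohort$maps),
      n_peptides_retained = length(results$panel_retained),
      n_sites_tested = if (!is.null(results$differential))
        nrow(results$differential$table) else NULL
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
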