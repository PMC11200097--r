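#' Whole-dataset SSR summary
#'
#' Compact summary of a mining run in the style of classical transcriptome
#' SSR surveys: sequence and bp totals, SSR counts (overall, per motif
#' size, compound membership), SSR frequency (percent) and density (per
#' Mb).  Motif-type tallies are reported for both actual and standardized
#' motifs.
#'
#' @param ssrs miner output table.
#' @param n_sequences number of sequences examined.
#' @param total_bp summed bp of the sequences examined.
#' @return data.frame of item / value rows.
#' @export
summarize_ssrs <- function(ssrs, n_sequences, total_bp) {
  per_tx <- table(ssrs$transcript_id)
  n_compound <- length(unique(paste(ssrs$transcript_id,
                                    ssrs$compound_id)[!is.na(ssrs$compound_id)]))
  size_counts <- tabulate(ssrs$motif_size, nbins = 6)
  items <- c("n_sequences_examined", "total_bp_examined", "n_ssrs",
             "n_ssr_sequences", "n_sequences_multi_ssr",
             "n_compound_ssrs", "n_ssrs_in_compounds",
             paste0("n_", c("mono", "di", "tri", "tetra", "penta", "hexa"),
                    "nucleotide"),
             "n_actual_motif_types", "n_standardized_motif_types",
             "frequency_pct", "density_per_mb", "mean_tract_length")
  values <- c(n_sequences, total_bp, nrow(ssrs), length(per_tx),
              sum(per_tx > 1), n_compound, sum(!is.na(ssrs$compound_id)),
              size_counts,
              length(unique(ssrs$motif)), length(unique(ssrs$canonical_motif)),
              round(ssr_frequency_pct(nrow(ssrs), n_sequences), 2),
              round(ssr_density(nrow(ssrs), total_bp), 2),
              round(mean(ssrs$tract_length), 2))
  data.frame(item = items, value = values, stringsAsFactors = FALSE)
}

#' Per-region SSR summary
#'
#' Counts sequences, bp, SSRs and density per transcribed-region category.
#' Boundary SSRs have no well-defined region length and get only a count.
#'
#' @param assignments [map_regions()] output.
#' @param annotations [transcript_annotation()] table.
#' @return data.frame: region, n_sequences, total_bp, n_ssrs,
#'   density_per_mb.
#' @export
summarize_regions <- function(assignments, annotations) {
  a <- annotations
  has_cds <- !is.na(a$cds_start)
  scope <- list(
    FIVE_UTR = list(n = sum(has_cds & a$cds_start > 1),
                    bp = sum(a$cds_start[has_cds] - 1)),
    CDS = list(n = sum(has_cds),
               bp = sum(a$cds_end[has_cds] - a$cds_start[has_cds] + 1)),
    THREE_UTR = list(n = sum(has_cds & a$cds_end < a$length),
                     bp = sum((a$length - a$cds_end)[has_cds])),
    FIVE_UTR_CDS_BOUNDARY = list(n = NA_real_, bp = NA_real_),
    CDS_THREE_UTR_BOUNDARY = list(n = NA_real_, bp = NA_real_),
    LNCRNA = list(n = sum(a$is_lncRNA), bp = sum(a$length[a$is_lncRNA])),
    OTHER = list(n = sum(!has_cds & !a$is_lncRNA),
                 bp = sum(a$length[!has_cds & !a$is_lncRNA]))
  )
  rows <- lapply(names(scope), function(r) {
    n_ssr <- sum(assignments$region == r)
    bp <- scope[[r]]$bp
    data.frame(region = r, n_sequences = scope[[r]]$n, total_bp = bp,
               n_ssrs = n_ssr,
               density_per_mb = if (!is.na(bp) && bp > 0)
                 round(ssr_density(n_ssr, bp), 2) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full SSR / expMotif pipeline
#'
#' Orchestrates mine -> map -> profile -> stats -> detect over either
#' provided input files or a simulated dataset, writing every stage table,
#' whole-dataset and per-region summaries, a warnings sidecar, and a run
#' manifest (package version, seed, config hash).  Re-running with the same
#' config reproduces identical outputs.
#'
#' @param config list with either `simulate` (a [synthetic_config()]) or
#'   `fasta` / `annotations` / `tpm` paths; optional `criteria`
#'   ([miner_criteria()]), `thresholds` ([level_thresholds()]), `detector`
#'   (list: alpha, min_carriers, vif_threshold, motif_mode).
#' @param out_dir output directory.
#' @return invisible list of all stage objects.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warn_log <- character(0)
  collect <- function(expr, stage) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)),
      warning = function(w) {
        warn_log <<- c(warn_log, paste0("[", stage, "] ",
                                        conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }
  criteria <- config$criteria %||% miner_criteria()
  thresholds <- config$thresholds %||% level_thresholds()
  det <- utils::modifyList(list(alpha = 0.05, min_carriers = 10,
                                vif_threshold = 10,
                                motif_mode = "standardized"),
                           config$detector %||% list())
  if (!is.null(config$simulate)) {
    sim <- collect(simulate_dataset(config$simulate), "simulate")
    seqs <- sim$sequences; ann <- sim$annotations; tpm <- sim$tpm
    utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    seqs <- collect(read_transcripts(config$fasta), "read_fasta")
    ann <- collect(read_annotation_tsv(config$annotations), "read_annotations")
    tpm <- collect(read_tpm_tsv(config$tpm), "read_tpm")
  }
  ssrs <- collect(mine_ssrs(seqs, criteria), "mine")
  write_ssr_tsv(ssrs, file.path(out_dir, "ssrs.tsv"))
  assignments <- collect(map_regions(ssrs, ann, seqs), "map")
  utils::write.table(assignments, file.path(out_dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  profiles <- collect(profile_expression(tpm, thresholds), "profile")
  utils::write.table(profiles, file.path(out_dir, "profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  t1 <- summarize_ssrs(ssrs, length(seqs), sum(nchar(seqs)))
  utils::write.table(t1, file.path(out_dir, "summary_dataset.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  t2 <- summarize_regions(assignments, ann)
  utils::write.table(t2, file.path(out_dir, "summary_regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  detection <- collect(
    detect_expmotifs(assignments, profiles, ann,
                     motif_mode = det$motif_mode, alpha = det$alpha,
                     min_carriers = det$min_carriers,
                     vif_threshold = det$vif_threshold), "detect")
  utils::write.table(detection$candidates,
                     file.path(out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(detection$calls, file.path(out_dir, "calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fit_rows <- do.call(rbind, lapply(names(detection$fits), function(k) {
    f <- detection$fits[[k]]$fits
    if (is.null(f)) return(NULL)
    cbind(data.frame(group = k, stringsAsFactors = FALSE), f)
  }))
  if (is.null(fit_rows))
    fit_rows <- data.frame(group = character(0))
  utils::write.table(fit_rows, file.path(out_dir, "fits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(warn_log, file.path(out_dir, "warnings.log"))
  cfg_file <- file.path(out_dir, "config.dput")
  dput(config, cfg_file)
  manifest <- c(
    paste0("package: ssrexp ",
           as.character(utils::packageVersion("ssrexp"))),
    paste0("r_version: ", R.version.string),
    paste0("config_md5: ", unname(tools::md5sum(cfg_file))),
    paste0("seed: ", if (!is.null(config$simulate))
      config$simulate$seed else "NA"),
    paste0("n_transcripts: ", length(seqs)),
    paste0("n_ssrs: ", nrow(ssrs)))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(list(ssrs = ssrs, assignments = assignments, profiles = profiles,
                 summary_dataset = t1, summary_regions = t2,
                 detection = detection))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
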