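#' Configuration for the synthetic transcriptome generator
#'
#' Defines the study conditions a simulated dataset emulates: transcript
#' counts and region lengths, lncRNA fraction, per-region background GC,
#' the SSR planting plan, and the expression model (12-organ TPM matrix
#' whose log expression capacity can depend on planted SSR characteristics
#' and whose across-organ concentration can be lowered for tissue-specific
#' carriers).
#'
#' `ssr_plan` is a data.frame with columns motif, region (FIVE_UTR / CDS /
#' THREE_UTR / LNCRNA), prob (per-transcript carrier probability),
#' min_reps, max_reps, and optionally mean_extra_copies (Poisson mean of
#' additional tracts per carrier, default 0).
#'
#' `expression` is a list: n_organs, mu0 / sigma0 (baseline lnTPM_max
#' normal), concentration / concentration_specific (Dirichlet concentration
#' for ordinary vs tissue-specific transcripts), effects (data.frame motif,
#' region, characteristic in abundance/density/length_bp, beta acting on
#' lnTPM_max), cv_effects (data.frame motif, region flagging carriers as
#' tissue-specific).
#'
#' @param n_transcripts transcript count.
#' @param lncRNA_fraction fraction of transcripts simulated as lncRNAs.
#' @param region_lengths named mean lengths (bp) for utr5, cds, utr3, lnc;
#'   individual lengths are drawn log-normally around these.
#' @param length_sdlog log-scale sd of the length draw.
#' @param gc named per-region background GC fractions.
#' @param ssr_plan planting plan (see Details); NULL plants nothing.
#' @param expression expression model settings (see Details).
#' @param seed mandatory integer seed (< 2^30).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_transcripts = 300,
                             lncRNA_fraction = 0.1,
                             region_lengths = c(utr5 = 150, cds = 600,
                                                utr3 = 250, lnc = 500),
                             length_sdlog = 0.2,
                             gc = c(FIVE_UTR = 0.5, CDS = 0.55,
                                    THREE_UTR = 0.35, LNCRNA = 0.4),
                             ssr_plan = NULL,
                             expression = list(),
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  seed <- as.integer(seed)
  if (is.na(seed) || abs(seed) >= 2^30) stop("seed must be an integer < 2^30")
  if (lncRNA_fraction < 0 || lncRNA_fraction > 1)
    stop("lncRNA_fraction must be in [0, 1]")
  if (!is.null(ssr_plan)) {
    need <- c("motif", "region", "prob", "min_reps", "max_reps")
    if (!all(need %in% names(ssr_plan)))
      stop("ssr_plan needs columns ", paste(need, collapse = ", "))
    if (any(ssr_plan$prob < 0 | ssr_plan$prob > 1))
      stop("planting probabilities must be in [0, 1]")
    if (is.null(ssr_plan$mean_extra_copies)) ssr_plan$mean_extra_copies <- 0
    mins <- miner_criteria()$min_repeats_by_size
    sz <- nchar(ssr_plan$motif)
    if (any(ssr_plan$min_reps < mins[sz]))
      stop("planted repeat counts must meet the miner minimums")
  }
  expr_defaults <- list(n_organs = 12L, mu0 = 1, sigma0 = 1.5,
                        concentration = 5, concentration_specific = 0.15,
                        effects = NULL, cv_effects = NULL)
  expression <- utils::modifyList(expr_defaults, expression)
  structure(list(n_transcripts = as.integer(n_transcripts),
                 lncRNA_fraction = lncRNA_fraction,
                 region_lengths = region_lengths,
                 length_sdlog = length_sdlog, gc = gc,
                 ssr_plan = ssr_plan, expression = expression, seed = seed),
            class = "synthetic_config")
}

.random_seq <- function(len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

.ssr_free_seq <- function(len, gc, criteria, max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    s <- .random_seq(len, gc)
    if (!.has_ssr(s, criteria)) return(s)
  }
  stop("could not draw an SSR-free background of length ", len)
}

.draw_len <- function(mean_len, sdlog, min_len = 60L) {
  max(min_len, round(stats::rlnorm(1, log(mean_len), sdlog)))
}

# plant one tract into a character vector at start (1-based), fixing flanks
# so the tract cannot extend into a longer run of the same period
.insert_tract <- function(x, start, tract, m) {
  tl <- nchar(tract)
  x[start:(start + tl - 1L)] <- strsplit(tract, "", fixed = TRUE)[[1]]
  q <- start + tl - 1L
  if (start > 1L && x[start - 1L] == x[start + m - 1L])
    x[start - 1L] <- setdiff(c("A", "C", "G", "T"), x[start + m - 1L])[1]
  if (q < length(x) && x[q + 1L] == x[q + 1L - m])
    x[q + 1L] <- setdiff(c("A", "C", "G", "T"), x[q + 1L - m])[1]
  x
}

#' Generate a synthetic transcriptome with planted SSRs
#'
#' Draws SSR-free background sequences region by region (rejection-sampled
#' against the miner so planted truth is unambiguous), assembles
#' 5'-UTR/CDS/3'-UTR transcripts and lncRNAs, and plants perfect SSR tracts
#' per the plan at recorded coordinates.  Every planted transcript is
#' re-mined and must yield exactly its truth rows; otherwise the transcript
#' is re-drawn.  Deterministic under the config seed.
#'
#' @param config a [synthetic_config()].
#' @return list: `sequences` (named character), `annotations`
#'   ([transcript_annotation()] table), `truth` (planted-SSR table with
#'   motif, canonical_motif, region, start, end, repeat_count,
#'   tract_length).
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  crit <- miner_criteria()
  n <- config$n_transcripts
  ids <- sprintf("tx%04d", seq_len(n))
  is_lnc <- stats::runif(n) < config$lncRNA_fraction
  rl <- config$region_lengths
  # carrier draws are made up front so the per-transcript retry loop cannot
  # change who carries what
  plan <- config$ssr_plan
  carrier <- NULL
  if (!is.null(plan) && nrow(plan)) {
    carrier <- matrix(FALSE, n, nrow(plan))
    copies <- matrix(0L, n, nrow(plan))
    for (j in seq_len(nrow(plan))) {
      elig <- if (plan$region[j] == "LNCRNA") is_lnc else !is_lnc
      carrier[, j] <- elig & stats::runif(n) < plan$prob[j]
      copies[, j] <- ifelse(carrier[, j],
                            1L + stats::rpois(n, plan$mean_extra_copies[j]),
                            0L)
    }
  }
  seqs <- character(n)
  ann_rows <- vector("list", n)
  truth_rows <- list()
  pick1 <- function(lo, hi) if (lo == hi) lo else sample(lo:hi, 1L)
  for (i in seq_len(n)) {
    done <- FALSE
    for (attempt in 1:25) {
      if (is_lnc[i]) {
        lens <- c(LNCRNA = .draw_len(rl[["lnc"]], config$length_sdlog))
        regions <- list(LNCRNA = c(1L, lens[["LNCRNA"]]))
        tx_len <- lens[["LNCRNA"]]
        cds <- c(NA_integer_, NA_integer_)
      } else {
        l5 <- .draw_len(rl[["utr5"]], config$length_sdlog)
        lc <- .draw_len(rl[["cds"]], config$length_sdlog)
        l3 <- .draw_len(rl[["utr3"]], config$length_sdlog)
        tx_len <- l5 + lc + l3
        regions <- list(FIVE_UTR = c(1L, l5),
                        CDS = c(l5 + 1L, l5 + lc),
                        THREE_UTR = c(l5 + lc + 1L, tx_len))
        cds <- c(l5 + 1L, l5 + lc)
      }
      seq_chars <- strsplit(paste(vapply(names(regions), function(rn) {
        b <- regions[[rn]]
        .ssr_free_seq(b[2] - b[1] + 1L, config$gc[[rn]], crit)
      }, character(1)), collapse = ""), "", fixed = TRUE)[[1]]
      tx_truth <- list()
      ok <- TRUE
      occupied <- matrix(numeric(0), ncol = 2)
      if (!is.null(plan)) for (j in seq_len(nrow(plan))) {
        if (!carrier[i, j] || !(plan$region[j] %in% names(regions))) next
        b <- regions[[plan$region[j]]]
        m <- nchar(plan$motif[j])
        for (cp in seq_len(copies[i, j])) {
          reps <- pick1(plan$min_reps[j], plan$max_reps[j])
          tract <- strrep(plan$motif[j], reps)
          tl <- nchar(tract)
          if (tl + 2L > b[2] - b[1] + 1L)
            stop("planted SSR (", tl, " bp) does not fit region ",
                 plan$region[j], " of ", ids[i])
          placed <- FALSE
          for (try in 1:30) {
            st <- pick1(b[1] + 1L, b[2] - tl)
            en <- st + tl - 1L
            clash <- nrow(occupied) > 0 &&
              any(st <= occupied[, 2] + 2 & en >= occupied[, 1] - 2)
            if (!clash) { placed <- TRUE; break }
          }
          if (!placed) next   # congested region: this copy is not planted
          seq_chars <- .insert_tract(seq_chars, st, tract, m)
          occupied <- rbind(occupied, c(st, en))
          tx_truth[[length(tx_truth) + 1L]] <-
            list(j = j, start = st, end = en, reps = reps)
        }
        if (!ok) break
      }
      if (!ok) next
      # verification: the miner must recover exactly the planted records
      seq_i <- paste(seq_chars, collapse = "")
      mined <- .ssr_runs(seq_i, crit)
      t_motif <- vapply(tx_truth, function(z) plan$motif[z$j], character(1))
      t_start <- vapply(tx_truth, `[[`, numeric(1), "start")
      t_end <- vapply(tx_truth, `[[`, numeric(1), "end")
      if (length(mined$start) == length(tx_truth) &&
          setequal(paste(mined$motif, mined$start, mined$end),
                   paste(t_motif, t_start, t_end))) {
        seqs[i] <- seq_i
        ann_rows[[i]] <- list(length = tx_len, cds_start = cds[1],
                              cds_end = cds[2])
        if (length(tx_truth))
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            transcript_id = ids[i], motif = t_motif,
            region = vapply(tx_truth, function(z) plan$region[z$j],
                            character(1)),
            start = as.integer(t_start), end = as.integer(t_end),
            repeat_count = vapply(tx_truth, function(z) as.integer(z$reps),
                                  integer(1)),
            stringsAsFactors = FALSE)
        done <- TRUE
        break
      }
    }
    if (!done) stop("could not realize planting for ", ids[i])
  }
  names(seqs) <- ids
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(transcript_id = character(0), motif = character(0),
               region = character(0), start = integer(0), end = integer(0),
               repeat_count = integer(0))
  truth$tract_length <- nchar(truth$motif) * truth$repeat_count
  canon_map <- if (!is.null(plan))
    stats::setNames(canonicalize_motif(plan$motif), plan$motif) else character(0)
  truth$canonical_motif <- unname(canon_map[truth$motif])
  truth <- truth[, c("transcript_id", "motif", "canonical_motif", "region",
                     "start", "end", "repeat_count", "tract_length")]
  rownames(truth) <- NULL
  list(sequences = seqs,
       annotations = transcript_annotation(
         ids, vapply(ann_rows, `[[`, numeric(1), "length"),
         vapply(ann_rows, function(z) as.integer(z$cds_start), integer(1)),
         vapply(ann_rows, function(z) as.integer(z$cds_end), integer(1)),
         is_lnc),
       truth = truth)
}

#' Generate a TPM matrix with planted expression effects
#'
#' Per transcript, draws baseline lnTPM_max ~ Normal(mu0, sigma0), adds
#' beta x characteristic for every planted effect the transcript carries,
#' spreads expression across organs with a Dirichlet draw (concentration
#' lowered for tissue-specific carriers, which raises TPM_CV; as the
#' concentration grows the organ profile flattens and TPM_CV tends to 0),
#' scales the row so its maximum equals exp(lnTPM_max), and finally
#' normalizes every organ column to a common total, mimicking the
#' compositional constraint of TPM.  Deterministic under the config seed.
#'
#' @param config a [synthetic_config()].
#' @param truth planted-SSR truth table from [generate_transcriptome()].
#' @param annotations annotation table from [generate_transcriptome()].
#' @return numeric matrix, transcripts x organs.
#' @export
generate_expression <- function(config, truth, annotations) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  ex <- config$expression
  ids <- annotations$transcript_id
  n <- length(ids)
  ln_max <- stats::rnorm(n, ex$mu0, ex$sigma0)
  characteristic_of <- function(motif, region, what) {
    sub <- truth[truth$motif == motif & truth$region == region, ,
                 drop = FALSE]
    cnt <- tapply(sub$tract_length,
                  factor(sub$transcript_id, levels = ids),
                  function(v) switch(what,
                                     abundance = length(v),
                                     length_bp = sum(v),
                                     density = NA))
    x <- as.numeric(cnt); x[is.na(x)] <- 0
    if (what == "density") {
      cntn <- tapply(sub$tract_length,
                     factor(sub$transcript_id, levels = ids), length)
      cntn[is.na(cntn)] <- 0
      x <- as.numeric(cntn) / (annotations$length / 1e6)
    }
    x
  }
  if (!is.null(ex$effects) && nrow(ex$effects)) {
    for (j in seq_len(nrow(ex$effects))) {
      e <- ex$effects[j, ]
      ln_max <- ln_max + e$beta *
        characteristic_of(e$motif, e$region, e$characteristic)
    }
  }
  conc <- rep(ex$concentration, n)
  if (!is.null(ex$cv_effects) && nrow(ex$cv_effects)) {
    for (j in seq_len(nrow(ex$cv_effects))) {
      cvj <- ex$cv_effects[j, ]
      hit <- ids %in% truth$transcript_id[truth$motif == cvj$motif &
                                            truth$region == cvj$region]
      conc[hit] <- ex$concentration_specific
    }
  }
  k <- ex$n_organs
  tpm <- matrix(0, n, k, dimnames = list(ids, sprintf("organ%02d", 1:k)))
  for (i in seq_len(n)) {
    g <- stats::rgamma(k, shape = conc[i])
    if (all(g == 0)) g <- rep(1, k)
    share <- g / sum(g)
    tpm[i, ] <- exp(ln_max[i]) * share / max(share)
  }
  sweep(tpm, 2, colSums(tpm), "/") * 1e6
}

#' Simulate a complete dataset
#'
#' Runs [generate_transcriptome()] and [generate_expression()] and
#' optionally writes FASTA + TSV outputs.
#'
#' @param config a [synthetic_config()].
#' @param out_dir optional output directory (created if missing); writes
#'   transcripts.fasta, annotations.tsv, truth.tsv, tpm.tsv.
#' @return list: sequences, annotations, truth, tpm.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  tr <- generate_transcriptome(config)
  tpm <- generate_expression(config, tr$truth, tr$annotations)
  out <- c(tr, list(tpm = tpm))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_transcripts(out$sequences, file.path(out_dir, "transcripts.fasta"))
    write_annotation_tsv(out$annotations, file.path(out_dir, "annotations.tsv"))
    utils::write.table(out$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_tpm_tsv(out$tpm, file.path(out_dir, "tpm.tsv"))
  }
  out
}
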