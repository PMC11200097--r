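#' Level thresholds for expression binning
#'
#' Cut points splitting TPM_max and TPM_CV into five levels, level 1 being
#' the highest values.  The default TPM_CV level-1 cut of 3.4641 (= sqrt(12))
#' is the sample CV of a 12-organ profile expressed in exactly one organ, so
#' level 1 of TPM_CV holds the strictly one-organ genes.
#'
#' @param max_cuts 4 strictly increasing reals for TPM_max.
#' @param cv_cuts 4 strictly increasing reals for TPM_CV.
#' @return list of class `level_thresholds`.
#' @export
level_thresholds <- function(max_cuts = c(1, 10, 100, 1000),
                             cv_cuts = c(0.5, 1, 1.5, 3.4641)) {
  for (cuts in list(max_cuts, cv_cuts)) {
    if (length(cuts) != 4L || anyNA(cuts) || any(diff(cuts) <= 0))
      stop("cuts must be 4 strictly increasing values")
  }
  structure(list(max_cuts = max_cuts, cv_cuts = cv_cuts),
            class = "level_thresholds")
}

#' Sample coefficient of variation of a TPM vector
#'
#' Sample (n-1 denominator) standard deviation divided by the mean.  For an
#' n-organ profile expressed in exactly one organ this equals sqrt(n) -- the
#' upper bound of the CV -- which is where the default level-1 threshold
#' 3.4641 for 12 organs comes from.
#'
#' @param tpm numeric vector of n >= 2 non-negative values.
#' @return the CV, or NA (with a warning) when the mean is zero.
#' @examples
#' tpm_cv(c(100, rep(0, 11))) # sqrt(12) = 3.4641...
#' @export
tpm_cv <- function(tpm) {
  if (length(tpm) < 2L || anyNA(tpm) || any(tpm < 0))
    stop("tpm must be >= 2 non-negative values")
  m <- mean(tpm)
  if (m == 0) {
    warning("zero-mean TPM vector; CV undefined")
    return(NA_real_)
  }
  stats::sd(tpm) / m
}

#' Assign a five-level bin
#'
#' Level 1 holds the highest values (value >= cuts\[4]), level 5 the lowest
#' (value < cuts\[1]); each interval is closed at its lower cut, so a TPM_CV
#' of exactly 3.4641 lands in level 1.
#'
#' @param value non-negative finite numeric (vectorized).
#' @param cuts 4 increasing cut points.
#' @return integer level(s) in 1..5.
#' @export
assign_level <- function(value, cuts) {
  if (any(!is.finite(value))) stop("value must be finite")
  if (length(cuts) != 4L || any(diff(cuts) <= 0)) stop("need 4 increasing cuts")
  as.integer(5L - findInterval(value, cuts))
}

#' Derive expression profiles from a TPM matrix
#'
#' Computes per-transcript TPM_max (expression capacity), TPM_CV (tissue
#' specificity), their five-level bins, and the everywhere-expressed flag
#' (all organs' TPM strictly above `floor`).  Transcripts with all-zero TPM
#' get NA CV and NA levels (natural-log transforms downstream need
#' TPM_max > 0).
#'
#' @param tpm numeric matrix or data.frame, transcripts x organs, with
#'   rownames (or a `transcript_id` column) giving ids.
#' @param thresholds a [level_thresholds()] object.
#' @param floor expression floor for `expressed_everywhere` (strict >).
#' @return data.frame: transcript_id, tpm_max, tpm_cv, level_max, level_cv,
#'   expressed_everywhere.
#' @export
profile_expression <- function(tpm, thresholds = level_thresholds(),
                               floor = 0.01) {
  if (is.data.frame(tpm)) {
    if ("transcript_id" %in% names(tpm)) {
      ids <- tpm$transcript_id
      tpm <- as.matrix(tpm[, setdiff(names(tpm), "transcript_id"), drop = FALSE])
      rownames(tpm) <- ids
    } else tpm <- as.matrix(tpm)
  }
  if (is.null(rownames(tpm))) stop("tpm needs transcript ids as rownames")
  if (ncol(tpm) < 2L) stop("need >= 2 organs")
  if (any(tpm < 0)) stop("negative TPM values")
  tmax <- apply(tpm, 1, max)
  tmean <- rowMeans(tpm)
  tsd <- apply(tpm, 1, stats::sd)
  tcv <- ifelse(tmean > 0, tsd / tmean, NA_real_)
  lv_max <- rep(NA_integer_, nrow(tpm))
  lv_cv <- rep(NA_integer_, nrow(tpm))
  pos <- tmax > 0
  lv_max[pos] <- assign_level(tmax[pos], thresholds$max_cuts)
  lv_cv[pos] <- assign_level(tcv[pos], thresholds$cv_cuts)
  data.frame(transcript_id = rownames(tpm),
             tpm_max = tmax, tpm_cv = tcv,
             level_max = lv_max, level_cv = lv_cv,
             expressed_everywhere = apply(tpm > floor, 1, all),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter to everywhere-expressed profiles
#'
#' Keeps profiles whose TPM exceeded the floor in every organ (strict >,
#' evaluated by [profile_expression()]); used for the UTR/CDS
#' differential-expression comparison, which is restricted to genes
#' expressed in all samples.
#'
#' @param profiles output of [profile_expression()].
#' @return the retained subset.
#' @export
expressed_filter <- function(profiles) {
  stopifnot("expressed_everywhere" %in% names(profiles))
  profiles[profiles$expressed_everywhere, , drop = FALSE]
}

#' Read / write TPM matrices and profile tables
#'
#' The TPM TSV has a header row of organ labels and a first column of
#' transcript ids.
#'
#' @param path TSV path.
#' @param x matrix / data.frame to write.
#' @return matrix (read) or the path (write).
#' @export
read_tpm_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' @rdname read_tpm_tsv
#' @export
write_tpm_tsv <- function(x, path) {
  d <- data.frame(transcript_id = rownames(x), x, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
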