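.REGIONS <- c("FIVE_UTR", "CDS", "THREE_UTR", "FIVE_UTR_CDS_BOUNDARY",
              "CDS_THREE_UTR_BOUNDARY", "LNCRNA", "OTHER")

#' Transcript annotation table
#'
#' Validates a coordinate table: one row per transcript with its length, an
#' optional CDS interval (1-based, inclusive, on transcript coordinates) and
#' a lncRNA flag.  lncRNAs must not carry a CDS.
#'
#' @param transcript_id character ids.
#' @param length transcript lengths (bp).
#' @param cds_start,cds_end CDS interval or NA.
#' @param is_lncRNA logical flag.
#' @return validated data.frame of class `transcript_annotation`.
#' @export
transcript_annotation <- function(transcript_id, length, cds_start = NA,
                                  cds_end = NA, is_lncRNA = FALSE) {
  ann <- data.frame(transcript_id = as.character(transcript_id),
                    length = as.integer(length),
                    cds_start = as.integer(cds_start),
                    cds_end = as.integer(cds_end),
                    is_lncRNA = as.logical(is_lncRNA),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ann$transcript_id)) stop("duplicated transcript ids")
  has_cds <- !is.na(ann$cds_start) | !is.na(ann$cds_end)
  if (any(has_cds & (is.na(ann$cds_start) | is.na(ann$cds_end))))
    stop("cds_start and cds_end must both be given or both NA")
  ok <- !has_cds | (ann$cds_start >= 1L & ann$cds_start <= ann$cds_end &
                      ann$cds_end <= ann$length)
  if (any(!ok)) stop("invalid CDS interval for: ",
                     paste(ann$transcript_id[!ok], collapse = ", "))
  if (any(ann$is_lncRNA & has_cds))
    stop("lncRNA transcripts must not have a CDS")
  class(ann) <- c("transcript_annotation", "data.frame")
  ann
}

#' Assign one SSR to a transcribed region
#'
#' An SSR fully 5' of the CDS is 5'-UTR, fully inside the CDS is CDS, fully
#' 3' of it is 3'-UTR; partial overlap with a UTR/CDS junction gives the
#' corresponding boundary category.  SSRs on lncRNAs are LNCRNA; SSRs on
#' transcripts with neither CDS nor lncRNA flag are OTHER.  Boundary and
#' OTHER records carry no relative position and are excluded from
#' region-level statistics downstream.
#'
#' The relative position is computed from the SSR start with the
#' transcribed region as the frame: (start - region_start + 1) /
#' region_length; for lncRNAs the whole transcript is the region.
#'
#' @param ssr_start,ssr_end 1-based inclusive SSR coordinates.
#' @param ann one-row annotation (list or data.frame row) with `length`,
#'   `cds_start`, `cds_end`, `is_lncRNA`.
#' @return list with `region` and `relative_position` (NA for boundary /
#'   OTHER).
#' @export
assign_region <- function(ssr_start, ssr_end, ann) {
  if (ssr_start < 1L || ssr_end > ann$length || ssr_start > ssr_end)
    stop("SSR [", ssr_start, ",", ssr_end, "] outside transcript of length ",
         ann$length)
  if (isTRUE(ann$is_lncRNA))
    return(list(region = "LNCRNA",
                relative_position = relative_position(ssr_start, 1L, ann$length)))
  if (is.na(ann$cds_start))
    return(list(region = "OTHER", relative_position = NA_real_))
  cs <- ann$cds_start; ce <- ann$cds_end
  if (ssr_end < cs) {
    return(list(region = "FIVE_UTR",
                relative_position = relative_position(ssr_start, 1L, cs - 1L)))
  }
  if (ssr_start > ce) {
    return(list(region = "THREE_UTR",
                relative_position = relative_position(ssr_start, ce + 1L,
                                                      ann$length - ce)))
  }
  if (ssr_start >= cs && ssr_end <= ce) {
    return(list(region = "CDS",
                relative_position = relative_position(ssr_start, cs,
                                                      ce - cs + 1L)))
  }
  if (ssr_start < cs)
    return(list(region = "FIVE_UTR_CDS_BOUNDARY", relative_position = NA_real_))
  list(region = "CDS_THREE_UTR_BOUNDARY", relative_position = NA_real_)
}

#' Relative position of an SSR within a transcribed region
#'
#' (ssr_start - region_start + 1) / region_length, in (0, 1]: the first base
#' of a 100 bp region maps to 0.01 and the last base to 1.
#'
#' @param ssr_start 1-based SSR start.
#' @param region_start 1-based region start.
#' @param region_length region length in bp.
#' @return numeric in (0, 1].
#' @export
relative_position <- function(ssr_start, region_start, region_length) {
  if (region_length < 1L) stop("region_length must be >= 1")
  if (ssr_start < region_start ||
      ssr_start > region_start + region_length - 1L)
    stop("SSR start ", ssr_start, " outside region [", region_start, ", ",
         region_start + region_length - 1L, "]")
  (ssr_start - region_start + 1) / region_length
}

#' GC content of a sequence
#'
#' 100 * (G + C) / (A + C + G + T); N bases are excluded from the
#' denominator.
#'
#' @param sequence non-empty A/C/G/T/N string (vectorized).
#' @return percentage in \[0, 100].
#' @examples
#' gc_content("ATGC") # 50
#' @export
gc_content <- function(sequence) {
  vapply(sequence, function(s) {
    if (is.na(s) || !nzchar(s)) stop("empty sequence")
    s <- toupper(s)
    n_gc <- nchar(gsub("[^GC]", "", s))
    n_acgt <- nchar(gsub("[^ACGT]", "", s))
    if (n_acgt == 0L) stop("sequence has no A/C/G/T bases")
    100 * n_gc / n_acgt
  }, numeric(1), USE.NAMES = FALSE)
}

.region_bounds <- function(ann_row, region) {
  switch(region,
         FIVE_UTR  = c(1L, ann_row$cds_start - 1L),
         CDS       = c(ann_row$cds_start, ann_row$cds_end),
         THREE_UTR = c(ann_row$cds_end + 1L, ann_row$length),
         LNCRNA    = c(1L, ann_row$length),
         OTHER     = c(1L, ann_row$length),
         c(NA_integer_, NA_integer_))
}

#' Map SSRs to transcribed regions
#'
#' Vectorized wrapper over [assign_region()]: attaches region, relative
#' position, SSR-tract GC and background GC (GC of the host region sequence
#' with the SSR tract excised) to every SSR record.
#'
#' @param ssrs miner output table.
#' @param annotations [transcript_annotation()] table.
#' @param sequences optional named character vector of transcript sequences;
#'   without it the GC columns are NA.
#' @return `ssrs` with columns region, relative_position, ssr_gc,
#'   background_gc appended.
#' @export
map_regions <- function(ssrs, annotations, sequences = NULL) {
  idx <- match(ssrs$transcript_id, annotations$transcript_id)
  if (anyNA(idx))
    stop("SSRs on unannotated transcripts: ",
         paste(unique(ssrs$transcript_id[is.na(idx)]), collapse = ", "))
  n <- nrow(ssrs)
  region <- character(n); relpos <- rep(NA_real_, n)
  ssr_gc <- rep(NA_real_, n); bg_gc <- rep(NA_real_, n)
  # plain vectors: data.frame row extraction is too slow inside the loop
  a_len <- annotations$length; a_cs <- annotations$cds_start
  a_ce <- annotations$cds_end; a_lnc <- annotations$is_lncRNA
  for (i in seq_len(n)) {
    ann <- list(length = a_len[idx[i]], cds_start = a_cs[idx[i]],
                cds_end = a_ce[idx[i]], is_lncRNA = a_lnc[idx[i]])
    a <- assign_region(ssrs$start[i], ssrs$end[i], ann)
    region[i] <- a$region
    relpos[i] <- a$relative_position
    if (!is.null(sequences)) {
      s <- sequences[[ssrs$transcript_id[i]]]
      ssr_gc[i] <- gc_content(substr(s, ssrs$start[i], ssrs$end[i]))
      b <- .region_bounds(ann, a$region)
      if (!is.na(b[1])) {
        left <- if (ssrs$start[i] > b[1]) substr(s, b[1], ssrs$start[i] - 1L) else ""
        right <- if (ssrs$end[i] < b[2]) substr(s, ssrs$end[i] + 1L, b[2]) else ""
        bg <- paste0(left, right)
        bg_gc[i] <- if (nzchar(gsub("[^ACGT]", "", bg))) gc_content(bg) else NA_real_
      }
    }
  }
  ssrs$region <- region
  ssrs$relative_position <- relpos
  ssrs$ssr_gc <- ssr_gc
  ssrs$background_gc <- bg_gc
  ssrs
}

#' Read / write the coordinate table
#'
#' TSV with columns transcript_id, length, cds_start, cds_end, is_lncRNA
#' (empty CDS fields allowed).
#'
#' @param path TSV path.
#' @param annotations annotation table to write.
#' @return annotation table (read) or the path (write).
#' @export
read_annotation_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = c("NA", ""))
  transcript_annotation(d$transcript_id, d$length, d$cds_start, d$cds_end,
                        as.logical(d$is_lncRNA))
}

#' @rdname read_annotation_tsv
#' @export
write_annotation_tsv <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
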