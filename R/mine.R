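#' SSR search criteria
#'
#' MISA-style detection thresholds.  `min_repeats_by_size` gives, for motif
#' sizes 1 through 6, the minimum number of whole repeat units a tract must
#' reach to be reported; the defaults (15, 8, 5, 4, 3, 3) make the shortest
#' reportable tract 15 bp.  `max_interruption_bp` is the largest gap allowed
#' between consecutive members of a compound SSR; the default 0 means
#' compound members must be directly adjacent (no intervening bases).
#'
#' @param min_repeats_by_size integer vector of length 6, all >= 1.
#' @param max_interruption_bp non-negative integer.
#' @return an object of class `miner_criteria`.
#' @examples
#' miner_criteria()
#' @export
miner_criteria <- function(min_repeats_by_size = c(15L, 8L, 5L, 4L, 3L, 3L),
                           max_interruption_bp = 0L) {
  min_repeats_by_size <- as.integer(min_repeats_by_size)
  if (length(min_repeats_by_size) != 6L || anyNA(min_repeats_by_size) ||
      any(min_repeats_by_size < 1L))
    stop("min_repeats_by_size must be 6 integers, all >= 1")
  max_interruption_bp <- as.integer(max_interruption_bp)
  if (length(max_interruption_bp) != 1L || is.na(max_interruption_bp) ||
      max_interruption_bp < 0L)
    stop("max_interruption_bp must be a single integer >= 0")
  structure(list(min_repeats_by_size = min_repeats_by_size,
                 max_interruption_bp = max_interruption_bp),
            class = "miner_criteria")
}

.empty_ssr_frame <- function() {
  data.frame(transcript_id = character(0), motif = character(0),
             canonical_motif = character(0), motif_size = integer(0),
             repeat_count = integer(0), start = integer(0), end = integer(0),
             tract_length = integer(0), compound_id = character(0),
             stringsAsFactors = FALSE)
}

.validate_sequence <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single string")
  sequence <- toupper(sequence)
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L)
    stop("non-IUPAC character '", substr(sequence, bad, bad),
         "' at position ", bad)
  sequence
}

#' Find perfect SSRs in one sequence
#'
#' Scans a transcript sequence for maximal uninterrupted tandem repeats of
#' primitive 1-6 bp motifs meeting the per-size minimum repeat counts.
#' Each qualifying run is reported once, at the smallest primitive repeat
#' unit (a poly-A run is never additionally reported as an AA
#' dinucleotide run).  Trailing partial repeats are truncated, so
#' `tract_length == motif_size * repeat_count` always holds.  Runs are
#' broken at any `N`.  Coordinates are 1-based and inclusive; the motif is
#' recorded as read on the transcript strand and its canonical
#' (strand-folded) class is attached.
#'
#' @param sequence a single A/C/G/T/N string.
#' @param criteria a [miner_criteria()] object.
#' @param transcript_id id recorded in the output rows.
#' @return data.frame with columns transcript_id, motif, canonical_motif,
#'   motif_size, repeat_count, start, end, tract_length, compound_id (NA
#'   here; populated by [find_compound_ssrs()]), sorted by start.
#' @examples
#' find_perfect_ssrs(paste0("G", strrep("A", 15), "G"))
#' @export
find_perfect_ssrs <- function(sequence, criteria = miner_criteria(),
                              transcript_id = "seq") {
  stopifnot(inherits(criteria, "miner_criteria"))
  sequence <- .validate_sequence(sequence)
  runs <- .ssr_runs(sequence, criteria)
  if (!length(runs$start)) return(.empty_ssr_frame())
  df <- data.frame(
    transcript_id = transcript_id,
    motif = runs$motif,
    motif_size = runs$motif_size,
    repeat_count = runs$repeat_count,
    start = runs$start,
    stringsAsFactors = FALSE
  )
  df$end <- df$start + df$motif_size * df$repeat_count - 1L
  df$tract_length <- df$motif_size * df$repeat_count
  umot <- unique(df$motif)
  df$canonical_motif <- canonicalize_motif(umot)[match(df$motif, umot)]
  df$compound_id <- NA_character_
  df <- df[order(df$start, df$motif_size), ]
  # same-motif overlaps cannot arise from maximal runs; guard regardless
  dup <- logical(nrow(df))
  if (nrow(df) > 1L) {
    for (j in 2:nrow(df)) {
      prev <- which(df$motif[seq_len(j - 1L)] == df$motif[j] &
                      df$end[seq_len(j - 1L)] >= df$start[j])
      if (length(prev)) dup[j] <- TRUE
    }
  }
  df <- df[!dup, c("transcript_id", "motif", "canonical_motif", "motif_size",
                   "repeat_count", "start", "end", "tract_length",
                   "compound_id")]
  rownames(df) <- NULL
  df
}

# core run scanner shared by find_perfect_ssrs, .has_ssr and the synthetic
# generator's verification step: maximal period-m runs of primitive motifs
# meeting the minimums, as parallel vectors (no data.frame overhead)
.ssr_runs <- function(sequence, criteria) {
  L <- nchar(sequence)
  x <- utf8ToInt(sequence)   # integer codes: fast vectorized comparisons
  N_CODE <- 78L              # "N"
  mins <- criteria$min_repeats_by_size
  motif <- character(0); size <- integer(0)
  reps <- integer(0); start <- integer(0)
  for (m in 1:6) {
    if (L < m * mins[m]) next
    i1 <- seq_len(L - m)
    eq <- x[i1] == x[i1 + m] & x[i1] != N_CODE
    r <- rle(eq)
    hits <- which(r$values & (r$lengths + m) %/% m >= mins[m])
    if (!length(hits)) next
    run_end <- cumsum(r$lengths)
    for (k in hits) {
      i <- run_end[k] - r$lengths[k] + 1L
      mo <- substr(sequence, i, i + m - 1L)
      if (!is_primitive_motif(mo)) next
      motif <- c(motif, mo); size <- c(size, m)
      reps <- c(reps, (r$lengths[k] + m) %/% m); start <- c(start, i)
    }
  }
  list(motif = motif, motif_size = size, repeat_count = reps, start = start,
       end = start + size * reps - 1L)
}

# fast predicate used by rejection sampling
.has_ssr <- function(sequence, criteria = miner_criteria()) {
  length(.ssr_runs(sequence, criteria)$start) > 0L
}

#' Group adjacent SSRs into compound SSRs
#'
#' Two or more SSRs with no intervening bases (gap <= `max_interruption_bp`)
#' form one compound SSR; maximal chains share a `compound_id`.  Member
#' records stay in the flat SSR table: compound membership is an annotation,
#' not a merge, so totals still count every perfect SSR.
#'
#' @param records SSR data.frame for one transcript, sorted by start and
#'   non-overlapping.
#' @param criteria a [miner_criteria()] object (supplies
#'   `max_interruption_bp`).
#' @param allow_overlap if `TRUE`, records overlapping by a few bases (which
#'   the miner can emit when a homopolymer run extends into a downstream
#'   tract of a different motif) are treated as adjacent instead of raising
#'   an error.
#' @return `records` with `compound_id` populated ("c1", "c2", ... per
#'   transcript) for compound members, NA elsewhere.
#' @export
find_compound_ssrs <- function(records, criteria = miner_criteria(),
                               allow_overlap = FALSE) {
  stopifnot(inherits(criteria, "miner_criteria"))
  n <- nrow(records)
  if (n == 0L) return(records)
  if (length(unique(records$transcript_id)) > 1L)
    stop("records must come from a single transcript")
  if (is.unsorted(records$start))
    stop("records must be sorted by start")
  gaps <- records$start[-1L] - records$end[-n] - 1L
  if (!allow_overlap && any(gaps < 0L))
    stop("records overlap; pass allow_overlap = TRUE to chain them")
  records$compound_id <- NA_character_
  if (n == 1L) return(records)
  linked <- gaps <= criteria$max_interruption_bp
  r <- rle(linked)
  pos <- cumsum(r$lengths) - r$lengths + 1L
  cid <- 0L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    cid <- cid + 1L
    idx <- pos[k]:(pos[k] + r$lengths[k])   # members span gap indices + 1
    records$compound_id[idx] <- paste0("c", cid)
  }
  records
}

#' Mine SSRs from a set of transcripts
#'
#' Runs [find_perfect_ssrs()] and [find_compound_ssrs()] over every
#' transcript and returns one flat table with a per-transcript `ssr_index`.
#'
#' @param transcripts named character vector of sequences, a
#'   [Biostrings::DNAStringSet], or a path to a FASTA file.
#' @param criteria a [miner_criteria()] object.
#' @return data.frame of SSR records (MISA-style table).
#' @examples
#' mine_ssrs(c(t1 = paste0(strrep("C", 20), strrep("AG", 8))))
#' @export
mine_ssrs <- function(transcripts, criteria = miner_criteria()) {
  seqs <- .as_sequence_vector(transcripts)
  res <- lapply(names(seqs), function(id) {
    df <- find_perfect_ssrs(seqs[[id]], criteria, transcript_id = id)
    if (nrow(df)) df <- find_compound_ssrs(df, criteria, allow_overlap = TRUE)
    df
  })
  out <- do.call(rbind, c(res, list(.empty_ssr_frame())))
  idx <- unlist(lapply(res, function(df) seq_len(nrow(df))), use.names = FALSE)
  out$ssr_index <- if (length(idx)) idx else integer(0)
  out <- out[, c("transcript_id", "ssr_index", "motif", "canonical_motif",
                 "motif_size", "repeat_count", "start", "end", "tract_length",
                 "compound_id")]
  rownames(out) <- NULL
  out
}

.as_sequence_vector <- function(transcripts) {
  if (inherits(transcripts, "DNAStringSet")) {
    seqs <- as.character(transcripts)
  } else if (is.character(transcripts) && length(transcripts) == 1L &&
             is.null(names(transcripts)) && file.exists(transcripts)) {
    seqs <- as.character(Biostrings::readDNAStringSet(transcripts))
  } else if (is.character(transcripts)) {
    seqs <- transcripts
  } else stop("transcripts must be a named character vector, DNAStringSet, or FASTA path")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all transcripts must be named")
  # FASTA headers may carry descriptions after the id
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) stop("duplicated transcript ids")
  seqs
}

#' Read transcripts from FASTA
#'
#' @param path FASTA file (wrapped or unwrapped, multi-record).
#' @return named character vector of uppercase sequences.
#' @export
read_transcripts <- function(path) {
  seqs <- toupper(as.character(Biostrings::readDNAStringSet(path)))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write transcripts to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_transcripts <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write / read the SSR table
#'
#' Plain TSV round-trip of the miner output.
#'
#' @param ssrs SSR data.frame.
#' @param path TSV path.
#' @return the path (write) or the table (read).
#' @export
write_ssr_tsv <- function(ssrs, path) {
  utils::write.table(ssrs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ssr_tsv
#' @export
read_ssr_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA")
}
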