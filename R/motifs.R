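#' @keywords internal
.DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Base-R reverse complement for plain character vectors of A/C/G/T motifs.
#' For whole sequences use [Biostrings::reverseComplement()]; this helper
#' exists so motif algebra does not round-trip through `XStringSet` objects.
#'
#' @param x character vector of DNA strings (A/C/G/T only).
#' @return character vector of reverse complements.
#' @examples
#' revcomp(c("AAG", "ACTTGC"))
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' All rotations of a motif
#'
#' @param motif single DNA string.
#' @return character vector of the `nchar(motif)` cyclic rotations.
#' @examples
#' motif_rotations("ACG")
#' @export
motif_rotations <- function(motif) {
  n <- nchar(motif)
  doubled <- paste0(motif, motif)
  vapply(seq_len(n), function(i) substr(doubled, i, i + n - 1L), character(1))
}

#' Is a motif primitive?
#'
#' A motif is primitive when it is not a whole-number repetition of a
#' shorter string (e.g. "AGAG" is not primitive, "AG" is).
#'
#' @param motif character vector of DNA strings.
#' @return logical vector.
#' @examples
#' is_primitive_motif(c("AG", "AGAG", "AAT"))
#' @export
is_primitive_motif <- function(motif) {
  vapply(motif, function(m) {
    n <- nchar(m)
    if (n == 0L) return(FALSE)
    for (d in seq_len(n - 1L)) {
      if (n %% d == 0L && strrep(substr(m, 1L, d), n / d) == m) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

.check_motif <- function(motif) {
  if (length(motif) != 1L || is.na(motif) || !nzchar(motif))
    stop("motif must be a single non-empty DNA string")
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif))
    stop("motif contains non-ACGT characters: ", motif)
  if (nchar(motif) > 6L)
    stop("motif longer than 6 bp: ", motif)
  if (!is_primitive_motif(motif))
    stop("motif is not primitive: ", motif)
  motif
}

#' Canonical (standardized) motif class
#'
#' Maps an SSR motif to its class representative: the lexicographically
#' smallest string among all cyclic rotations of the motif and of its
#' reverse complement.  This is the usual "standardized motif" notation in
#' microsatellite surveys, where e.g. GA, AG, CT and TC all belong to the
#' class written AG/CT, and TTC belongs to AAG/CTT.
#'
#' The result is invariant under rotation and reverse complementation of
#' the input and is idempotent.
#'
#' @param motif character vector of primitive DNA motifs, 1-6 bp.
#' @return character vector of canonical class representatives.
#' @examples
#' canonicalize_motif("GA")     # "AG"
#' canonicalize_motif("TTC")    # "AAG"
#' canonicalize_motif("ACTTGC") # "AAGTGC"
#' @export
canonicalize_motif <- function(motif) {
  vapply(motif, function(m) {
    m <- .check_motif(m)
    min(c(motif_rotations(m), motif_rotations(revcomp(m))))
  }, character(1), USE.NAMES = FALSE)
}

#' Number of canonical motif classes for a motif size
#'
#' Counts, by exhaustive enumeration, the canonical classes of primitive
#' motifs of a given size under rotation + reverse-complement equivalence.
#' Dinucleotides give the familiar four classes AT/AT, AC/GT, AG/CT and
#' CG/CG; mononucleotides give two (A/T, C/G).
#'
#' @param motif_size integer in 1..6.
#' @return integer count of classes.
#' @examples
#' count_canonical_classes(2) # 4
#' count_canonical_classes(3) # 10
#' @export
count_canonical_classes <- function(motif_size) {
  if (length(motif_size) != 1L || is.na(motif_size) ||
      motif_size != as.integer(motif_size) || motif_size < 1 || motif_size > 6)
    stop("motif_size must be a single integer in 1..6")
  motif_size <- as.integer(motif_size)
  grids <- rep(list(.DNA_BASES), motif_size)
  all_motifs <- do.call(paste0, expand.grid(grids, stringsAsFactors = FALSE))
  prim <- all_motifs[is_primitive_motif(all_motifs)]
  length(unique(canonicalize_motif(prim)))
}

#' Enumerate canonical motif classes for a motif size
#'
#' @param motif_size integer in 1..6.
#' @return sorted character vector of class representatives.
#' @export
enumerate_canonical_classes <- function(motif_size) {
  if (length(motif_size) != 1L || is.na(motif_size) ||
      motif_size != as.integer(motif_size) || motif_size < 1 || motif_size > 6)
    stop("motif_size must be a single integer in 1..6")
  grids <- rep(list(.DNA_BASES), as.integer(motif_size))
  all_motifs <- do.call(paste0, expand.grid(grids, stringsAsFactors = FALSE))
  prim <- all_motifs[is_primitive_motif(all_motifs)]
  sort(unique(canonicalize_motif(prim)))
}
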