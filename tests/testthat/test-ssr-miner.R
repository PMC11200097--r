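test_that("perfect-SSR detection respects the per-size minimum repeat counts", {
  # mono threshold boundary: 15 repeats qualify, 14 do not
  hit <- find_perfect_ssrs(paste0("G", strrep("A", 15), "G"))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$motif, "A")
  expect_equal(hit$repeat_count, 15L)
  expect_equal(c(hit$start, hit$end), c(2L, 16L))
  expect_equal(hit$tract_length, 15L)
  expect_equal(nrow(find_perfect_ssrs(strrep("A", 14))), 0L)

  # di threshold boundary
  di <- find_perfect_ssrs(strrep("AG", 8))
  expect_equal(nrow(di), 1L)
  expect_equal(di$motif_size, 2L)
  expect_equal(di$repeat_count, 8L)
  expect_equal(di$tract_length, 16L)
  expect_equal(nrow(find_perfect_ssrs(strrep("AG", 7))), 0L)

  # trailing partial repeats are truncated to whole units
  part <- find_perfect_ssrs(paste0(strrep("ACG", 5), "AC", strrep("T", 30)))
  acg <- part[part$motif == "ACG", ]
  expect_equal(acg$repeat_count, 5L)
  expect_equal(acg$end, 15L)
  expect_true(all(part$tract_length == part$motif_size * part$repeat_count))
})

test_that("runs are reported at the smallest primitive unit and broken at N", {
  # a poly-A run is never re-reported as AA / AAA ...
  mono <- find_perfect_ssrs(strrep("A", 40))
  expect_equal(nrow(mono), 1L)
  expect_equal(mono$motif_size, 1L)
  # an AT run is not a mono run (mono minimum unmet) and not an ATAT run
  at <- find_perfect_ssrs(strrep("AT", 10))
  expect_equal(at$motif, "AT")
  expect_equal(nrow(at), 1L)
  # N splits runs: 10 + 10 A's do not reach the mono minimum
  expect_equal(nrow(find_perfect_ssrs(
    paste0(strrep("A", 10), "N", strrep("A", 10)))), 0L)
  split <- find_perfect_ssrs(paste0(strrep("A", 15), "N", strrep("A", 16)))
  expect_equal(split$repeat_count, c(15L, 16L))
  # invalid characters are rejected with the offending position
  expect_error(find_perfect_ssrs("ACGTXACGT"), "position 5")
})

test_that("miner output matches the brute-force oracle on structured sequences", {
  set.seed(42)
  for (rep in 1:30) {
    s <- structured_dna(500)
    expect_same_ssrs(find_perfect_ssrs(s), oracle_find_ssrs(s))
  }
  # repeat counts and coordinates, not just keys, on one dense case
  s <- paste0(strrep("A", 16), strrep("AG", 9), rand_dna(50),
              strrep("AAG", 6), "N", strrep("ACGT", 5))
  got <- find_perfect_ssrs(s)
  exp <- oracle_find_ssrs(s)
  expect_equal(got$repeat_count[order(got$start, got$motif_size)],
               exp$repeat_count)
})

test_that("motif canonicalization folds rotations and strands into one class", {
  expect_equal(canonicalize_motif("GA"), "AG")
  expect_equal(canonicalize_motif("TTC"), "AAG")
  expect_equal(canonicalize_motif("ACTTGC"), "AAGTGC")
  expect_equal(canonicalize_motif("A"), "A")
  # class-function property over every primitive motif of sizes 1-4
  for (m in 1:4) {
    grids <- rep(list(c("A", "C", "G", "T")), m)
    mots <- do.call(paste0, expand.grid(grids, stringsAsFactors = FALSE))
    mots <- mots[is_primitive_motif(mots)]
    canon <- canonicalize_motif(mots)
    expect_equal(canonicalize_motif(canon), canon)       # idempotent
    expect_equal(canonicalize_motif(revcomp(mots)), canon)
    rot1 <- vapply(mots, function(x) motif_rotations(x)[min(2, nchar(x))],
                   character(1), USE.NAMES = FALSE)
    expect_equal(canonicalize_motif(rot1), canon)
  }
  expect_error(canonicalize_motif("AGAG"), "primitive")
  expect_error(canonicalize_motif(""), "non-empty")
})

test_that("canonical class counts per motif size are stable under enumeration", {
  expect_equal(count_canonical_classes(1), 2L)
  expect_equal(count_canonical_classes(2), 4L)
  expect_equal(count_canonical_classes(3), 10L)
  expect_equal(enumerate_canonical_classes(2), c("AC", "AG", "AT", "CG"))
  expect_equal(count_canonical_classes(4),
               length(enumerate_canonical_classes(4)))
  expect_error(count_canonical_classes(7), "1..6")
})

test_that("compound SSRs are maximal chains of gap-free neighbours", {
  mk <- function(starts, sizes, reps, motifs) {
    data.frame(transcript_id = "t", motif = motifs,
               canonical_motif = canonicalize_motif(motifs),
               motif_size = sizes, repeat_count = reps, start = starts,
               end = starts + sizes * reps - 1L,
               tract_length = sizes * reps, compound_id = NA_character_,
               stringsAsFactors = FALSE)
  }
  # adjacent pair -> one compound of 2
  two <- find_compound_ssrs(mk(c(1L, 16L), c(1L, 2L), c(15L, 8L), c("A", "AG")))
  expect_equal(two$compound_id, c("c1", "c1"))
  # 1 bp gap -> not compound under the 0-interruption default
  gap <- find_compound_ssrs(mk(c(1L, 17L), c(1L, 2L), c(15L, 8L), c("A", "AG")))
  expect_true(all(is.na(gap$compound_id)))
  # four mutually adjacent records chain into one compound
  st <- c(1L, 16L, 31L, 46L)
  four <- find_compound_ssrs(mk(st, rep(1L, 4), rep(15L, 4),
                                c("A", "C", "G", "T")))
  expect_equal(four$compound_id, rep("c1", 4))
  # configurable interruption distance
  relax <- find_compound_ssrs(mk(c(1L, 17L), c(1L, 2L), c(15L, 8L),
                                 c("A", "AG")),
                              miner_criteria(max_interruption_bp = 1))
  expect_equal(relax$compound_id, c("c1", "c1"))
  # unsorted and overlapping inputs are rejected
  expect_error(find_compound_ssrs(mk(c(16L, 1L), c(2L, 1L), c(8L, 15L),
                                     c("AG", "A"))), "sorted")
  expect_error(find_compound_ssrs(mk(c(1L, 10L), c(1L, 2L), c(15L, 8L),
                                     c("A", "AG"))), "overlap")
})

test_that("mining a FASTA file round-trips through the MISA-style table", {
  seqs <- c(t1 = paste0(rand_dna(30), strrep("AG", 8), rand_dna(30)),
            t2 = strrep("C", 20))
  fa <- tempfile(fileext = ".fasta")
  write_transcripts(seqs, fa)
  ssrs <- mine_ssrs(fa)
  expect_setequal(ssrs$transcript_id, c("t1", "t2"))
  expect_true(all(c("ssr_index", "canonical_motif") %in% names(ssrs)))
  tsv <- tempfile(fileext = ".tsv")
  write_ssr_tsv(ssrs, tsv)
  back <- read_ssr_tsv(tsv)
  expect_equal(back$start, ssrs$start)
  expect_equal(back$motif, ssrs$motif)
})
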