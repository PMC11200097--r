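# Independent oracles and fixture builders used across the suite.

# Brute-force SSR oracle: tests every (start, motif size, primitive motif)
# for a left-maximal run of whole repeats meeting the per-size minimum.
# Deliberately position-by-position, unlike the vectorized miner.
oracle_find_ssrs <- function(sequence, mins = c(15, 8, 5, 4, 3, 3)) {
  x <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  L <- length(x)
  recs <- list()
  for (m in 1:6) {
    for (i in seq_len(max(0L, L - m * mins[m] + 1L))) {
      motif <- paste(x[i:(i + m - 1L)], collapse = "")
      if (grepl("N", motif, fixed = TRUE)) next
      if (!is_primitive_motif(motif)) next
      # left-maximality: period-m property must fail just before i
      if (i > 1L && x[i - 1L] != "N" && x[i - 1L] == x[i + m - 1L]) next
      r <- 1L
      repeat {
        lo <- i + r * m
        hi <- lo + m - 1L
        if (hi > L) break
        nxt <- x[lo:hi]
        if (any(nxt == "N") || !all(nxt == x[i:(i + m - 1L)])) break
        r <- r + 1L
      }
      if (r >= mins[m])
        recs[[length(recs) + 1L]] <- data.frame(
          motif = motif, motif_size = m, repeat_count = r,
          start = i, end = i + r * m - 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(recs))
    return(data.frame(motif = character(0), motif_size = integer(0),
                      repeat_count = integer(0), start = integer(0),
                      end = integer(0)))
  out <- do.call(rbind, recs)
  out <- out[order(out$start, out$motif_size), ]
  rownames(out) <- NULL
  out
}

# Direct-formula oracle for adjusted standardized residuals
oracle_adjusted_residuals <- function(tab) {
  tab <- as.matrix(tab)
  N <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / N
  (tab - E) / sqrt(E * outer(1 - rowSums(tab) / N, 1 - colSums(tab) / N))
}

# O(n^2) pair-counting oracle for Kendall tau-b
oracle_kendall_taub <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

rand_dna <- function(L, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Random sequence enriched in genuine SSR content: random chunks
# interleaved with repeat tracts around the reporting thresholds, plus
# occasional N breaks.
structured_dna <- function(L, mins = c(15, 8, 5, 4, 3, 3)) {
  parts <- character(0)
  len <- 0L
  while (len < L) {
    if (stats::runif(1) < 0.45) {
      m <- sample(1:6, 1)
      motif <- paste(sample(c("A", "C", "G", "T"), m, replace = TRUE),
                     collapse = "")
      reps <- mins[m] + sample(-2:4, 1)
      parts <- c(parts, strrep(motif, max(1, reps)))
    } else if (stats::runif(1) < 0.08) {
      parts <- c(parts, strrep("N", sample(1:3, 1)))
    } else {
      parts <- c(parts, rand_dna(sample(10:60, 1), gc = stats::runif(1, 0.2, 0.7)))
    }
    len <- sum(nchar(parts))
  }
  substr(paste(parts, collapse = ""), 1, L)
}

expect_same_ssrs <- function(found, expected) {
  fk <- paste(found$motif, found$start, found$end)
  ek <- paste(expected$motif, expected$start, expected$end)
  expect_identical(sort(fk), sort(ek))
}

# Small standard simulation shared by detector tests: one planted
# abundance effect on lnTPM_max among null motifs.
planted_sim <- function(seed, n_transcripts = 150, beta = 1.5) {
  plan <- data.frame(motif = c("AG", "AAT"),
                     region = c("FIVE_UTR", "THREE_UTR"),
                     prob = 0.3, min_reps = c(8, 5), max_reps = c(12, 8),
                     mean_extra_copies = 0.8)
  cfg <- synthetic_config(
    n_transcripts = n_transcripts, seed = seed, ssr_plan = plan,
    expression = list(sigma0 = 1,
                      effects = data.frame(motif = "AG", region = "FIVE_UTR",
                                           characteristic = "abundance",
                                           beta = beta)))
  simulate_dataset(cfg)
}
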