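#' SSR density (counts per Mb)
#'
#' @param n_ssrs SSR count.
#' @param total_bp summed bp of the sequences or regions examined.
#' @return SSRs per megabase.
#' @examples
#' ssr_density(48295, 194653584) # 248.11 to 2 dp
#' @export
ssr_density <- function(n_ssrs, total_bp) {
  if (any(total_bp <= 0)) stop("total_bp must be positive")
  n_ssrs / (total_bp / 1e6)
}

#' SSR frequency (percent)
#'
#' 100 * n_ssrs / n_sequences; with SSR counts this is the classical
#' "frequency" statistic (it can exceed 100 when sequences carry several
#' SSRs), and with SSR-containing-sequence counts it gives the proportion
#' of SSR-bearing sequences.
#'
#' @param n_ssrs count (SSRs, or SSR-containing sequences).
#' @param n_sequences number of sequences examined.
#' @return percentage.
#' @examples
#' ssr_frequency_pct(48295, 63940) # 75.53 to 2 dp
#' @export
ssr_frequency_pct <- function(n_ssrs, n_sequences) {
  if (any(n_sequences <= 0)) stop("n_sequences must be positive")
  100 * n_ssrs / n_sequences
}

#' Chi-squared test with adjusted standardized residuals
#'
#' Pearson chi-squared test of independence on a counts table, plus per-cell
#' adjusted standardized residuals
#' (O - E) / sqrt(E (1 - row_total/N) (1 - col_total/N)), which are
#' approximately standard normal under independence and localize which
#' cells drive an enrichment signal.
#'
#' @param table counts matrix with >= 2 rows and columns and no zero
#'   marginal.
#' @return list: statistic, df, p_value, expected, residuals (adjusted
#'   standardized residuals matrix).
#' @export
chi_square_with_residuals <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) stop("need a table >= 2x2")
  if (any(table < 0)) stop("negative counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column marginal")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = ct$expected, residuals = ct$stdres)
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H across the groups, followed by Dunn's
#' pairwise z tests with Benjamini-Hochberg adjustment.  Dunn's z uses
#' mid-ranks and the tie correction
#' sigma_ij^2 = (N(N+1)/12 - sum(t^3 - t)/(12(N-1))) (1/n_i + 1/n_j).
#' One-sided mode halves the p-value in the direction given by the observed
#' rank-mean ordering (used where directional letters are reported).
#'
#' @param groups named list of numeric vectors (>= 2 groups, total n >= 3).
#' @param alternative "two.sided" (default) or "one.sided".
#' @param p_adjust multiplicity correction for the Dunn p-values.
#' @return list: statistic (H), df, p_value, dunn (data.frame with group1,
#'   group2, z, higher, p_value, adjusted_p).
#' @export
kw_dunn <- function(groups, alternative = c("two.sided", "one.sided"),
                    p_adjust = "BH") {
  alternative <- match.arg(alternative)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  if (k < 2L) stop("need >= 2 groups")
  ns <- lengths(groups)
  if (any(ns < 1L)) stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  if (N < 3L) stop("need total n >= 3")
  g <- factor(rep(names(groups), ns), levels = names(groups))
  if (length(unique(x)) == 1L) {
    kwstat <- 0; kw_p <- 1
  } else {
    kw <- stats::kruskal.test(x, g)
    kwstat <- unname(kw$statistic); kw_p <- kw$p.value
  }
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  tiecor <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  dunn <- do.call(rbind, lapply(pairs, function(p) {
    s2 <- (N * (N + 1) / 12 - tiecor) * (1 / ns[p[1]] + 1 / ns[p[2]])
    z <- if (s2 > 0) (rbar[p[1]] - rbar[p[2]]) / sqrt(s2) else 0
    data.frame(group1 = p[1], group2 = p[2], z = unname(z),
               higher = unname(ifelse(z >= 0, p[1], p[2])),
               p_value = unname(if (alternative == "two.sided")
                 2 * stats::pnorm(-abs(z)) else stats::pnorm(-abs(z))),
               stringsAsFactors = FALSE)
  }))
  dunn$adjusted_p <- stats::p.adjust(dunn$p_value, method = p_adjust)
  list(statistic = kwstat, df = k - 1L, p_value = kw_p, dunn = dunn)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall tau with its test; wraps [stats::cor.test()].
#' A constant input yields NA tau with a warning rather than an error, so
#' degenerate groupings can be flagged and skipped.
#'
#' @param x,y equal-length numeric vectors (n >= 2).
#' @return list: tau, statistic, p_value.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) stop("need equal lengths >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector; tau undefined")
    return(list(tau = NA_real_, statistic = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                         exact = FALSE))
  list(tau = unname(ct$estimate), statistic = unname(ct$statistic),
       p_value = ct$p.value)
}

#' Per-group SSR characteristics
#'
#' Summarizes an SSR table by arbitrary grouping columns: SSR counts,
#' sequence counts, abundance (SSRs per sequence), density (SSRs per Mb of
#' the grouped sequences' summed bp), frequency (100 * SSRs / sequences),
#' the proportion of SSR-bearing sequences, and mean GC / tract length.
#'
#' @param ssrs SSR table (optionally with region/ssr_gc columns from
#'   [map_regions()]).
#' @param by character vector of grouping columns in `ssrs`.
#' @param n_sequences,total_bp denominators for the grouped scope (scalar,
#'   or named vector keyed by the single `by` column's values).
#' @return data.frame of group statistics.
#' @export
group_stats <- function(ssrs, by, n_sequences, total_bp) {
  stopifnot(all(by %in% names(ssrs)))
  key <- interaction(ssrs[by], drop = TRUE, lex.order = TRUE)
  split_idx <- split(seq_len(nrow(ssrs)), key)
  rows <- lapply(names(split_idx), function(kname) {
    idx <- split_idx[[kname]]
    nseq <- if (length(n_sequences) > 1) n_sequences[[kname]] else n_sequences
    bp <- if (length(total_bp) > 1) total_bp[[kname]] else total_bp
    sub <- ssrs[idx, , drop = FALSE]
    data.frame(group = kname,
               n_sequences = nseq,
               n_ssr_sequences = length(unique(sub$transcript_id)),
               n_ssrs = nrow(sub),
               total_bp = bp,
               abundance = nrow(sub) / nseq,
               proportion_ssr_sequences =
                 length(unique(sub$transcript_id)) / nseq,
               density = ssr_density(nrow(sub), bp),
               frequency_pct = ssr_frequency_pct(nrow(sub), nseq),
               mean_gc = if ("ssr_gc" %in% names(sub))
                 mean(sub$ssr_gc, na.rm = TRUE) else NA_real_,
               mean_tract_length = mean(sub$tract_length),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Expression differences between SSR location groups
#'
#' Restricting to everywhere-expressed profiles, forms four gene groups --
#' SSRs only in the 5'-UTR, only in the CDS, only in the 3'-UTR, and
#' SSR-free -- and compares TPM_max and TPM_CV across them with
#' Kruskal-Wallis plus Dunn's post hoc test.  Genes with SSRs in more than
#' one of the three regions are excluded entirely.  Optionally repeats the
#' contrast within strata (e.g. motif_size or canonical_motif).
#'
#' @param profiles everywhere-expressed profiles (see [expressed_filter()]).
#' @param assignments [map_regions()] output.
#' @param stratify_by optional column of `assignments` to stratify on.
#' @param alternative passed to [kw_dunn()].
#' @return named list of results; each element has `groups` (sizes) and
#'   `tpm_max` / `tpm_cv` [kw_dunn()] results, or NULL with a warning when
#'   a group is empty.
#' @export
region_differential <- function(profiles, assignments, stratify_by = NULL,
                                alternative = "two.sided") {
  core <- c("FIVE_UTR", "CDS", "THREE_UTR")
  run_one <- function(assign_sub, label) {
    in_core <- assign_sub[assign_sub$region %in% core, , drop = FALSE]
    per_gene <- tapply(in_core$region, in_core$transcript_id,
                       function(r) length(unique(r)))
    single <- names(per_gene)[per_gene == 1L]
    multi <- names(per_gene)[per_gene > 1L]
    gene_region <- vapply(single, function(id)
      in_core$region[in_core$transcript_id == id][1], character(1))
    # SSR-free = expressed genes with no SSR anywhere; genes whose SSRs sit
    # in boundary/OTHER/lncRNA categories lack solid localization and are
    # dropped, as are multi-region genes
    any_ssr <- unique(assign_sub$transcript_id)
    grouping <- setNames(rep(NA_character_, nrow(profiles)),
                         profiles$transcript_id)
    grouping[!(profiles$transcript_id %in% any_ssr)] <- "SSR_FREE"
    keep <- intersect(single, profiles$transcript_id)
    grouping[keep] <- gene_region[keep]
    grouping[profiles$transcript_id %in% multi] <- NA_character_
    gsizes <- table(factor(grouping, levels = c(core, "SSR_FREE")))
    if (any(gsizes == 0)) {
      warning("empty group in region differential [", label, "]; skipped")
      return(NULL)
    }
    mk <- function(resp) {
      vals <- split(profiles[[resp]][!is.na(grouping) &
                                       !is.na(profiles[[resp]])],
                    grouping[!is.na(grouping) & !is.na(profiles[[resp]])])
      kw_dunn(vals[c(core, "SSR_FREE")], alternative = alternative)
    }
    list(groups = gsizes, tpm_max = mk("tpm_max"), tpm_cv = mk("tpm_cv"))
  }
  assignments <- assignments[assignments$transcript_id %in%
                               profiles$transcript_id, , drop = FALSE]
  out <- list(overall = run_one(assignments, "overall"))
  if (!is.null(stratify_by)) {
    stopifnot(stratify_by %in% names(assignments))
    for (lev in sort(unique(assignments[[stratify_by]]))) {
      sub <- assignments[assignments[[stratify_by]] == lev, , drop = FALSE]
      out[[paste0(stratify_by, "=", lev)]] <- run_one(sub, lev)
    }
  }
  out
}
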