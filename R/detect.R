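.CORE_REGIONS <- c("FIVE_UTR", "CDS", "THREE_UTR")

#' Build motif x region carrier groups
#'
#' For every (motif, transcribed region) combination, collects the carrier
#' transcripts and their per-transcript SSR characteristics: abundance
#' (SSR count), density (SSRs per Mb of the transcript), and summed tract
#' length (bp), together with the natural-log expression responses.  In
#' "standardized" mode motifs are canonical classes; in "actual" mode they
#' are the motifs as read on the transcript strand (whose effects can be
#' strand-specific).
#'
#' @param assignments [map_regions()] output.
#' @param profiles [profile_expression()] output.
#' @param annotations [transcript_annotation()] table (transcript lengths
#'   for the density denominator).
#' @param motif_mode "standardized" or "actual".
#' @param regions region categories to keep (default 5'-UTR, CDS, 3'-UTR).
#' @return data.frame: motif, motif_mode, region, transcript_id, abundance,
#'   density, length_bp, ln_tpm_max, ln_tpm_cv.
#' @export
build_motif_region_groups <- function(assignments, profiles, annotations,
                                      motif_mode = c("standardized", "actual"),
                                      regions = .CORE_REGIONS) {
  motif_mode <- match.arg(motif_mode)
  mcol <- if (motif_mode == "standardized") "canonical_motif" else "motif"
  a <- assignments[assignments$region %in% regions, , drop = FALSE]
  if (!nrow(a)) return(data.frame())
  key <- paste(a[[mcol]], a$region, a$transcript_id, sep = "\r")
  agg <- tapply(a$tract_length, key, function(v) c(n = length(v), bp = sum(v)))
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  df <- data.frame(
    motif = vapply(parts, `[[`, character(1), 1),
    motif_mode = motif_mode,
    region = vapply(parts, `[[`, character(1), 2),
    transcript_id = vapply(parts, `[[`, character(1), 3),
    abundance = vapply(agg, `[[`, numeric(1), "n"),
    length_bp = vapply(agg, `[[`, numeric(1), "bp"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  tlen <- annotations$length[match(df$transcript_id,
                                   annotations$transcript_id)]
  if (anyNA(tlen)) stop("carrier transcripts missing from annotations")
  df$density <- df$abundance / (tlen / 1e6)
  pidx <- match(df$transcript_id, profiles$transcript_id)
  df$ln_tpm_max <- ifelse(!is.na(pidx) & profiles$tpm_max[pidx] > 0,
                          log(profiles$tpm_max[pidx]), NA_real_)
  df$ln_tpm_cv <- ifelse(!is.na(pidx) & !is.na(profiles$tpm_cv[pidx]) &
                           profiles$tpm_cv[pidx] > 0,
                         log(profiles$tpm_cv[pidx]), NA_real_)
  df[order(df$motif, df$region, df$transcript_id),
     c("motif", "motif_mode", "region", "transcript_id", "abundance",
       "density", "length_bp", "ln_tpm_max", "ln_tpm_cv")]
}

#' Primary nonparametric filter for candidate expMotifs
#'
#' Per motif x region x response, a Mann-Whitney (Wilcoxon rank-sum) test
#' compares the expression of carrier transcripts against all profiled
#' transcripts lacking that motif in that region; when a motif occupies
#' three or more regions a Kruskal-Wallis test across regions (with Dunn's
#' post hoc) is also run.  Candidates are combinations with raw p < alpha.
#' Carrier groups smaller than `min_carriers` are skipped with a warning.
#'
#' @param groups [build_motif_region_groups()] output.
#' @param profiles [profile_expression()] output.
#' @param alpha significance threshold (default 0.05).
#' @param min_carriers smallest testable carrier group (default 3).
#' @param p_adjust optional multiplicity correction across all Mann-Whitney
#'   tests ("none" reproduces the raw-p filtering convention).
#' @return data.frame: motif, region (NA for across-region KW rows),
#'   response, test, n_carriers, statistic, p_value, candidate.
#' @export
primary_filter <- function(groups, profiles, alpha = 0.05, min_carriers = 3,
                           p_adjust = "none") {
  stopifnot(nrow(groups) > 0)
  responses <- c(tpm_max = "tpm_max", tpm_cv = "tpm_cv")
  rows <- list()
  combos <- unique(groups[, c("motif", "region")])
  for (i in seq_len(nrow(combos))) {
    mo <- combos$motif[i]; re <- combos$region[i]
    carriers <- groups$transcript_id[groups$motif == mo & groups$region == re]
    if (length(carriers) < min_carriers) {
      warning("motif ", mo, " in ", re, ": only ", length(carriers),
              " carriers; skipped")
      next
    }
    is_car <- profiles$transcript_id %in% carriers
    for (resp in names(responses)) {
      y <- profiles[[responses[[resp]]]]
      ok <- !is.na(y)
      if (sum(ok & is_car) < min_carriers || sum(ok & !is_car) < min_carriers)
        next
      wt <- suppressWarnings(stats::wilcox.test(y[ok & is_car],
                                                y[ok & !is_car]))
      rows[[length(rows) + 1L]] <- data.frame(
        motif = mo, region = re, response = resp, test = "mann_whitney",
        n_carriers = sum(ok & is_car), statistic = unname(wt$statistic),
        p_value = wt$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    out$p_value_adj <- stats::p.adjust(out$p_value, method = p_adjust)
    out$candidate <- out$p_value_adj < alpha
  }
  # across-region heterogeneity for motifs present in >= 3 regions
  kw_rows <- list()
  for (mo in unique(groups$motif)) {
    sub <- groups[groups$motif == mo, , drop = FALSE]
    regs <- names(which(table(sub$region) >= min_carriers))
    if (length(regs) < 3L) next
    for (resp in names(responses)) {
      vals <- lapply(regs, function(r) {
        ids <- sub$transcript_id[sub$region == r]
        v <- profiles[[responses[[resp]]]][profiles$transcript_id %in% ids]
        v[!is.na(v)]
      })
      names(vals) <- regs
      if (any(lengths(vals) < 2L)) next
      kd <- kw_dunn(vals)
      kw_rows[[length(kw_rows) + 1L]] <- data.frame(
        motif = mo, region = NA_character_, response = resp,
        test = "kruskal_wallis", n_carriers = sum(lengths(vals)),
        statistic = kd$statistic, p_value = kd$p_value,
        p_value_adj = kd$p_value, candidate = kd$p_value < alpha,
        stringsAsFactors = FALSE)
    }
  }
  rbind(out, do.call(rbind, kw_rows))
}

.fit_form_row <- function(fit, form, predictors, excluded = FALSE,
                          max_vif = NA_real_) {
  sm <- summary(fit)
  fstat <- sm$fstatistic
  f_p <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  co <- sm$coefficients
  data.frame(form = form, predictors = predictors,
             n = length(stats::fitted(fit)),
             r_squared = sm$r.squared, bic = stats::BIC(fit),
             f_p_value = unname(f_p),
             top_coef_p = unname(co[nrow(co), 4]),
             max_vif = max_vif, excluded = excluded,
             stringsAsFactors = FALSE)
}

#' Regression suite for one motif-region group
#'
#' Fits, per SSR characteristic (abundance, density, tract length),
#' polynomial regressions of degree 1-3 of the log response on the
#' characteristic, plus the three additive bivariate linear models over
#' characteristic pairs.  Bivariate fits with a variance inflation factor
#' above `vif_threshold` are discarded (collinearity screen).  An overfit
#' guard replaces manual curation of higher-degree fits: a degree-k
#' polynomial is excluded when its top-order coefficient is not significant
#' (p >= alpha) or its BIC improves on degree k-1 by less than 2.  The
#' optimal model is the minimum-BIC fit among surviving models whose
#' overall F-test has p < alpha.
#'
#' @param group one motif-region subset of [build_motif_region_groups()]
#'   output with > `min_carriers` rows.
#' @param response "ln_tpm_max" or "ln_tpm_cv".
#' @param alpha significance threshold.
#' @param vif_threshold VIF above which a bivariate fit is dropped.
#' @param min_carriers strict lower bound on usable carrier count.
#' @return list: `fits` (one row per fitted model), `models` (the lm
#'   objects, same order), `optimal` (row index into `fits`, or NA).
#' @export
fit_regressions <- function(group, response = c("ln_tpm_max", "ln_tpm_cv"),
                            alpha = 0.05, vif_threshold = 10,
                            min_carriers = 10) {
  response <- match.arg(response)
  y <- group[[response]]
  ok <- is.finite(y)
  group <- group[ok, , drop = FALSE]; y <- y[ok]
  if (nrow(group) <= min_carriers)
    stop("group has ", nrow(group), " usable carriers; need > ", min_carriers)
  chars <- c("abundance", "density", "length_bp")
  fits <- list(); models <- list()
  for (ch in chars) {
    x <- group[[ch]]
    if (stats::sd(x) == 0) next        # constant characteristic: singular
    prev_bic <- NA_real_
    for (d in 1:3) {
      if (length(unique(x)) <= d) break
      fit <- stats::lm(y ~ poly(x, d, raw = TRUE))
      row <- .fit_form_row(fit, c("linear", "quadratic", "cubic")[d], ch)
      if (d > 1 &&
          (is.na(row$top_coef_p) || row$top_coef_p >= alpha ||
             !isTRUE(row$bic < prev_bic - 2)))
        row$excluded <- TRUE
      prev_bic <- row$bic   # degree k is judged against degree k-1's BIC
      fits[[length(fits) + 1L]] <- row
      models[[length(models) + 1L]] <- fit
    }
  }
  pairs <- utils::combn(chars, 2, simplify = FALSE)
  for (p in pairs) {
    x1 <- group[[p[1]]]; x2 <- group[[p[2]]]
    if (stats::sd(x1) == 0 || stats::sd(x2) == 0) next
    fit <- stats::lm(y ~ x1 + x2)
    if (any(is.na(stats::coef(fit)))) next    # rank-deficient design
    vifs <- tryCatch(car::vif(fit), error = function(e) Inf)
    row <- .fit_form_row(fit, "bivariate", paste(p, collapse = "+"),
                         excluded = max(vifs) > vif_threshold,
                         max_vif = max(vifs))
    fits[[length(fits) + 1L]] <- row
    models[[length(models) + 1L]] <- fit
  }
  fits <- do.call(rbind, fits)
  optimal <- NA_integer_
  if (!is.null(fits)) {
    fits$significant <- !is.na(fits$f_p_value) & fits$f_p_value < alpha
    eligible <- which(!fits$excluded & fits$significant)
    if (length(eligible)) optimal <- eligible[which.min(fits$bic[eligible])]
  }
  list(fits = fits, models = models, optimal = optimal)
}

#' Combine primary-filter and regression evidence into expMotif calls
#'
#' A motif x region x response combination is called an expMotif only when
#' both evidence types agree: its primary (Mann-Whitney) p-value is below
#' alpha AND a surviving, significant optimal regression model exists.
#'
#' @param candidates [primary_filter()] output (Mann-Whitney rows).
#' @param fits named list of [fit_regressions()] results keyed
#'   "motif|region|response".
#' @param alpha significance threshold.
#' @return data.frame with the full evidence table: motif, region, response,
#'   n_carriers, primary_p, best_form, best_predictors, r_squared, bic,
#'   called.
#' @export
call_expmotifs <- function(candidates, fits, alpha = 0.05) {
  empty <- data.frame(motif = character(0), region = character(0),
                      response = character(0), n_carriers = integer(0),
                      primary_p = numeric(0), best_form = character(0),
                      best_predictors = character(0), r_squared = numeric(0),
                      bic = numeric(0), called = logical(0),
                      stringsAsFactors = FALSE)
  if (is.null(candidates) || !nrow(candidates)) return(empty)
  mw <- candidates[candidates$test == "mann_whitney", , drop = FALSE]
  if (!nrow(mw)) return(empty)
  rows <- lapply(seq_len(nrow(mw)), function(i) {
    key <- paste(mw$motif[i], mw$region[i], mw$response[i], sep = "|")
    fr <- fits[[key]]
    has_fit <- !is.null(fr) && !is.na(fr$optimal)
    best <- if (has_fit) fr$fits[fr$optimal, ] else NULL
    data.frame(motif = mw$motif[i], region = mw$region[i],
               response = mw$response[i], n_carriers = mw$n_carriers[i],
               primary_p = mw$p_value[i],
               best_form = if (has_fit) best$form else NA_character_,
               best_predictors = if (has_fit) best$predictors else NA_character_,
               r_squared = if (has_fit) best$r_squared else NA_real_,
               bic = if (has_fit) best$bic else NA_real_,
               called = mw$p_value[i] < alpha && has_fit,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full expMotif detection cascade
#'
#' Builds motif x region groups, applies the nonparametric primary filter,
#' runs the regression suite on candidate groups large enough for modeling,
#' and intersects the evidence.  Run in standardized mode first; actual
#' mode is conventionally restricted (via `restrict_to_classes`) to actual
#' motifs whose canonical class was a standardized candidate, with the
#' carrier-count rule strictly above `min_carriers`.
#'
#' @param assignments,profiles,annotations pipeline tables.
#' @param motif_mode "standardized" or "actual".
#' @param alpha significance threshold.
#' @param min_carriers regression requires carriers > this (default 10).
#' @param vif_threshold collinearity screen for bivariate fits.
#' @param restrict_to_classes optional canonical classes to keep (actual
#'   mode).
#' @return list: groups, candidates, fits (named list), calls.
#' @export
detect_expmotifs <- function(assignments, profiles, annotations,
                             motif_mode = "standardized", alpha = 0.05,
                             min_carriers = 10, vif_threshold = 10,
                             restrict_to_classes = NULL) {
  groups <- build_motif_region_groups(assignments, profiles, annotations,
                                      motif_mode)
  if (!is.null(restrict_to_classes)) {
    cls <- canonicalize_motif(unique(groups$motif))
    names(cls) <- unique(groups$motif)
    groups <- groups[cls[groups$motif] %in% restrict_to_classes, ,
                     drop = FALSE]
  }
  if (!nrow(groups)) stop("no motif-region groups to test")
  candidates <- suppressWarnings(primary_filter(groups, profiles,
                                                alpha = alpha))
  fits <- list()
  mw <- if (is.null(candidates))
    data.frame(motif = character(0), region = character(0),
               response = character(0)) else
    candidates[candidates$test == "mann_whitney" & candidates$candidate, ,
               drop = FALSE]
  for (i in seq_len(nrow(mw))) {
    sub <- groups[groups$motif == mw$motif[i] &
                    groups$region == mw$region[i], , drop = FALSE]
    respcol <- c(tpm_max = "ln_tpm_max", tpm_cv = "ln_tpm_cv")[mw$response[i]]
    if (sum(is.finite(sub[[respcol]])) <= min_carriers) next
    key <- paste(mw$motif[i], mw$region[i], mw$response[i], sep = "|")
    fits[[key]] <- fit_regressions(sub, respcol, alpha = alpha,
                                   vif_threshold = vif_threshold,
                                   min_carriers = min_carriers)
  }
  calls <- call_expmotifs(candidates, fits, alpha = alpha)
  list(groups = groups, candidates = candidates, fits = fits, calls = calls)
}

#' Relative-position probability density by expression level
#'
#' Kernel density estimate of SSR relative positions on (0, 1], computed
#' per expression level.  Bandwidth is Silverman's rule of thumb on the
#' level's positions; the estimate is reflected at both boundaries so mass
#' is not lost off the ends of the unit interval.  Levels with fewer than
#' `min_n` positions are skipped with a warning.
#'
#' @param positions numeric vector of relative positions in (0, 1].
#' @param levels optional parallel vector of level labels; NULL pools all.
#' @param n_grid evaluation grid size.
#' @param min_n minimum positions per curve.
#' @return list: `curves` (level, x, density) and `peaks` (level, peak
#'   position of each local maximum).
#' @export
position_density <- function(positions, levels = NULL, n_grid = 512,
                             min_n = 5) {
  if (!length(positions)) stop("no positions")
  if (any(positions <= 0 | positions > 1, na.rm = TRUE))
    stop("positions must lie in (0, 1]")
  if (is.null(levels)) levels <- rep("all", length(positions))
  curves <- list(); peaks <- list()
  for (lev in sort(unique(levels))) {
    x <- positions[levels == lev & !is.na(positions)]
    if (length(x) < min_n) {
      warning("level ", lev, ": only ", length(x), " positions; skipped")
      next
    }
    bw <- max(stats::bw.nrd0(x), 1e-3)  # degenerate (all-equal) input
    refl <- c(x, -x, 2 - x)
    d <- stats::density(refl, bw = bw, from = 0, to = 1, n = n_grid)
    y <- 3 * d$y
    curves[[lev]] <- data.frame(level = lev, x = d$x, density = y,
                                stringsAsFactors = FALSE)
    # local maxima: strictly risen into, not rising out of (plateau-safe)
    imax <- which(diff(c(-Inf, y)) > 0 & diff(c(y, -Inf)) <= 0)
    peaks[[lev]] <- data.frame(level = lev, peak = d$x[imax],
                               density = y[imax], stringsAsFactors = FALSE)
  }
  if (!length(curves)) stop("no level had enough positions")
  list(curves = do.call(rbind, c(curves, list(make.row.names = FALSE))),
       peaks = do.call(rbind, c(peaks, list(make.row.names = FALSE))))
}
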