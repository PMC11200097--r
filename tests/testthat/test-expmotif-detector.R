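test_that("motif-region groups carry per-transcript SSR characteristics", {
  assignments <- data.frame(
    transcript_id = c("a", "a", "a", "b"),
    motif = c("GA", "GA", "CT", "GA"),
    canonical_motif = c("AG", "AG", "AG", "AG"),
    tract_length = c(16, 20, 18, 24),
    region = c("FIVE_UTR", "FIVE_UTR", "FIVE_UTR", "THREE_UTR"),
    stringsAsFactors = FALSE)
  profiles <- data.frame(transcript_id = c("a", "b"),
                         tpm_max = c(100, 10), tpm_cv = c(1, 2),
                         stringsAsFactors = FALSE)
  ann <- transcript_annotation(c("a", "b"), c(1000L, 2000L))
  std <- build_motif_region_groups(assignments, profiles, ann, "standardized")
  arow <- std[std$transcript_id == "a" & std$region == "FIVE_UTR", ]
  expect_equal(arow$motif, "AG")
  expect_equal(arow$abundance, 3)          # GA, GA and CT all fold to AG
  expect_equal(arow$length_bp, 54)
  expect_equal(arow$density, 3 / (1000 / 1e6))
  expect_equal(arow$ln_tpm_max, log(100))
  act <- build_motif_region_groups(assignments, profiles, ann, "actual")
  expect_setequal(act$motif, c("GA", "CT"))
  expect_equal(act$abundance[act$motif == "GA" & act$transcript_id == "a"], 2)
})

test_that("primary filter detects a planted carrier shift and skips tiny groups", {
  set.seed(23)
  n <- 600
  ids <- sprintf("t%03d", 1:n)
  carriers <- ids[1:200]
  tmax <- stats::rlnorm(n, 2, 1)
  tmax[ids %in% carriers] <- tmax[ids %in% carriers] * exp(1)  # +1 on ln scale
  profiles <- data.frame(transcript_id = ids, tpm_max = tmax,
                         tpm_cv = stats::rgamma(n, 2), stringsAsFactors = FALSE)
  groups <- data.frame(motif = "AG", motif_mode = "standardized",
                       region = "FIVE_UTR", transcript_id = carriers,
                       abundance = 1, density = 1, length_bp = 16,
                       stringsAsFactors = FALSE)
  pf <- primary_filter(groups, profiles)
  hit <- pf[pf$response == "tpm_max" & pf$test == "mann_whitney", ]
  expect_true(hit$candidate)
  expect_lt(hit$p_value, 1e-6)
  # two carriers: below the minimum group size, skipped with a warning
  tiny <- groups[1:2, ]
  expect_warning(pf2 <- primary_filter(tiny, profiles), "skipped")
  expect_null(pf2)
})

test_that("null primary-filter candidate rate stays near alpha", {
  set.seed(29)
  n <- 300
  ids <- sprintf("t%03d", 1:n)
  profiles <- data.frame(transcript_id = ids,
                         tpm_max = stats::rlnorm(n, 2, 1),
                         tpm_cv = stats::rgamma(n, 2), stringsAsFactors = FALSE)
  groups <- do.call(rbind, lapply(1:200, function(g) {
    data.frame(motif = paste0("m", g), motif_mode = "standardized",
               region = "THREE_UTR",
               transcript_id = sample(ids, 25),
               abundance = 1, density = 1, length_bp = 15,
               stringsAsFactors = FALSE)
  }))
  pf <- primary_filter(groups, profiles)
  mw <- pf[pf$test == "mann_whitney", ]
  rate <- mean(mw$candidate)
  env <- stats::qbinom(c(0.025, 0.975), nrow(mw), 0.05) / nrow(mw)
  expect_gte(rate, env[1])
  expect_lte(rate, env[2])
})

test_that("regression suite recovers a noiseless line exactly", {
  set.seed(31)
  g <- data.frame(abundance = rep(1, 50),
                  density = stats::runif(50, 0, 4),
                  length_bp = rep(20, 50))
  g$ln_tpm_max <- 2 + 3 * g$density
  # summary.lm warns about the (intentionally) perfect fit
  fr <- suppressWarnings(fit_regressions(g, "ln_tpm_max"))
  best <- fr$fits[fr$optimal, ]
  expect_equal(best$form, "linear")
  expect_equal(best$predictors, "density")
  expect_equal(best$r_squared, 1)
  expect_equal(unname(stats::coef(fr$models[[fr$optimal]])), c(2, 3),
               tolerance = 1e-8)
  # constant characteristics are skipped, not fitted
  expect_false("abundance" %in% fr$fits$predictors[fr$fits$form == "linear"])
})

test_that("BIC prefers the quadratic when the signal is genuinely quadratic", {
  set.seed(37)
  wins <- 0L
  for (r in 1:25) {
    x <- stats::runif(400, 0, 3)
    g <- data.frame(abundance = rep(1, 400), density = x,
                    length_bp = rep(20, 400),
                    ln_tpm_max = 1 + 0.5 * x - 0.8 * x^2 +
                      stats::rnorm(400, 0, 0.1))
    fr <- fit_regressions(g, "ln_tpm_max")
    best <- fr$fits[fr$optimal, ]
    if (best$form == "quadratic" && best$predictors == "density")
      wins <- wins + 1L
  }
  expect_gte(wins, 24L)
})

test_that("collinear bivariate fits are discarded by the VIF screen", {
  set.seed(41)
  d <- stats::runif(60, 1, 5)
  g <- data.frame(abundance = stats::rpois(60, 2) + 1, density = d,
                  length_bp = 2 * d,              # perfectly collinear
                  ln_tpm_max = stats::rnorm(60))
  fr <- fit_regressions(g, "ln_tpm_max")
  biv <- fr$fits[fr$fits$form == "bivariate", ]
  dl <- biv[biv$predictors == "density+length_bp", ]
  expect_true(nrow(dl) == 0 || all(dl$excluded))
  # near-collinear pair also trips the threshold
  g$length_bp <- 2 * d + stats::rnorm(60, 0, 1e-4)
  fr2 <- fit_regressions(g, "ln_tpm_max")
  dl2 <- fr2$fits[fr2$fits$predictors == "density+length_bp", ]
  expect_true(all(dl2$excluded))
  expect_gt(dl2$max_vif[1], 10)
})

test_that("expMotif calls require both primary and regression evidence", {
  cand <- data.frame(motif = c("AG", "AT"), region = "FIVE_UTR",
                     response = "tpm_max", test = "mann_whitney",
                     n_carriers = 20, statistic = 1,
                     p_value = c(0.001, 0.001), stringsAsFactors = FALSE)
  fits <- list("AG|FIVE_UTR|tpm_max" = list(
    fits = data.frame(form = "linear", predictors = "density",
                      r_squared = 0.4, bic = 10, stringsAsFactors = FALSE),
    optimal = 1L))
  calls <- call_expmotifs(cand, fits)
  expect_true(calls$called[calls$motif == "AG"])
  expect_false(calls$called[calls$motif == "AT"])   # no significant fit
  # significant fit but failed primary: also not called
  cand$p_value <- c(0.9, 0.9)
  calls2 <- call_expmotifs(cand, fits)
  expect_false(any(calls2$called))
  # fuzzed evidence tables never produce a call without both legs
  set.seed(43)
  for (i in 1:30) {
    p <- stats::runif(1)
    has_fit <- stats::runif(1) < 0.5
    cd <- data.frame(motif = "M", region = "CDS", response = "tpm_max",
                     test = "mann_whitney", n_carriers = 15, statistic = 1,
                     p_value = p, stringsAsFactors = FALSE)
    fl <- if (has_fit) fits else list()
    names(fl) <- if (has_fit) "M|CDS|tpm_max"
    cl <- call_expmotifs(cd, fl)
    expect_equal(cl$called, p < 0.05 && has_fit)
  }
})

test_that("end-to-end detection finds the planted motif and responds to the right response", {
  sim <- planted_sim(seed = 47)
  ssrs <- mine_ssrs(sim$sequences)
  am <- map_regions(ssrs, sim$annotations, sim$sequences)
  pr <- profile_expression(sim$tpm)
  det <- detect_expmotifs(am, pr, sim$annotations)
  called <- det$calls[det$calls$called, ]
  expect_true(any(called$motif == "AG" & called$region == "FIVE_UTR" &
                    called$response == "tpm_max"))
  expect_false(any(called$motif == "AAT"))
})

test_that("position density integrates to one and recovers planted structure", {
  # degenerate input: single peak at the common position
  pd0 <- position_density(rep(0.5, 20))
  expect_equal(pd0$peaks$peak[which.max(pd0$peaks$density)], 0.5,
               tolerance = 0.01)
  # uniform positions: flat density near 1 away from the boundaries
  set.seed(53)
  u <- stats::runif(10000)
  pdu <- position_density(u)
  mid <- pdu$curves[pdu$curves$x >= 0.1 & pdu$curves$x <= 0.9, ]
  expect_true(all(abs(mid$density - 1) < 0.1))
  # mass check by trapezoidal integration
  integ <- function(cv) sum(diff(cv$x) * (head(cv$density, -1) +
                                            tail(cv$density, -1)) / 2)
  expect_equal(integ(pdu$curves), 1, tolerance = 0.02)
  # two planted clusters recovered within +/- 0.05
  x <- c(stats::rnorm(600, 0.2, 0.03), stats::rnorm(600, 0.8, 0.03))
  x <- x[x > 0 & x <= 1]
  pdm <- position_density(x)
  pk <- pdm$peaks[order(-pdm$peaks$density), ][1:2, "peak"]
  expect_equal(sort(pk), c(0.2, 0.8), tolerance = 0.05)
  # per-level curves: small levels skipped with a warning
  expect_warning(
    pdl <- position_density(c(u[1:100], 0.4, 0.5),
                            levels = c(rep("L1", 100), "L2", "L2")),
    "skipped")
  expect_setequal(unique(pdl$curves$level), "L1")
  expect_error(position_density(c(0.2, 1.2)), "\\(0, 1\\]")
})
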