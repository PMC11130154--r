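# Kaplan-Meier, log-rank, median split, maximally selected cutpoints,
# composite bulk phenotype.

test_that("KM estimate matches the hand product-limit calculation", {
  tab <- toy_survival(time = c(1, 2, 3), event = c(1, 0, 1))
  km <- km_estimate(tab)
  expect_equal(km_survival_at(km, 1), 2 / 3)
  expect_equal(km_survival_at(km, 2.5), 2 / 3)
  expect_equal(km_survival_at(km, 3), 0)
  expect_equal(km_survival_at(km, 0.5), 1)
})

test_that("KM curve is 1 everywhere with no events and non-increasing", {
  cens <- toy_survival(time = c(5, 10, 15), event = c(0, 0, 0))
  km <- km_estimate(cens)
  expect_true(all(km$surv == 1))
  co <- generate_survival_cohort(100, censoring_rate = 0.3, seed = 61)
  km2 <- km_estimate(co)
  expect_true(all(diff(km2$surv) <= 1e-12))
  expect_true(all(km2$surv >= 0 & km2$surv <= 1))
})

test_that("KM equals the empirical survival function without censoring and
           is invariant to duplicating the cohort", {
  co <- generate_survival_cohort(80, censoring_rate = 0, seed = 62)
  km <- km_estimate(co)
  at <- sort(co$time)
  expect_equal(km_survival_at(km, at), 1 - ecdf(co$time)(at))
  dbl <- rbind(co, co)
  expect_equal(km_survival_at(km_estimate(dbl), at),
               km_survival_at(km, at))
  neg <- toy_survival(time = c(-1, 2), event = c(1, 1))
  expect_error(km_estimate(neg), "non-negative")
})

test_that("log-rank matches the hand hypergeometric calculation", {
  a <- toy_survival(time = c(1, 2), event = c(1, 1))
  b <- toy_survival(time = c(3, 4), event = c(1, 1))
  lr <- logrank_test(list(a, b))
  # O_A = 2, E_A = 1/2 + 1/3, V = 1/4 + 2/9 -> chi-square = 49/17
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-9)
  expect_equal(lr$df, 1)
})

test_that("log-rank symmetry, relabelling and monotone-time invariance", {
  g <- toy_survival(time = c(1, 2, 3, 4), event = c(1, 0, 1, 1))
  expect_equal(logrank_test(list(g, g))$statistic, 0, tolerance = 1e-12)
  expect_equal(logrank_test(list(g, g))$p, 1)
  co <- generate_survival_cohort(100, hazard_ratio = 2, seed = 63)
  grp <- attr(co, "truth")$high_group
  s1 <- logrank_test(co, grp)
  s2 <- logrank_test(co, !grp)
  expect_equal(s1$statistic, s2$statistic, tolerance = 1e-9)
  co2 <- co
  co2$time <- co$time^2       # strictly monotone transform of time
  expect_equal(logrank_test(co2, grp)$statistic, s1$statistic,
               tolerance = 1e-9)
  expect_error(logrank_test(list(g, g[0, ])), "at least one patient")
})

test_that("median split: strict above-median high group, ties go low", {
  tab <- toy_survival(time = 1:4, event = rep(1, 4), cov = c(1, 2, 3, 4))
  ms <- median_split(tab, "cov")
  expect_setequal(ms$high$cov, c(3, 4))
  expect_setequal(ms$low$cov, c(1, 2))
  odd <- toy_survival(time = 1:5, event = rep(1, 5), cov = c(1, 2, 3, 4, 5))
  ms2 <- median_split(odd, "cov")
  expect_true(3 %in% ms2$low$cov)       # value at the median goes low
  expect_equal(nrow(ms2$high) + nrow(ms2$low), 5)
  const <- toy_survival(time = 1:4, event = rep(1, 4), cov = rep(2, 4))
  expect_error(median_split(const, "cov"), "degenerate")
})

test_that("cutpoint search equals survdiff-based brute force", {
  brute_force <- function(tab, covariate, minprop = 0.1) {
    x <- tab[[covariate]]
    ux <- sort(unique(x))
    cands <- (ux[-1] + ux[-length(ux)]) / 2
    best <- NULL
    for (cp in cands) {
      high <- x > cp
      if (sum(high) < minprop * nrow(tab) ||
          sum(!high) < minprop * nrow(tab)) next
      sd <- survival::survdiff(survival::Surv(time, event) ~ high, data = tab)
      z <- sqrt(unname(sd$chisq))
      if (is.nan(z)) next
      if (is.null(best) || z > best$z + 1e-12) best <- list(cp = cp, z = z)
    }
    best
  }
  for (s in 1:10) {
    co <- generate_survival_cohort(60, hazard_ratio = sample(c(1, 2, 3), 1),
                                   seed = 300 + s)
    got <- max_selected_cutpoint(co, "caf_abundance")
    want <- brute_force(co, "caf_abundance")
    expect_equal(got$cutpoint, want$cp)
    expect_equal(abs(got$statistic), want$z, tolerance = 1e-9)
  }
})

test_that("cutpoint is forced between two separated value blocks", {
  # two covariate value blocks perfectly separating early deaths from long
  # survivors: the only candidate cutpoints lie between the blocks
  tab <- toy_survival(time = c(1:10, 101:110),
                      event = rep(1, 20),
                      score = rep(c(10, 50), each = 10))
  cut <- max_selected_cutpoint(tab, "score")
  expect_gt(cut$cutpoint, 10)
  expect_lt(cut$cutpoint, 50)
  expect_lt(cut$statistic, 0)   # high-score block has fewer events early
})

test_that("minprop constrains admissible cutpoints; ties take smallest", {
  tab <- toy_survival(time = 1:10, event = rep(1, 10), score = 1:10)
  cut <- max_selected_cutpoint(tab, "score", minprop = 0.5)
  expect_equal(cut$cutpoint, 5.5)   # only the 5/5 split is admissible
  expect_equal(cut$n_high, 5)
  # mirror-symmetric design: two equal |z| maxima, smallest cutpoint wins
  sym <- toy_survival(time = c(2, 1, 1, 2), event = rep(1, 4),
                      score = c(1, 2, 3, 4))
  expect_equal(max_selected_cutpoint(sym, "score")$cutpoint, 1.5)
  const <- toy_survival(time = 1:4, event = rep(1, 4), score = rep(1, 4))
  expect_error(max_selected_cutpoint(const, "score"), "constant")
})

test_that("bulk CAF-S5 phenotype combines the three marker cutpoints", {
  tab <- toy_survival(time = 1:3, event = rep(1, 3),
                      FAP = c(5, 5, 1), PDPN = c(5, 5, 5),
                      aSMA = c(1, 5, 1))
  cuts <- list(FAP = list(cutpoint = 2), PDPN = list(cutpoint = 2),
               aSMA = list(cutpoint = 2))
  expect_equal(assign_bulk_phenotype(tab, cuts),
               c("CAF-S5", "other", "other"))
  expect_error(assign_bulk_phenotype(tab, cuts[c("FAP", "PDPN")]),
               "cutpoints")
  expect_error(assign_bulk_phenotype(tab[, -5], cuts), "lacks column")
})

test_that("five-year restriction never increases the event count", {
  for (s in 1:5) {
    co <- generate_survival_cohort(150, hazard_ratio = 2,
                                   censoring_rate = 0.2, seed = 400 + s)
    tr <- restrict_followup(co, 1826)
    expect_lte(sum(tr$event), sum(co$event))
    expect_true(all(tr$time <= 1826))
  }
})
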