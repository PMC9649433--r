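test_that("within-locus standardization and log transform behave", {
  rec <- data.frame(case_id = rep(c("c1", "c2", "c3"), 2),
                    locus = rep(c("A", "B"), each = 3),
                    snowflake = c(1, 2, 3, 10, 20, 60),
                    all_eps = c(0, 1, 2, 1, 2, 3),
                    abv_eps = c(0, 1, 1, 0, 1, 2),
                    pirche_DRB1 = c(0, 4, 9, 0, 1, 2))
  out <- normalizeRecords(rec)
  # sample-sd convention: (1,2,3) -> (-1, 0, 1)
  expect_equal(out$z_snowflake[out$locus == "A"], c(-1, 0, 1))
  for (L in c("A", "B")) {
    expect_equal(mean(out$z_snowflake[out$locus == L]), 0, tolerance = 1e-9)
    expect_equal(sd(out$z_snowflake[out$locus == L]), 1, tolerance = 1e-9)
  }
  expect_equal(out$log_pirche_DRB1, log1p(rec$pirche_DRB1))
  expect_equal(out$log_pirche_DRB1[1], 0)
  degen <- rec; degen$abv_eps <- 1
  expect_error(normalizeRecords(degen), "degenerate-locus.*abv_eps")
})

test_that("rank test matches exhaustive enumeration for small samples", {
  expect_equal(rankTest(c(1, 2, 3), c(10, 11, 12))$p.value, 0.1)
  expect_equal(rankTest(c(1, 2, 3), c(1, 2, 3))$p.value, 1.0)
  set.seed(31)
  for (i in 1:8) {
    m <- sample(3:6, 1); n <- sample(3:6, 1)
    g0 <- sample(1:12, m, replace = (i %% 2 == 0))
    g1 <- sample(1:12, n, replace = (i %% 2 == 0))
    expect_equal(rankTest(g0, g1)$p.value, oracleRankP(g0, g1),
                 tolerance = 1e-12)
  }
  expect_error(rankTest(numeric(0), 1), "non-empty")
})

test_that("rank test p decreases with group separation and ignores monotone maps", {
  set.seed(32)
  g0 <- rnorm(40)
  ps <- vapply(c(0, 0.5, 1, 2), function(shift)
    rankTest(g0, g0 + shift)$p.value, 0)
  expect_true(all(diff(ps) < 0))
  g1 <- g0 + 1
  expect_equal(rankTest(g0, g1)$p.value,
               rankTest(exp(g0), exp(g1))$p.value)
})

test_that("spearman correlation handles ranks, ties and degeneracy", {
  expect_equal(spearmanRho(1:5, 2 * (1:5) + 3)$rho, 1)
  expect_equal(spearmanRho(1:5, rev(1:5))$rho, -1)
  expect_equal(spearmanRho(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8)
  # invariant under strictly monotone transforms
  set.seed(33)
  x <- rnorm(30); y <- x + rnorm(30)
  expect_equal(spearmanRho(x, y)$rho, spearmanRho(exp(x), y^3 + y)$rho)
  expect_error(spearmanRho(rep(1, 5), 1:5), "undefined-correlation")
})

test_that("logistic odds ratios reproduce the 2x2 cross-product", {
  rec <- data.frame(outcome = c(rep(TRUE, 10), rep(FALSE, 40),
                                rep(TRUE, 5), rep(FALSE, 45)),
                    exposed = rep(c(1, 0), c(50, 50)))
  fit <- logisticUnivariable(rec, "exposed")
  expect_equal(fit$table$estimate, (10 * 45) / (40 * 5), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_error(logisticUnivariable(
    data.frame(outcome = rep(TRUE, 10), x = 1:10), "x"), "both classes")
  # null predictor at large n: OR near 1, CI covers 1
  set.seed(34)
  null <- data.frame(outcome = rbinom(2000, 1, 0.3) == 1,
                     x = rnorm(2000))
  nf <- logisticUnivariable(null, "x")
  expect_lt(nf$table$ci_low, 1)
  expect_gt(nf$table$ci_high, 1)
  # complete separation is flagged
  sep <- data.frame(outcome = rep(c(FALSE, TRUE), each = 20),
                    x = c(rnorm(20), rnorm(20) + 50))
  expect_false(logisticUnivariable(sep, "x")$converged)
})

test_that("stepwise selection lowers AIC and keeps true predictors", {
  set.seed(35)
  dropped <- 0L
  for (i in 1:20) {
    rec <- data.frame(outcome = rbinom(600, 1, 0.3) == 1,
                      noise = rnorm(600))
    st <- stepwiseAic(rec, "noise")
    expect_lte(st$aic, st$fullAic)
    expect_lte(st$aic, st$nullAic + 1e-9)
    if (!length(st$selected)) dropped <- dropped + 1L
  }
  expect_gte(dropped, 12L)  # pure noise is usually discarded

  set.seed(36)
  kept <- 0L
  for (i in 1:20) {
    x <- rnorm(600)
    rec <- data.frame(outcome = rbinom(600, 1,
                                       plogis(-1 + log(1.6) * x)) == 1,
                      signal = x, noise = rnorm(600))
    st <- stepwiseAic(rec, c("signal", "noise"))
    if ("signal" %in% st$selected) kept <- kept + 1L
  }
  expect_gte(kept, 16L)
})

test_that("cox regression matches the log-rank test and recovers effects", {
  # two groups, distinct uncensored times: score test == log-rank
  set.seed(37)
  rec <- data.frame(follow_up = c(rexp(30, 1), rexp(30, 2.5)),
                    outcome = TRUE,
                    grp = rep(c(0, 1), each = 30))
  fit <- coxRegression(rec, "grp")
  expect_gt(fit$table$estimate, 1)
  lr <- survival::survdiff(survival::Surv(follow_up, outcome) ~ grp,
                           data = rec)
  expect_equal(fit$scoreTest$p, 1 - pchisq(lr$chisq, 1), tolerance = 1e-6)
  expect_error(coxRegression(transform(rec, grp = 1), "grp"), "constant")
  expect_error(coxRegression(transform(rec, outcome = FALSE), "grp"),
               "no events")
  # parameter recovery: true log-HR 0.5, ~30% censoring, n=600
  set.seed(38)
  est <- vapply(1:50, function(i) {
    x <- rnorm(600)
    tev <- rexp(600, 0.1 * exp(0.5 * x))
    cens <- runif(600, 0, 25)
    d <- data.frame(follow_up = pmin(tev, cens), outcome = tev <= cens,
                    x = x)
    log(coxRegression(d, "x")$table$estimate)
  }, 0)
  expect_lt(abs(mean(est) - 0.5), 0.15)
})

test_that("cross-locus tables detect coupling only when it is simulated", {
  cfg0 <- simulationConfig(seed = 301, nCases = 420)
  pool <- makeAllelePool(cfg0)
  pc0 <- simulatePregnancy(pool, cfg0)
  rec0 <- normalizeRecords(poolPregnancy(pc0$scores))
  tab0 <- crossLocusTable(rec0)
  offLoc <- function(tab) {
    unlist(lapply(names(tab), function(target) {
      uni <- tab[[target]]$univariable
      vapply(setdiff(c("A", "B", "C"), target), function(L)
        uni[[paste0("snow_", L)]]$table$estimate, 0)
    }))
  }
  # without coupling, off-locus odds ratios hover near 1
  expect_lt(abs(mean(log(offLoc(tab0)))), 0.25)

  cfgC <- simulationConfig(seed = 301, nCases = 420,
                           crossLocusCoupling = 0.5)
  pcC <- simulatePregnancy(pool, cfgC)
  recC <- normalizeRecords(poolPregnancy(pcC$scores))
  tabC <- crossLocusTable(recC)
  expect_gt(mean(log(offLoc(tabC))), 0.15)
})
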