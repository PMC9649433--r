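# Statistical battery: rank tests, Spearman correlation, univariable and
# stepwise-AIC logistic regression, Cox regression, cross-locus tables.

#' Two-sample rank test (Mann-Whitney form)
#'
#' Compares score distributions between outcome-negative and -positive
#' groups. For combined n <= 20 the two-sided p-value is exact: without
#' ties via the exact Wilcoxon distribution, with ties by exhaustive
#' enumeration of all group assignments on mid-ranks. Larger samples use
#' the normal approximation with tie correction.
#'
#' @param group0,group1 numeric score vectors (both non-empty).
#' @return list with \code{statistic} (U for group0) and \code{p.value}.
#' @export
rankTest <- function(group0, group1) {
  if (!length(group0) || !length(group1))
    stop("invalid-input: both groups must be non-empty")
  m <- length(group0); n <- length(group1); N <- m + n
  r <- rank(c(group0, group1))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  hasTies <- anyDuplicated(c(group0, group1)) > 0
  if (N <= 20) {
    if (!hasTies) {
      p <- stats::wilcox.test(group0, group1, exact = TRUE)$p.value
    } else {
      # exhaustive enumeration of the C(N, m) assignments on mid-ranks
      mu <- m * n / 2
      obs <- abs(U - mu)
      combos <- utils::combn(N, m)
      Us <- colSums(matrix(r[combos], nrow = m)) - m * (m + 1) / 2
      p <- mean(abs(Us - mu) >= obs - 1e-12)
    }
  } else {
    p <- stats::wilcox.test(group0, group1, exact = FALSE,
                            correct = FALSE)$p.value
  }
  list(statistic = U, p.value = min(p, 1))
}

#' Spearman rank correlation
#'
#' Rho on mid-ranks with the asymptotic p-value; invariant under
#' strictly monotone transforms of either input.
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return list with \code{rho} and \code{p.value}.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must be equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined-correlation: constant input vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p.value = ct$p.value)
}

# Wald summary of a fitted glm/coxph on the exponentiated scale
.waldTable <- function(est, se, terms, level = 0.95) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(term = terms, estimate = exp(est),
             ci_low = exp(est - zq * se), ci_high = exp(est + zq * se),
             p = 2 * stats::pnorm(-abs(est / se)),
             stringsAsFactors = FALSE)
}

#' Univariable logistic regression
#'
#' Maximum-likelihood binomial fit of the outcome on one predictor;
#' reports the odds ratio (per unit — per 1 SD when the predictor is a
#' z-score) with Wald 95 percent CI. Complete separation is flagged, not
#' silently reported.
#'
#' @param records data.frame of pooled records.
#' @param predictor predictor column name.
#' @param outcomeCol logical/0-1 outcome column (default
#'   \code{"outcome"}).
#' @return list: \code{table} (term, estimate = OR, ci_low, ci_high, p),
#'   \code{aic}, \code{converged}.
#' @export
logisticUnivariable <- function(records, predictor,
                                outcomeCol = "outcome") {
  y <- as.integer(records[[outcomeCol]])
  if (length(unique(y)) < 2)
    stop("outcome must contain both classes")
  dat <- data.frame(y = y, x = records[[predictor]])
  fit <- suppressWarnings(stats::glm(y ~ x, data = dat,
                                     family = stats::binomial()))
  est <- stats::coef(fit)[["x"]]
  se <- sqrt(diag(stats::vcov(fit)))[["x"]]
  converged <- isTRUE(fit$converged) && abs(est) < 15 && se < 10
  tab <- .waldTable(est, se, predictor)
  list(table = tab, aic = stats::AIC(fit), converged = converged)
}

#' Stepwise model selection by AIC (binomial logistic)
#'
#' Bidirectional stepwise search starting from the full model over all
#' candidate columns; at each step the single addition or removal with
#' the lowest AIC is taken, stopping when no move lowers AIC.
#'
#' @param records data.frame of pooled records (complete cases used).
#' @param candidates character vector of candidate predictor columns.
#' @param outcomeCol outcome column name.
#' @return list: \code{selected} (term names kept), \code{table} (Wald
#'   OR table of the final model), \code{aic}, \code{fullAic},
#'   \code{nullAic}.
#' @export
stepwiseAic <- function(records, candidates, outcomeCol = "outcome") {
  if (!length(candidates)) stop("at least one candidate required")
  dat <- records[, c(outcomeCol, candidates), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  dat[[outcomeCol]] <- as.integer(dat[[outcomeCol]])
  fml <- stats::as.formula(paste(outcomeCol, "~",
                                 paste(candidates, collapse = " + ")))
  full <- suppressWarnings(stats::glm(fml, data = dat,
                                      family = stats::binomial()))
  null <- suppressWarnings(stats::glm(
    stats::as.formula(paste(outcomeCol, "~ 1")), data = dat,
    family = stats::binomial()))
  sel <- suppressWarnings(stats::step(
    full, scope = list(lower = stats::as.formula(paste(outcomeCol, "~ 1")),
                       upper = fml),
    direction = "both", trace = 0))
  terms <- setdiff(names(stats::coef(sel)), "(Intercept)")
  tab <- if (length(terms)) {
    est <- stats::coef(sel)[terms]
    se <- sqrt(diag(stats::vcov(sel)))[terms]
    .waldTable(est, se, terms)
  } else {
    data.frame(term = character(), estimate = numeric(),
               ci_low = numeric(), ci_high = numeric(), p = numeric())
  }
  list(selected = terms, table = tab, aic = stats::AIC(sel),
       fullAic = stats::AIC(full), nullAic = stats::AIC(null))
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Breslow tie handling; hazard ratios (per
#' 1 SD for z-scored predictors) with Wald 95 percent CI, plus the score
#' test (which coincides with the log-rank test for a single two-group
#' covariate without ties).
#'
#' @param records data.frame with follow-up time and event columns.
#' @param terms predictor column names.
#' @param timeCol follow-up time column (must be positive).
#' @param outcomeCol event indicator column.
#' @return list: \code{table} (term, estimate = HR, ci_low, ci_high, p),
#'   \code{scoreTest} (statistic, df, p), \code{converged}.
#' @export
coxRegression <- function(records, terms, timeCol = "follow_up",
                          outcomeCol = "outcome") {
  time <- records[[timeCol]]
  event <- as.integer(records[[outcomeCol]])
  if (any(time <= 0)) stop("follow-up must be positive")
  if (sum(event) == 0) stop("no events: Cox model undefined")
  for (tm in terms)
    if (stats::sd(records[[tm]]) == 0)
      stop("covariate ", tm, " is constant (no information)")
  dat <- records[, terms, drop = FALSE]
  dat$.time <- time; dat$.event <- event
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "breslow")
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  sct <- summary(fit)$sctest
  list(table = .waldTable(est, se, terms),
       scoreTest = list(statistic = unname(sct["test"]),
                        df = unname(sct["df"]),
                        p = unname(sct["pvalue"])),
       converged = all(is.finite(est)) && all(abs(est) < 15))
}

#' Cross-locus regression table
#'
#' For the subset of cases mismatched at all three Class I loci, builds
#' case-level predictors (the z-scored Snowflake of each locus of origin
#' and the log surrogate peptide count of each locus presented by the
#' chosen presenter) and, for each antibody target locus, runs
#' univariable logistic regressions plus the stepwise-AIC minimal model.
#'
#' @param records normalized pooled pregnancy records (long: one row per
#'   case and locus) with columns \code{case_id}, \code{locus},
#'   \code{z_snowflake}, a \code{log_pirche_<presenter>} column and
#'   \code{outcome}.
#' @param presenter presenter locus whose surrogate count is used
#'   (default \code{"DRB1"}).
#' @return named list by target locus; each element holds
#'   \code{univariable} (list by predictor) and \code{stepwise}.
#' @export
crossLocusTable <- function(records, presenter = "DRB1") {
  pirCol <- paste0("log_pirche_", presenter)
  need <- c("case_id", "locus", "z_snowflake", pirCol, "outcome")
  if (!all(need %in% names(records)))
    stop("records needs columns: ", paste(need, collapse = ", "))
  loci <- c("A", "B", "C")
  full <- names(which(table(records$case_id[records$locus %in% loci]) == 3L))
  sub <- records[records$case_id %in% full & records$locus %in% loci, ]
  if (!nrow(sub)) stop("no cases mismatched at all three loci")
  wide <- NULL
  for (L in loci) {
    d <- sub[sub$locus == L, c("case_id", "z_snowflake", pirCol, "outcome")]
    names(d) <- c("case_id", paste0("snow_", L), paste0("pir_", L),
                  paste0("csa_", L))
    wide <- if (is.null(wide)) d else merge(wide, d, by = "case_id")
  }
  preds <- c(paste0("snow_", loci), paste0("pir_", loci))
  out <- list()
  for (target in loci) {
    wide$outcome <- wide[[paste0("csa_", target)]]
    uni <- lapply(stats::setNames(preds, preds), function(p)
      logisticUnivariable(wide, p))
    stepRes <- stepwiseAic(wide, preds)
    out[[target]] <- list(univariable = uni, stepwise = stepRes)
  }
  out
}

#' Write a regression report as CSV
#'
#' One row per term: estimate, CI bounds, p, model AIC.
#'
#' @param result output of \code{\link{logisticUnivariable}},
#'   \code{\link{stepwiseAic}} or \code{\link{coxRegression}}.
#' @param file output CSV path.
#' @export
writeRegressionReport <- function(result, file) {
  tab <- result$table
  tab$aic <- if (!is.null(result$aic)) result$aic else NA_real_
  write.csv(tab, file, row.names = FALSE)
  invisible(tab)
}
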