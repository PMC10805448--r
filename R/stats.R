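#' Normality screening (Lilliefors-corrected Kolmogorov-Smirnov)
#'
#' One-sample KS test of a metric sample against a normal distribution with
#' mean and SD estimated from the sample, using the Lilliefors correction
#' (the plain KS p-value would be anti-conservative with estimated
#' parameters). Advisory only: it gates nothing downstream.
#'
#' @param values numeric sample (n >= 5, non-constant).
#' @return A list with `statistic` and `p`.
#' @export
ks_normality <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 5L) {
    stop("normality screening needs at least 5 observations", call. = FALSE)
  }
  if (sd(values) == 0) {
    stop("constant sample: normality test undefined", call. = FALSE)
  }
  fit <- nortest::lillie.test(values)
  list(statistic = unname(fit$statistic), p = unname(fit$p.value))
}

#' Covariate-adjusted two-group comparison
#'
#' Operationalises a "two-sample t test with age and gender controlled" as
#' the group term of the additive linear model `y ~ group + age + gender`
#' fitted by least squares. Returns the group coefficient's t statistic and
#' two-sided p-value, plus covariate-adjusted group means evaluated at
#' grand-mean covariates. Covariates with zero variance are dropped (the
#' model then reduces exactly to the classical pooled two-sample t test).
#'
#' @param y numeric response per subject.
#' @param group factor/character with two levels; the t statistic is for
#'   the second level relative to the first.
#' @param age numeric covariate.
#' @param gender factor/character (`male`/`female`) or 0/1 numeric.
#' @return A list of class `group_comparison`: `t`, `p`, `df`,
#'   `adjusted_means` (named by group level), `estimate` (group-2 minus
#'   group-1 adjusted difference), `dropped_covariates`.
#' @export
adjusted_group_compare <- function(y, group, age = NULL, gender = NULL) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) {
    stop("`group` must have exactly two levels", call. = FALSE)
  }
  if (any(table(group) == 0L)) stop("both groups must be non-empty",
                                    call. = FALSE)
  ok <- !is.na(y) & !is.na(group)
  covs <- list()
  if (!is.null(age)) covs$age <- as.numeric(age)
  if (!is.null(gender)) {
    g <- gender
    if (!is.numeric(g)) g <- as.numeric(as.factor(g)) - 1
    covs$gender <- g
  }
  for (v in covs) ok <- ok & !is.na(v)
  y <- y[ok]; group <- droplevels(group[ok])
  covs <- lapply(covs, function(v) v[ok])
  dropped <- names(covs)[vapply(covs, function(v) sd(v) == 0, logical(1))]
  covs <- covs[setdiff(names(covs), dropped)]
  dat <- data.frame(y = y, group = group)
  for (nm in names(covs)) dat[[nm]] <- covs[[nm]]
  form <- stats::reformulate(c("group", names(covs)), response = "y")
  fit <- lm(form, data = dat)
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design: a covariate is confounded with the group ",
         "term", call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  row <- grep("^group", rownames(sm))
  tval <- sm[row, "t value"]
  pval <- sm[row, "Pr(>|t|)"]
  cf <- coef(fit)
  base <- cf[["(Intercept)"]] +
    sum(vapply(names(covs), function(nm) cf[[nm]] * mean(covs[[nm]]),
               numeric(1)))
  lev <- levels(group)
  adj <- c(base, base + cf[[paste0("group", lev[2])]])
  names(adj) <- lev
  structure(list(t = unname(tval), p = unname(pval),
                 df = fit$df.residual, adjusted_means = adj,
                 estimate = unname(diff(adj)),
                 dropped_covariates = dropped),
            class = "group_comparison")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1) with rejection flags at
#' `q_level`.
#'
#' @param p numeric p-values in \[0, 1\].
#' @param q_level FDR level (default 0.05).
#' @return A list with `q` (adjusted p-values) and `reject` (logical).
#' @export
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.04))$q
fdr_bh <- function(p, q_level = 0.05) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- p.adjust(p, method = "BH")
  list(q = q, reject = q <= q_level)
}

#' Partial correlation
#'
#' Residualises `x` and `y` on the covariate matrix (with intercept) by
#' least squares and correlates the residuals. The p-value comes from
#' `t = r sqrt(df / (1 - r^2))` with `df = n - 2 - k` covariates.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data.frame of covariates (may be NULL
#'   for a plain Pearson correlation).
#' @return A list with `r`, `df`, `p`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates)) {
    Z <- matrix(1, n, 1)
    k <- 0L
  } else {
    Z <- as.matrix(covariates)
    if (nrow(Z) != n) stop("covariates must have one row per observation",
                           call. = FALSE)
    keep <- apply(Z, 2, function(v) sd(v) > 0)
    Z <- cbind(1, Z[, keep, drop = FALSE])
    k <- sum(keep)
  }
  if (n <= k + 2L) {
    stop("insufficient degrees of freedom: need n > covariates + 2",
         call. = FALSE)
  }
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  tol_x <- 1e-10 * max(sd(x), 1)
  tol_y <- 1e-10 * max(sd(y), 1)
  if (sd(rx) <= tol_x || sd(ry) <= tol_y) {
    stop("zero residual variance after removing covariates", call. = FALSE)
  }
  r <- cor(rx, ry)
  df <- n - 2L - k
  r_cl <- min(max(r, -1 + 1e-15), 1 - 1e-15)
  tval <- r_cl * sqrt(df / (1 - r_cl^2))
  list(r = r, df = df, p = 2 * pt(-abs(tval), df))
}
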