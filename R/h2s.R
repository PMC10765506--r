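#' One-way ANOVA battery for H2S production
#'
#' Fits the one-way model `Y_ij = mu_i + eps_ij` for mean H2S score
#' against a grouping factor (incubation-time level within an origin or
#' a species), and runs the assumption battery used to license the F
#' test: Levene's test for homoscedasticity, a one-sample
#' Kolmogorov--Smirnov test of normality on the Studentized residuals,
#' and a runs test of their independence.
#'
#' @param data data frame with at least the response and factor
#'   columns.
#' @param response name of the numeric response column (mean H2S score,
#'   0--3).
#' @param factor_col name of the factor column (e.g. the incubation-time
#'   level 1/2/3 coding days 2/5/8).
#' @param alpha significance level for the assumption verdicts.
#' @param levene_center `"mean"` for classical Levene (default) or
#'   `"median"` for the Brown--Forsythe variant.
#' @return an object of class `"h2s_anova"`: F statistic, degrees of
#'   freedom, p-value, the three assumption tests with p-values, flags
#'   at `alpha`, and the Studentized residuals.
#' @examples
#' d <- data.frame(level = rep(1:3, each = 8),
#'                 y = c(rnorm(8, 1), rnorm(8, 1.5), rnorm(8, 2)))
#' h2s_anova(d, response = "y", factor_col = "level")
#' @export
h2s_anova <- function(data, response = "response", factor_col = "group",
                      alpha = 0.05, levene_center = c("mean", "median")) {
  levene_center <- match.arg(levene_center)
  y <- data[[response]]
  g <- factor(data[[factor_col]])
  if (nlevels(g) < 2L)
    .oeno_stop("need at least two factor levels", "oenotype_bad_input")
  if (any(table(g) < 2L))
    .oeno_stop("need at least two observations per level", "oenotype_bad_input")
  fit <- lm(y ~ g)
  an <- anova(fit)
  lev <- levene_test(y, g, center = levene_center)
  sres <- studentized_residuals(y, g)
  ks <- ks_normality(sres)
  rt <- runs_test(sres)
  structure(list(
    F = an$`F value`[1L], df = c(between = an$Df[1L], within = an$Df[2L]),
    p = an$`Pr(>F)`[1L],
    levene = lev, ks = ks, runs = rt,
    assumptions = c(homoscedastic = lev$p > alpha,
                    normal_errors = ks$p > alpha,
                    independent_errors = rt$p > alpha),
    alpha = alpha, residuals = sres, fit = fit,
    factor_levels = levels(g)), class = "h2s_anova")
}

#' @export
print.h2s_anova <- function(x, ...) {
  cat("One-way ANOVA, model Y_ij = mu_i + eps_ij\n")
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g -> %s at alpha = %g\n",
              x$df[1L], x$df[2L], x$F, x$p,
              if (x$p < x$alpha) "group means differ" else "no evidence of differences",
              x$alpha))
  cat(sprintf("  Levene (homoscedasticity):      p = %.4g [%s]\n", x$levene$p,
              if (x$assumptions[1L]) "ok" else "violated"))
  cat(sprintf("  KS on Studentized residuals:    p = %.4g [%s]\n", x$ks$p,
              if (x$assumptions[2L]) "ok" else "violated"))
  cat(sprintf("  Runs test (independence):       p = %.4g [%s]\n", x$runs$p,
              if (x$assumptions[3L]) "ok" else "violated"))
  invisible(x)
}

#' Levene's test for equality of variances
#'
#' Classical (mean-centered) Levene by default; `center = "median"`
#' gives the Brown--Forsythe variant.  Delegates to
#' [car::leveneTest()].
#'
#' @param y numeric response.
#' @param g grouping factor.
#' @param center `"mean"` or `"median"`.
#' @return list with `statistic`, `df` and `p`.
#' @export
levene_test <- function(y, g, center = c("mean", "median")) {
  center <- match.arg(center)
  g <- factor(g)
  lt <- car::leveneTest(y, g, center = if (center == "mean") mean else median)
  list(statistic = lt$`F value`[1L], df = c(lt$Df[1L], lt$Df[2L]),
       p = lt$`Pr(>F)`[1L], center = center)
}

#' Studentized residuals of a one-way fit
#'
#' Externally Studentized residuals: each raw residual divided by a
#' leave-one-out estimate of the error standard deviation times
#' `sqrt(1 - h_i)`, where the leverage of an observation in a balancedly
#' parameterized one-way model is `1/n_group`.
#'
#' @param y numeric response.
#' @param g grouping factor.
#' @return numeric vector of Studentized residuals.
#' @export
studentized_residuals <- function(y, g) {
  g <- factor(g)
  if (any(table(g) < 2L))
    .oeno_stop("Studentized residuals undefined for groups of size 1",
               "oenotype_bad_input")
  rstudent(lm(y ~ g))
}

#' Kolmogorov--Smirnov normality check of residuals
#'
#' One-sample KS test of the standardized residuals against the
#' standard normal.  Mean and sd are estimated from the residuals, so
#' the p-value carries the usual Lilliefors caveat and is used as a
#' screening diagnostic, not an exact test.
#'
#' @param residuals numeric vector (at least 3 values, nonzero spread).
#' @return list with `statistic` (D) and `p`.
#' @export
ks_normality <- function(residuals) {
  if (length(residuals) < 3L)
    .oeno_stop("need at least three residuals", "oenotype_bad_input")
  s <- stats::sd(residuals)
  if (!is.finite(s) || s == 0)
    .oeno_stop("residuals have zero spread", "oenotype_bad_input")
  z <- (residuals - mean(residuals)) / s
  kt <- suppressWarnings(ks.test(z, "pnorm"))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

# exact distribution of the number of runs given n1 positive and n2
# negative signs: all arrangements equally likely under independence
.runs_pmf <- function(n1, n2) {
  rmax <- 2L * min(n1, n2) + (n1 != n2)
  r <- 2:rmax
  p <- vapply(r, function(ri) {
    if (ri %% 2L == 0L) {
      k <- ri %/% 2L
      2 * choose(n1 - 1, k - 1) * choose(n2 - 1, k - 1)
    } else {
      k <- (ri - 1L) %/% 2L
      choose(n1 - 1, k) * choose(n2 - 1, k - 1) +
        choose(n1 - 1, k - 1) * choose(n2 - 1, k)
    }
  }, numeric(1L)) / choose(n1 + n2, n1)
  setNames(p, r)
}

#' Runs test of randomness
#'
#' Counts runs of signs about the median (values equal to the median
#' are dropped).  For `n <= 20` the two-sided p-value comes from the
#' exact distribution of the number of runs given the sign counts; for
#' larger samples from the normal approximation with mean
#' `1 + 2 n1 n2 / n`.  Two-sided p is `2 * min(P(R <= r), P(R >= r))`,
#' capped at 1.
#'
#' @param x numeric vector (typically residuals, in observation order).
#' @param exact force the exact or approximate branch; default chooses
#'   exact for `n <= 20`.
#' @return list with `runs`, `n1`, `n2`, `expected`, `p` and `method`.
#' @examples
#' runs_test(c(1, 2, -1, -2, 3))$runs  # 3
#' @export
runs_test <- function(x, exact = NULL) {
  s <- sign(x - median(x))
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  if (n < 2L || n1 == 0L || n2 == 0L)
    .oeno_stop("runs test needs both signs present", "oenotype_bad_input")
  r <- 1L + sum(diff(s) != 0)
  expected <- 1 + 2 * n1 * n2 / n
  if (is.null(exact)) exact <- n <= 20L
  if (exact) {
    pmf <- .runs_pmf(n1, n2)
    rv <- as.integer(names(pmf))
    p <- min(1, 2 * min(sum(pmf[rv <= r]), sum(pmf[rv >= r])))
    method <- "exact"
  } else {
    v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
    z <- (r - expected) / sqrt(v)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(runs = r, n1 = n1, n2 = n2, expected = expected, p = p,
       method = method)
}
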