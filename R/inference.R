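# ROI-level statistics: Welch t from group summaries or raw data, Hedges g
# with the small-sample correction, Bonferroni, Pearson correlation,
# additive-model (Type II) main effects, and 2x2 chi-squared balance tests.

#' Group summary (n, mean, sample SD)
#'
#' @param n Group size (>= 2), or a numeric vector of raw values from which
#'   n, mean and SD are taken.
#' @param mean,sd Group mean and sample standard deviation (ignored when
#'   `n` is a raw vector).
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(n, mean = NULL, sd = NULL) {
  if (length(n) > 1) {
    x <- as.double(n)
    return(structure(list(n = length(x), mean = base::mean(x),
                          sd = stats::sd(x)), class = "group_summary"))
  }
  if (n < 2) stop("group size must be >= 2")
  if (!is.finite(mean) || !is.finite(sd) || sd < 0)
    stop("mean must be finite and sd nonnegative")
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

.as_summary <- function(x) {
  if (inherits(x, "group_summary")) x else group_summary(x)
}

#' Welch two-sample t test
#'
#' Computed from group summaries, so it gives identical results whether
#' called on raw vectors or on their (n, mean, sd) triples:
#' `t = (m_a - m_b) / sqrt(sd_a^2/n_a + sd_b^2/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p.
#'
#' @param a,b `group_summary` objects or raw numeric vectors.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  a <- .as_summary(a); b <- .as_summary(b)
  if (a$sd == 0 && b$sd == 0)
    stop("both group SDs are zero; Welch t undefined")
  va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
  tval <- (a$mean - b$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Hedges g standardized mean difference
#'
#' Pooled-SD standardized difference with the small-sample bias correction
#' `J = 1 - 3 / (4 df - 1)`, `df = n_a + n_b - 2`.
#'
#' @param a,b `group_summary` objects or raw numeric vectors.
#' @return Hedges g (signed like `mean_a - mean_b`).
#' @export
hedges_g <- function(a, b) {
  a <- .as_summary(a); b <- .as_summary(b)
  df <- a$n + b$n - 2
  sp <- sqrt(((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df)
  if (sp == 0) stop("pooled SD is zero; Hedges g undefined")
  J <- 1 - 3 / (4 * df - 1)
  J * (a$mean - b$mean) / sp
}

#' Bonferroni correction
#'
#' @param p Two-sided p-value in (0, 1].
#' @param m Family size (>= 1).
#' @return `min(1, m * p)`.
#' @export
bonferroni <- function(p, m) {
  if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]")
  if (any(m < 1)) stop("m must be >= 1")
  pmin(1, m * p)
}

#' ROI-level group comparison
#'
#' Welch t, Hedges g, and Bonferroni-corrected p for one contrast
#' (`a - b`; with `a` the control group, positive t means longer control
#' timescales).
#'
#' @param a,b `group_summary` objects or raw numeric vectors.
#' @param m Bonferroni family size (default 5, one test per discovery ROI).
#' @return A one-row data frame: t, df, p, p_bonf, g.
#' @export
compare_groups <- function(a, b, m = 5) {
  w <- welch_t(a, b)
  data.frame(t = w$t, df = w$df, p = w$p,
             p_bonf = bonferroni(w$p, m), g = hedges_g(a, b))
}

#' Pearson correlation with two-sided p
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance; Pearson r undefined")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Main effects in an additive linear model
#'
#' Ordinary least squares on `y ~ term1 + term2 + ...` with no
#' interactions; each term's F and p are Type II (the increase in residual
#' sum of squares from dropping that term from the full model). This is the
#' model behind both the sex ANCOVAs (group effect controlling for sex) and
#' the medication-dose main effects.
#'
#' @param y Numeric response (e.g. ROI mean INT per subject).
#' @param data Data frame of factors and/or covariates; every column is
#'   entered additively.
#' @return Data frame with one row per term: `term`, `df`, `F`, `p`.
#' @export
linear_main_effects <- function(y, data) {
  data <- as.data.frame(data)
  if (nrow(data) != length(y)) stop("y and data lengths differ")
  ok <- stats::complete.cases(data) & is.finite(y)
  y <- y[ok]; data <- data[ok, , drop = FALSE]
  for (nm in names(data))
    if (is.character(data[[nm]])) data[[nm]] <- factor(data[[nm]])
  fit <- stats::lm(y ~ ., data = data)
  X <- stats::model.matrix(fit)
  if (fit$rank < ncol(X)) {
    al <- stats::alias(fit)$Complete
    stop("rank-deficient design; collinear terms: ",
         paste(rownames(al), collapse = ", "))
  }
  if (nrow(data) <= ncol(X))
    stop("need more observations than parameters")
  dr <- stats::drop1(fit, test = "F")
  terms <- rownames(dr)[-1]
  data.frame(term = terms, df = dr$Df[-1], F = dr$`F value`[-1],
             p = dr$`Pr(>F)`[-1], row.names = NULL)
}

#' 2x2 chi-squared test of independence
#'
#' Pearson chi-squared on a 2x2 count table with the Yates continuity
#' correction by default (1 degree of freedom), via the closed form
#' `n (|ad - bc| - c0)^2 / (r1 r2 c1 c2)` with `c0 = n/2` when corrected.
#'
#' @param table 2x2 matrix of counts.
#' @param continuity Apply the Yates correction (default `TRUE`).
#' @return List with `chi2`, `p`, `df = 1`.
#' @export
chi2_2x2 <- function(table, continuity = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2)) stop("table must be 2x2")
  if (any(table < 0)) stop("counts must be nonnegative")
  n <- sum(table)
  r <- rowSums(table); c <- colSums(table)
  if (any(r == 0) || any(c == 0))
    stop("zero marginal; chi-squared undefined")
  det <- abs(table[1, 1] * table[2, 2] - table[1, 2] * table[2, 1])
  corr <- if (continuity) min(det, n / 2) else 0
  chi2 <- n * (det - corr)^2 / prod(r, c)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       df = 1L)
}
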