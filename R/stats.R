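# Study statistics: change scores, ANOVA/ANCOVA with partial eta squared,
# Bonferroni-corrected follow-up t-tests with Cohen's d, Pearson correlation,
# and the design-planning computations (eta squared to Cohen's f, noncentral-F
# power, required sample size for the repeated-measures between-factors test).

#' Early/late and pre/post change scores for one subject
#'
#' Training change is the difference between the mean PI of the last and the
#' first `n_early`/`n_late` training trials; transfer change is the
#' difference between the mean post- and pre-transfer PI.
#'
#' @param pi_series per-trial training PI (>= `n_early + n_late` trials).
#' @param pre,post pre- and post-transfer per-trial PIs.
#' @param n_early,n_late numbers of early/late trials averaged (default 10).
#' @return list with `early`, `late`, `training_change`, `pre`, `post`,
#'   `transfer_change`.
#' @export
change_scores <- function(pi_series, pre, post, n_early = 10L, n_late = 10L) {
  if (length(pi_series) < n_early + n_late)
    stop("insufficient training trials for change scores")
  if (length(pre) < 1L || length(post) < 1L)
    stop("need at least one pre and one post transfer trial")
  early <- mean(pi_series[seq_len(n_early)])
  late <- mean(pi_series[seq.int(length(pi_series) - n_late + 1L,
                                 length(pi_series))])
  list(early = early, late = late, training_change = late - early,
       pre = mean(pre), post = mean(post),
       transfer_change = mean(post) - mean(pre))
}

.cohen_d_pooled <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

#' Two-sample t-test with Cohen's d
#'
#' Classical pooled-variance two-sample t-test; Cohen's d uses the pooled SD.
#'
#' @param x,y numeric samples.
#' @return list with `t`, `df`, `p`, `d`, `mean_difference`.
#' @export
two_sample_t <- function(x, y) {
  tt <- t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = .cohen_d_pooled(x, y),
       mean_difference = mean(x) - mean(y))
}

#' Paired-samples t-test with Cohen's d
#'
#' Cohen's d is the mean difference divided by the SD of the differences.
#'
#' @param x,y paired numeric samples.
#' @return list with `t`, `df`, `p`, `d`, `mean_difference`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  tt <- t.test(x, y, paired = TRUE)
  d <- mean(x - y) / sd(x - y)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = d, mean_difference = mean(x - y))
}

#' Pearson correlation
#' @param x,y numeric vectors (>= 3 pairs, nonzero variance).
#' @return list with `r`, `df`, `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("undefined correlation: zero variance")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value)
}

#' Bonferroni adjustment
#' @param p raw p-values.
#' @param family_size number of tests in the family (default `length(p)`).
#' @return adjusted p-values, `min(1, p * family_size)`.
#' @export
bonferroni <- function(p, family_size = length(p)) {
  pmin(1, p * family_size)
}

#' One-way between-subjects ANOVA with partial eta squared and follow-ups
#'
#' Classical least-squares one-way ANOVA. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`. When the omnibus test is requested
#' with follow-ups, all pairwise comparisons are tested with t-tests using
#' the pooled ANOVA error term (error df), Bonferroni-corrected; Cohen's d is
#' the mean difference over the root mean square error.
#'
#' @param values numeric dependent variable.
#' @param group factor (or coercible) of group labels.
#' @param followups logical; run pairwise follow-up t-tests if the design has
#'   more than two levels.
#' @param family_size Bonferroni family size for the follow-ups; defaults to
#'   the number of pairwise comparisons.
#' @return list of class `anova_report`: `F`, `df1`, `df2`, `p`, `eta2p`,
#'   and (optionally) `followups` (data.frame).
#' @export
one_way_anova <- function(values, group, followups = TRUE,
                          family_size = NULL) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("degenerate design: need >= 2 groups")
  if (any(table(group) < 2L)) stop("degenerate design: need >= 2 per group")
  fit <- aov(values ~ group)
  an <- summary(fit)[[1]]
  ss_eff <- an[1, "Sum Sq"]; ss_err <- an[2, "Sum Sq"]
  mse <- an[2, "Mean Sq"]; df2 <- an[2, "Df"]
  rep <- list(F = an[1, "F value"], df1 = an[1, "Df"], df2 = df2,
              p = an[1, "Pr(>F)"],
              eta2p = ss_eff / (ss_eff + ss_err))
  if (followups && nlevels(group) >= 2L) {
    lev <- levels(group)
    pairs <- utils::combn(lev, 2L)
    if (is.null(family_size)) family_size <- ncol(pairs)
    fu <- lapply(seq_len(ncol(pairs)), function(j) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      x <- values[group == g1]; y <- values[group == g2]
      md <- mean(x) - mean(y)
      se <- sqrt(mse * (1 / length(x) + 1 / length(y)))
      tval <- md / se
      praw <- 2 * pt(abs(tval), df2, lower.tail = FALSE)
      data.frame(group1 = g1, group2 = g2, mean_difference = md, se = se,
                 t = tval, df = df2, d = md / sqrt(mse), p = praw,
                 p_bonf = min(1, praw * family_size))
    })
    rep$followups <- do.call(rbind, fu)
    rep$family_size <- family_size
  }
  structure(rep, class = "anova_report")
}

#' ANCOVA / factorial ANOVA with Type-II sums of squares
#'
#' Least-squares linear model of a dependent variable on one or more factors
#' and numeric covariates. Covariates are mean-centred before fitting.
#' Type-II sums of squares (via `car::Anova`) are used so results do not
#' depend on term order in unbalanced designs; partial eta squared is
#' reported per term.
#'
#' @param data data.frame with all variables.
#' @param dv name of the dependent-variable column.
#' @param factors character vector of factor column names.
#' @param covariates character vector of numeric covariate column names.
#' @param interactions logical; include interactions among the factors.
#' @return data.frame of class `anova_table` with one row per term: `term`,
#'   `F`, `df1`, `df2`, `p`, `eta2p`.
#' @export
ancova <- function(data, dv, factors, covariates = character(0),
                   interactions = FALSE) {
  stopifnot(all(c(dv, factors, covariates) %in% names(data)))
  d <- data
  for (f in factors) d[[f]] <- factor(d[[f]])
  for (cv in covariates) d[[cv]] <- d[[cv]] - mean(d[[cv]])
  fterm <- if (interactions && length(factors) > 1L)
    paste(factors, collapse = " * ") else paste(factors, collapse = " + ")
  rhs <- paste(c(covariates, fterm), collapse = " + ")
  fit <- lm(stats::as.formula(paste(dv, "~", rhs)), data = d)
  if (qr(stats::model.matrix(fit))$rank < ncol(stats::model.matrix(fit)))
    stop("degenerate design: rank-deficient model matrix")
  an <- car::Anova(fit, type = 2)
  terms <- rownames(an)
  keep <- terms != "Residuals"
  ss_err <- an["Residuals", "Sum Sq"]
  df2 <- an["Residuals", "Df"]
  out <- data.frame(
    term = terms[keep],
    F = an[keep, "F value"],
    df1 = an[keep, "Df"],
    df2 = df2,
    p = an[keep, "Pr(>F)"],
    eta2p = an[keep, "Sum Sq"] / (an[keep, "Sum Sq"] + ss_err)
  )
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Convert partial eta squared to Cohen's f
#' @param eta2 partial eta squared in `[0, 1)`.
#' @return Cohen's f, `sqrt(eta2 / (1 - eta2))`.
#' @export
eta2_to_f <- function(eta2) {
  if (any(eta2 < 0) || any(eta2 >= 1)) stop("eta squared must be in [0, 1)")
  sqrt(eta2 / (1 - eta2))
}

#' Convert Cohen's f to partial eta squared
#' @param f Cohen's f (>= 0).
#' @return partial eta squared, `f^2 / (1 + f^2)`.
#' @export
f_to_eta2 <- function(f) {
  if (any(f < 0)) stop("f must be >= 0")
  f^2 / (1 + f^2)
}

#' Power of the repeated-measures between-factors F-test
#'
#' Noncentral-F power of the between-subjects factor in a repeated-measures
#' design with `n_measurements` correlated measurements per subject, as in
#' G*Power's "ANOVA: repeated measures, between factors" procedure. The
#' noncentrality parameter is
#' `lambda = N * m * f^2 / (1 + (m - 1) * rho)` with numerator df
#' `n_groups - 1` and denominator df `N - n_groups`.
#'
#' @param N total sample size.
#' @param f Cohen's f of the between factor.
#' @param n_groups number of groups.
#' @param n_measurements number of repeated measurements.
#' @param corr_repeated correlation among repeated measures, in `[0, 1)`.
#' @param alpha significance level.
#' @return power in `[0, 1]`.
#' @export
rm_anova_power <- function(N, f, n_groups, n_measurements, corr_repeated,
                           alpha = 0.05) {
  stopifnot(N > n_groups, f >= 0, corr_repeated >= 0, corr_repeated < 1,
            alpha > 0, alpha < 1)
  lambda <- N * n_measurements * f^2 / (1 + (n_measurements - 1) * corr_repeated)
  df1 <- n_groups - 1
  df2 <- N - n_groups
  1 - pf(qf(1 - alpha, df1, df2), df1, df2, ncp = lambda)
}

#' Required total sample size for target power
#'
#' Smallest total N (a multiple of `n_groups`, so groups stay equal-sized)
#' whose [rm_anova_power()] reaches the target.
#'
#' @param f Cohen's f (> 0).
#' @param alpha significance level.
#' @param power target power in `(0, 1)`.
#' @param n_groups,n_measurements,corr_repeated design; see
#'   [rm_anova_power()].
#' @param max_N search cap.
#' @return smallest qualifying total N.
#' @export
required_sample_size <- function(f, alpha = 0.05, power = 0.95,
                                 n_groups = 15, n_measurements = 2,
                                 corr_repeated = 0, max_N = 1e6) {
  stopifnot(f > 0, power > 0, power < 1)
  N <- n_groups * 2  # smallest N with at least 2 per group
  while (N <= max_N) {
    if (rm_anova_power(N, f, n_groups, n_measurements, corr_repeated,
                       alpha) >= power)
      return(N)
    N <- N + n_groups
  }
  stop("no-solution: target power unreachable within N <= ", max_N)
}

#' Correlation between training change and transfer change
#'
#' Pearson correlation, over all subjects, between the training change score
#' (late minus early PI) and the transfer change score (post minus pre PI).
#'
#' @param cohort data.frame with columns `training_change` and
#'   `transfer_change` (one row per subject).
#' @return list with `r`, `df`, `p`.
#' @export
training_transfer_correlation <- function(cohort) {
  stopifnot(all(c("training_change", "transfer_change") %in% names(cohort)))
  pearson_r(cohort$training_change, cohort$transfer_change)
}

#' @importFrom stats pt var fitted residuals qnorm
NULL
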