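# Group comparisons: pooled-variance t-tests (raw data or summary
# statistics), Cohen's d, Benjamini-Hochberg FDR, channel-wise comparison
# tables, covariate-adjusted ANCOVA.

#' Pooled-variance two-sample t-test
#'
#' Student's t with `df = n1 + n2 - 2` and a two-sided p value. The pooled
#' (rather than Welch) form matches the effect-size conventions used
#' alongside it. Also available from summary statistics via
#' [independent_t_summary()]. Zero pooled variance with unequal means gives
#' an infinite t and p = 0 with a warning.
#'
#' @param x,y numeric samples (each n >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
independent_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  independent_t_summary(mean(x), stats::sd(x), length(x),
                        mean(y), stats::sd(y), length(y))
}

#' @rdname independent_t
#' @param mean1,sd1,n1,mean2,sd2,n2 per-group summary statistics.
#' @export
independent_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = df, p = 1))
    warning("zero pooled variance: t is infinite")
    return(list(t = sign(mean1 - mean2) * Inf, df = df, p = 0))
  }
  tval <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Pooled-SD standardized mean difference (Cohen's d)
#'
#' `d = (mean1 - mean2) / s_pooled` with
#' `s_pooled = sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2))`.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 per-group summary statistics.
#' @return scalar d; errors on zero pooled SD.
#' @export
cohens_d_pooled <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) stop("zero pooled SD: d undefined")
  (mean1 - mean2) / sp
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment with monotonicity enforcement; input order is
#' preserved in the output. Thin wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p vector of p values in \[0, 1\].
#' @return adjusted p values, same order and length.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Channel-wise group comparison of a nodal metric
#'
#' One pooled-variance t-test per node/channel between the two groups'
#' subject-level metric values, Cohen's d, and BH-adjusted p values across
#' the channel family. Nodes missing in more than half of either group's
#' subjects are flagged unreliable.
#'
#' @param group1,group2 subject x node matrices of a nodal metric (e.g.
#'   nodal local efficiency at one sparsity).
#' @param metric metric name recorded in the output.
#' @param alpha significance level applied to `p_fdr` for the `significant`
#'   column.
#' @return data.frame with one row per node: means, SDs, t, df, p, p_fdr,
#'   cohens_d, significant, unreliable.
#' @export
channelwise_compare <- function(group1, group2, metric = "eloc_nodal",
                                alpha = 0.05) {
  group1 <- as.matrix(group1); group2 <- as.matrix(group2)
  stopifnot(ncol(group1) == ncol(group2))
  nnode <- ncol(group1)
  rows <- lapply(seq_len(nnode), function(j) {
    x <- group1[, j]; y <- group2[, j]
    unreliable <- mean(is.na(x)) > 0.5 || mean(is.na(y)) > 0.5
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2)
      return(data.frame(metric = metric, node = j, mean1 = NA, sd1 = NA,
                        mean2 = NA, sd2 = NA, t = NA, df = NA, p = NA,
                        cohens_d = NA, unreliable = TRUE))
    tt <- independent_t(x, y)
    d <- tryCatch(cohens_d_pooled(mean(x), stats::sd(x), length(x),
                                  mean(y), stats::sd(y), length(y)),
                  error = function(e) 0)
    data.frame(metric = metric, node = j,
               mean1 = mean(x), sd1 = stats::sd(x),
               mean2 = mean(y), sd2 = stats::sd(y),
               t = tt$t, df = tt$df, p = tt$p, cohens_d = d,
               unreliable = unreliable)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p)
  out$significant <- !is.na(out$p_fdr) & out$p_fdr < alpha
  out[, c("metric", "node", "mean1", "sd1", "mean2", "sd2", "t", "df",
          "p", "p_fdr", "cohens_d", "significant", "unreliable")]
}

#' One-way ANCOVA for a group effect with covariates
#'
#' Linear-model decomposition with Type II sums of squares: the group F is
#' the extra-sum-of-squares test of the group term after all covariates.
#' Partial eta squared is `SS_group / (SS_group + SS_error)`. Per-covariate
#' F tests (each adjusted for all other terms) are reported alongside.
#'
#' @param outcome numeric response.
#' @param group two-level factor (or coercible).
#' @param covariates data.frame (or named list) of numeric/logical
#'   covariate columns.
#' @return list with `F`, `p`, `partial_eta_sq`, `df`, and `covariate_tests`
#'   (data.frame of per-covariate F and p).
#' @export
ancova <- function(outcome, group, covariates) {
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  group <- factor(group)
  stopifnot(nlevels(group) == 2,
            length(outcome) > ncol(covariates) + 2)
  dat <- data.frame(.y = outcome, .g = group, covariates)
  cn <- colnames(covariates)
  full <- stats::lm(stats::reformulate(c(cn, ".g"), ".y"), data = dat)
  if (any(is.na(stats::coef(full)))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))]
    stop("collinear model terms: ", paste(bad, collapse = ", "))
  }
  red <- stats::lm(stats::reformulate(cn, ".y"), data = dat)
  ss_err <- sum(stats::residuals(full)^2)
  ss_grp <- sum(stats::residuals(red)^2) - ss_err
  df_err <- stats::df.residual(full)
  Fg <- (ss_grp / 1) / (ss_err / df_err)
  cov_tests <- do.call(rbind, lapply(cn, function(v) {
    redv <- stats::lm(stats::reformulate(c(setdiff(cn, v), ".g"), ".y"),
                      data = dat)
    ssv <- sum(stats::residuals(redv)^2) - ss_err
    Fv <- (ssv / 1) / (ss_err / df_err)
    data.frame(covariate = v, F = Fv,
               p = stats::pf(Fv, 1, df_err, lower.tail = FALSE))
  }))
  list(F = Fg, p = stats::pf(Fg, 1, df_err, lower.tail = FALSE),
       partial_eta_sq = ss_grp / (ss_grp + ss_err),
       df = c(1, df_err), covariate_tests = cov_tests)
}
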