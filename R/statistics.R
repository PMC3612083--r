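#' Welch's unequal-variance t-test between two per-bead samples
#'
#' Two-tailed t-test assuming unequal variances (the spreadsheet convention
#' used for this assay): Welch's t statistic with Welch-Satterthwaite
#' degrees of freedom and a two-tailed p from the t distribution. No
#' multiple-testing correction is applied; the assay reports pairwise tests
#' only.
#'
#' @param a,b numeric vectors of per-bead affinities (length >= 2 each,
#'   non-degenerate).
#' @return A list with \code{t}, \code{df} and \code{p}.
#' @export
welch_ttest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs >= 2 observations", call. = FALSE)
  if (sd(a) == 0 && sd(b) == 0)
    stop("degenerate samples: both have zero variance", call. = FALSE)
  ht <- t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Ordinary least-squares line with R-squared
#'
#' Linear fit of output signal against input, as used to verify the assay's
#' linear input-output relationship. \code{R2 = 1 - SS_res / SS_tot}; for a
#' constant response (SS_tot = 0) the fit is a flat line and R-squared is 0
#' by convention.
#'
#' @param x,y numeric vectors of equal length >= 2; \code{x} not constant.
#' @return A list with \code{slope}, \code{intercept}, \code{r_squared}.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2", call. = FALSE)
  if (sd(x) == 0) stop("constant x: slope undefined", call. = FALSE)
  fit <- lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(fit$residuals^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2)
}

#' Fold change between two conditions
#'
#' @param a,b [ibrp_affinity()] results, or bare affinity means.
#' @return \code{mean(a) / mean(b)}.
#' @export
fold_change <- function(a, b) {
  ma <- if (inherits(a, "affinity_result")) a$affinity_mean else a
  mb <- if (inherits(b, "affinity_result")) b$affinity_mean else b
  if (mb == 0) stop("division by zero mean in fold change", call. = FALSE)
  ma / mb
}

#' Summary record for one condition
#'
#' The per-condition report row used in figures: mean, standard deviation
#' (n-1 denominator), bead count n and the relative (max-scaled) affinity.
#'
#' @param result an [ibrp_affinity()] result.
#' @return One-row data frame with \code{condition_id}, \code{affinity_mean},
#'   \code{affinity_sd}, \code{n}, \code{relative_affinity}.
#' @export
summarize_condition <- function(result) {
  stopifnot(inherits(result, "affinity_result"))
  data.frame(condition_id = result$condition_id,
             affinity_mean = result$affinity_mean,
             affinity_sd = result$affinity_sd,
             n = result$n,
             relative_affinity = result$relative_affinity)
}

#' All pairwise condition comparisons
#'
#' Fold change and Welch t-test for every ordered pair of conditions
#' (each unordered pair once, first vs second in list order).
#'
#' @param results list of [ibrp_affinity()] results.
#' @return Data frame with \code{condition_a}, \code{condition_b},
#'   \code{fold_change}, \code{t}, \code{df}, \code{p}.
#' @export
compare_conditions <- function(results) {
  stopifnot(length(results) >= 2L)
  idx <- utils::combn(length(results), 2L)
  rows <- apply(idx, 2L, function(ij) {
    a <- results[[ij[1]]]; b <- results[[ij[2]]]
    ht <- welch_ttest(a$per_bead, b$per_bead)
    data.frame(condition_a = a$condition_id, condition_b = b$condition_id,
               fold_change = fold_change(a, b),
               t = ht$t, df = ht$df, p = ht$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
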