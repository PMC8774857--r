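#' Per-variant Wald ratio estimates
#'
#' The Wald ratio divides the variant-outcome association by the
#' variant-exposure association; its standard error uses first-order terms of
#' the delta expansion only, `se_y / |beta_x|`, so exposure uncertainty is
#' ignored. Weights are the inverse squared standard errors.
#'
#' @param h A [harmonise()] result (or data frame with `rsid`, `beta_x`,
#'   `se_x`, `beta_y`, `se_y`).
#' @return Data frame of class `ratio_estimates`: `rsid`, `theta`, `se_theta`,
#'   `weight`.
#' @export
#' @examples
#' h <- data.frame(rsid = "rs1", beta_x = 0.1, se_x = 0.01,
#'                 beta_y = -0.05, se_y = 0.02)
#' wald_ratios(h) # theta = -0.5, se_theta = 0.2
wald_ratios <- function(h) {
  stopifnot(all(c("rsid", "beta_x", "beta_y", "se_y") %in% names(h)))
  if (any(h$beta_x == 0)) {
    stop("degenerate instrument: beta_x = 0 for ",
         paste(h$rsid[h$beta_x == 0], collapse = ", "), call. = FALSE)
  }
  se_theta <- h$se_y / abs(h$beta_x)
  out <- data.frame(rsid = h$rsid, theta = h$beta_y / h$beta_x,
                    se_theta = se_theta, weight = se_theta^-2,
                    stringsAsFactors = FALSE)
  class(out) <- c("ratio_estimates", "data.frame")
  out
}

new_mr_estimate <- function(method, estimate, se, pval, n_snps,
                            q = NA_real_, q_pval = NA_real_, phi = NA_real_,
                            ci_low = estimate - Z975 * se,
                            ci_high = estimate + Z975 * se) {
  structure(list(method = method, estimate = estimate, se = se,
                 ci_low = ci_low, ci_high = ci_high, pval = pval,
                 n_snps = n_snps, q = q, q_pval = q_pval, phi = phi),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: %.4f (SE %.4f, 95%% CI %.4f to %.4f), p = %.3g, J = %d\n",
              x$method, x$estimate, x$se, x$ci_low, x$ci_high, x$pval, x$n_snps))
  if (!is.na(x$q)) {
    cat(sprintf("  Cochran's Q = %.3f (p = %.3g), overdispersion phi = %.3f\n",
                x$q, x$q_pval, x$phi))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, estimate = x$estimate, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             n_snps = x$n_snps, q = x$q, q_pval = x$q_pval, phi = x$phi,
             stringsAsFactors = FALSE)
}

#' Multiplicative random-effects inverse-variance weighted estimate
#'
#' Pools Wald ratios by their inverse variances. Heterogeneity beyond chance
#' inflates the standard error through the multiplicative overdispersion
#' factor `phi = max(1, Q / (J - 1))`, so the estimate equals the fixed-effect
#' IVW estimate while its SE is never anti-conservative. The pooled estimate is
#' algebraically identical to the slope of zero-intercept weighted least
#' squares of `beta_y` on `beta_x` with weights `se_y^-2`. P-values use the
#' standard normal reference.
#'
#' @param ratios A [wald_ratios()] result.
#' @return An `mr_estimate` (method `"IVW-MRE"`). `q` and `q_pval` are `NA`
#'   when only one variant is supplied.
#' @export
mr_ivw <- function(ratios) {
  J <- nrow(ratios)
  if (is.null(J) || J < 1L) stop("at least one ratio required", call. = FALSE)
  w <- ratios$weight
  est <- sum(w * ratios$theta) / sum(w)
  if (J >= 2L) {
    q <- sum(w * (ratios$theta - est)^2)
    q_pval <- stats::pchisq(q, df = J - 1, lower.tail = FALSE)
    phi <- max(1, q / (J - 1))
  } else {
    q <- NA_real_; q_pval <- NA_real_; phi <- 1
  }
  se <- sqrt(phi / sum(w))
  pval <- 2 * stats::pnorm(-abs(est / se))
  new_mr_estimate("IVW-MRE", est, se, pval, J, q = q, q_pval = q_pval,
                  phi = phi)
}

# Weighted-median interpolation of ordered ratios at cumulative weight 0.5
weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1L] >= 0.5) return(theta[1L])
  if (s[length(s)] <= 0.5) return(theta[length(s)])
  stats::approx(s, theta, xout = 0.5, ties = "ordered")$y
}

median_boot <- function(ratios, n_boot, seed, weighted) {
  if (n_boot < 2L) stop("n_boot must be at least 2", call. = FALSE)
  theta <- ratios$theta; se <- ratios$se_theta; J <- length(theta)
  with_seed(seed, {
    draws <- matrix(stats::rnorm(n_boot * J, mean = theta, sd = se),
                    nrow = J, ncol = n_boot)
    reps <- apply(draws, 2L, function(th) {
      if (weighted) weighted_median_point(th, ratios$weight)
      else stats::median(th)
    })
    stats::sd(reps)
  })
}

#' Simple median estimate
#'
#' The sample median of the Wald ratios (midpoint convention for even J),
#' consistent when at least half of the variants are valid instruments. The
#' standard error is a parametric bootstrap: each replicate redraws every ratio
#' from `Normal(theta_j, se_theta_j^2)` and takes the median; the SE is the SD
#' of the replicate medians. CI and p-value use the normal reference.
#'
#' @param ratios A [wald_ratios()] result. Fewer than 3 variants triggers a
#'   warning (the median then offers little robustness).
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap stream.
#' @return An `mr_estimate` (method `"simple-median"`).
#' @export
mr_simple_median <- function(ratios, n_boot = 1000, seed) {
  J <- nrow(ratios)
  if (J < 1L) stop("at least one ratio required", call. = FALSE)
  if (J < 3L) warning("simple median with J < 3 offers little robustness",
                      call. = FALSE)
  est <- stats::median(ratios$theta)
  se <- median_boot(ratios, n_boot, seed, weighted = FALSE)
  new_mr_estimate("simple-median", est, se,
                  2 * stats::pnorm(-abs(est / se)), J)
}

#' Weighted median estimate
#'
#' Ratios are ordered and the weighted empirical CDF (cumulative normalised
#' weight minus half the variant's own weight) is linearly interpolated at
#' one half; consistent when valid variants carry at least 50% of the total
#' weight. Bootstrap SE as in [mr_simple_median()], with weights held at their
#' observed values (`se_theta` is fixed across replicates).
#'
#' @inheritParams mr_simple_median
#' @return An `mr_estimate` (method `"weighted-median"`).
#' @export
mr_weighted_median <- function(ratios, n_boot = 1000, seed) {
  J <- nrow(ratios)
  if (J < 1L) stop("at least one ratio required", call. = FALSE)
  if (J < 3L) warning("weighted median with J < 3 offers little robustness",
                      call. = FALSE)
  est <- weighted_median_point(ratios$theta, ratios$weight)
  se <- median_boot(ratios, n_boot, seed, weighted = TRUE)
  new_mr_estimate("weighted-median", est, se,
                  2 * stats::pnorm(-abs(est / se)), J)
}

#' MR-Egger regression
#'
#' Weighted least squares of the variant-outcome effects on the
#' variant-exposure effects with an unconstrained intercept, weights `se_y^-2`,
#' after orienting every variant so `beta_x >= 0`. Under the InSIDE assumption
#' the slope estimates the causal effect and the intercept the average
#' directional pleiotropic effect; the intercept's p-value is the pleiotropy
#' test. Standard errors are inflated by `sqrt(max(1, RSS_w / (J - 2)))` and
#' referred to the t distribution with `J - 2` degrees of freedom.
#'
#' @param h A [harmonise()] result with at least 3 variants.
#' @return List with elements `slope` and `intercept`, each an `mr_estimate`
#'   (methods `"Egger-slope"`, `"Egger-intercept"`); both carry the shared
#'   overdispersion factor `phi`.
#' @export
mr_egger <- function(h) {
  J <- nrow(h)
  if (J < 3L) stop("MR-Egger requires at least 3 variants", call. = FALSE)
  flip <- h$beta_x < 0
  bx <- ifelse(flip, -h$beta_x, h$beta_x)
  by <- ifelse(flip, -h$beta_y, h$beta_y)
  w <- h$se_y^-2
  if (stats::sd(bx) == 0) {
    stop("singular MR-Egger fit: all beta_x identical", call. = FALSE)
  }
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  coef <- as.vector(solve(XtWX, crossprod(X, w * by)))
  resid <- by - as.vector(X %*% coef)
  rss_w <- sum(w * resid^2)
  phi <- max(1, rss_w / (J - 2))
  vc <- phi * solve(XtWX)
  se <- unname(sqrt(diag(vc)))
  tq <- stats::qt(0.975, df = J - 2)
  pvals <- 2 * stats::pt(-abs(coef / se), df = J - 2)
  mk <- function(i, method) {
    new_mr_estimate(method, coef[i], se[i], pvals[i], J, phi = phi,
                    ci_low = coef[i] - tq * se[i],
                    ci_high = coef[i] + tq * se[i])
  }
  list(slope = mk(2L, "Egger-slope"), intercept = mk(1L, "Egger-intercept"))
}

#' Cochran's Q heterogeneity statistic
#'
#' Weighted sum of squared deviations of the per-variant ratios from the
#' pooled estimate; chi-square with `J - 1` degrees of freedom under
#' homogeneity. Excess heterogeneity may indicate outliers and, in turn,
#' horizontal pleiotropy.
#'
#' @param ratios A [wald_ratios()] result.
#' @param pooled An `mr_estimate` (typically [mr_ivw()]) supplying the pooled
#'   estimate.
#' @return List `q`, `q_pval`, or both `NA` when fewer than 2 variants.
#' @export
cochran_q <- function(ratios, pooled) {
  J <- nrow(ratios)
  if (J < 2L) return(list(q = NA_real_, q_pval = NA_real_))
  q <- sum(ratios$weight * (ratios$theta - pooled$estimate)^2)
  list(q = q, q_pval = stats::pchisq(q, df = J - 1, lower.tail = FALSE))
}
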