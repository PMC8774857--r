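# Zero-intercept WLS slope of by on bx with weights w, leaving out variant j
# for every j at once: (Sxy - w_j bx_j by_j) / (Sxx - w_j bx_j^2)
loo_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO global, outlier and distortion tests
#'
#' Residual-sum-of-squares simulation test for horizontal pleiotropy. For each
#' variant the leave-one-out IVW slope is computed and the variant's weighted
#' squared residual about it accumulated into the observed RSS. The global
#' test compares this RSS with its parametric-simulation distribution (each
#' replicate redraws the exposure effects about their observed values and the
#' outcome effects about the leave-one-out fitted values). The outlier test
#' compares each variant's own squared residual with its simulated
#' counterparts, Bonferroni-adjusted over the J variants. When outliers are
#' flagged, an outlier-corrected IVW estimate is computed and the distortion
#' test compares the resulting shift in the estimate against the shifts from
#' removing random variant sets of the same size.
#'
#' All Monte-Carlo p-values use the add-one estimator `(1 + exceedances) /
#' (n_sim + 1)`, bounded below by `1/(n_sim + 1)`.
#'
#' @param h A [harmonise()] result with at least 4 variants (the leave-one-out
#'   fit needs 3 remaining). At exactly 4 variants a warning notes the limited
#'   outlier-detection power.
#' @param n_sim Number of simulation replicates (default 1000, minimum 100).
#' @param outlier_alpha Threshold applied to the Bonferroni-adjusted per-SNP
#'   outlier p-values (default 0.05).
#' @param seed Integer seed; identical seed and inputs give identical results.
#' @param n_distortion Random outlier-sets drawn for the distortion test
#'   (default 1000).
#' @return An object of class `presso_result`: `rss_obs`, `global_pval`,
#'   `per_snp` (rsid, residual, outlier_pval), `outlier_set`, `corrected` (an
#'   `mr_estimate` or `NULL`), `distortion_pval` (`NA` when no outliers),
#'   `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed,
                      n_distortion = 1000) {
  J <- nrow(h)
  if (J < 4L) stop("MR-PRESSO requires at least 4 variants", call. = FALSE)
  if (J == 4L) warning("outlier-detection power is limited with J = 4",
                       call. = FALSE)
  if (n_sim < 100L) stop("n_sim must be at least 100", call. = FALSE)

  bx <- h$beta_x; by <- h$beta_y
  sex <- h$se_x; sey <- h$se_y
  w <- sey^-2

  th_loo <- loo_slopes(bx, by, w)
  resid <- by - th_loo * bx
  contrib <- resid^2 * w
  rss_obs <- sum(contrib)

  with_seed(seed, {
    # replicate matrices: n_sim rows, J columns
    bx_star <- matrix(stats::rnorm(n_sim * J, mean = rep(bx, each = n_sim),
                                   sd = rep(sex, each = n_sim)),
                      nrow = n_sim)
    by_star <- matrix(stats::rnorm(n_sim * J, mean = rep(th_loo * bx, each = n_sim),
                                   sd = rep(sey, each = n_sim)),
                      nrow = n_sim)
    wm <- matrix(w, nrow = n_sim, ncol = J, byrow = TRUE)
    sxy <- rowSums(wm * bx_star * by_star)
    sxx <- rowSums(wm * bx_star^2)
    th_loo_star <- (sxy - wm * bx_star * by_star) / (sxx - wm * bx_star^2)
    resid_star <- by_star - th_loo_star * bx_star
    contrib_star <- resid_star^2 * wm
    rss_star <- rowSums(contrib_star)

    global_pval <- (1 + sum(rss_star >= rss_obs)) / (n_sim + 1)
    outlier_raw <- (1 + colSums(contrib_star >= rep(contrib, each = n_sim))) /
      (n_sim + 1)
    outlier_pval <- pmin(1, outlier_raw * J)
    outlier_set <- h$rsid[outlier_pval < outlier_alpha]

    ratios <- wald_ratios(h)
    full <- mr_ivw(ratios)
    corrected <- NULL
    distortion_pval <- NA_real_
    if (length(outlier_set) > 0L) {
      keep <- !(h$rsid %in% outlier_set)
      if (sum(keep) >= 2L) {
        corrected <- mr_ivw(ratios[keep, , drop = FALSE])
        corrected$method <- "PRESSO-corrected"
        d_obs <- corrected$estimate - full$estimate
        k <- length(outlier_set)
        d_rand <- vapply(seq_len(n_distortion), function(b) {
          drop_idx <- sample.int(J, k)
          mr_ivw(ratios[-drop_idx, , drop = FALSE])$estimate - full$estimate
        }, numeric(1))
        distortion_pval <- (1 + sum(abs(d_rand) >= abs(d_obs))) /
          (n_distortion + 1)
      } else {
        warning("all or nearly all variants flagged as outliers; ",
                "corrected estimate not computed", call. = FALSE)
      }
    }

    structure(list(rss_obs = rss_obs, global_pval = global_pval,
                   per_snp = data.frame(rsid = h$rsid, residual = resid,
                                        outlier_pval = outlier_pval,
                                        stringsAsFactors = FALSE),
                   outlier_set = outlier_set, corrected = corrected,
                   distortion_pval = distortion_pval,
                   n_sim = n_sim, seed = seed),
              class = "presso_result")
  })
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("<presso_result> RSS = %.4f, global p = %.4g (%d simulations)\n",
              x$rss_obs, x$global_pval, x$n_sim))
  if (length(x$outlier_set) > 0L) {
    cat("  outliers:", paste(x$outlier_set, collapse = ", "),
        sprintf("(distortion p = %.3g)\n", x$distortion_pval))
    if (!is.null(x$corrected)) print(x$corrected)
  } else {
    cat("  no outliers flagged\n")
  }
  invisible(x)
}
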