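test_that("Wald ratios use first-order delta standard errors", {
  h <- make_instrument(beta_x = 0.1, se_x = 0.01, beta_y = -0.05, se_y = 0.02)
  r <- wald_ratios(h)
  expect_equal(r$theta, -0.5)
  expect_equal(r$se_theta, 0.2)
  expect_equal(r$weight, 0.2^-2)

  # null outcome effect
  h0 <- make_instrument(beta_x = -0.2, se_x = 0.01, beta_y = 0, se_y = 0.03)
  r0 <- wald_ratios(h0)
  expect_equal(r0$theta, 0)
  expect_equal(r0$se_theta, 0.03 / 0.2)

  # negating both betas leaves the ratio unchanged
  h2 <- make_instrument(beta_x = -0.1, se_x = 0.01, beta_y = 0.05, se_y = 0.02)
  expect_equal(wald_ratios(h2)$theta, r$theta)
  expect_equal(wald_ratios(h2)$se_theta, r$se_theta)

  expect_error(wald_ratios(make_instrument(0, 0.01, 0.1, 0.02, rsid = "rsZ")),
               "rsZ")
})

test_that("IVW degenerates correctly at J = 1 and under homogeneity", {
  r1 <- wald_ratios(make_instrument(0.1, 0.01, -0.05, 0.02))
  e1 <- mr_ivw(r1)
  expect_equal(e1$estimate, -0.5)
  expect_true(is.na(e1$q))
  expect_equal(e1$phi, 1)
  expect_equal(e1$se, 0.2)

  # identical ratios: estimate equals the common value, Q = 0, phi floored at 1
  h <- make_instrument(beta_x = c(0.1, 0.2, 0.05), se_x = rep(0.01, 3),
                       beta_y = c(0.05, 0.10, 0.025), se_y = c(.02, .01, .03))
  e <- mr_ivw(wald_ratios(h))
  expect_equal(e$estimate, 0.5)
  expect_equal(e$q, 0)
  expect_equal(e$q_pval, 1)
  expect_equal(e$phi, 1)
})

test_that("ratio-pooled IVW equals the zero-intercept WLS slope exactly", {
  for (seed in 1:20) {
    h <- random_instrument(J = sample(2:12, 1), seed = seed)
    est <- mr_ivw(wald_ratios(h))
    expect_equal(est$estimate, ivw_wls_oracle(h), tolerance = 1e-12)
  }
})

test_that("IVW confidence interval and p follow the overdispersed normal", {
  h <- random_instrument(8, seed = 3)
  r <- wald_ratios(h)
  e <- mr_ivw(r)
  w <- r$weight
  q <- sum(w * (r$theta - e$estimate)^2)
  se <- sqrt(max(1, q / 7) / sum(w))
  expect_equal(e$se, se)
  expect_equal(e$ci_low, e$estimate - 1.959964 * se)
  expect_equal(e$pval, 2 * pnorm(-abs(e$estimate / se)))
  expect_true(e$ci_low <= e$estimate && e$estimate <= e$ci_high)
})

test_that("the simple median is robust and uses the midpoint convention", {
  h <- make_instrument(beta_x = rep(1, 3), se_x = rep(.1, 3),
                       beta_y = c(1, 2, 30), se_y = rep(0.5, 3))
  est <- mr_simple_median(wald_ratios(h), n_boot = 200, seed = 1)
  expect_equal(est$estimate, 2)

  h2 <- make_instrument(beta_x = c(1, 1), se_x = rep(.1, 2),
                        beta_y = c(1, 3), se_y = rep(0.5, 2))
  expect_warning(e2 <- mr_simple_median(wald_ratios(h2), n_boot = 50, seed = 1),
                 "J < 3")
  expect_equal(e2$estimate, 2)

  expect_error(mr_simple_median(wald_ratios(h), n_boot = 1, seed = 1),
               "n_boot")
})

test_that("bootstrap SEs are stable across seeds at large n_boot", {
  r <- wald_ratios(random_instrument(6, seed = 10))
  se_a <- mr_simple_median(r, n_boot = 10000, seed = 1)$se
  se_b <- mr_simple_median(r, n_boot = 10000, seed = 2)$se
  expect_lt(abs(se_a - se_b) / se_a, 0.05)
  wm_a <- mr_weighted_median(r, n_boot = 10000, seed = 1)$se
  wm_b <- mr_weighted_median(r, n_boot = 10000, seed = 2)$se
  expect_lt(abs(wm_a - wm_b) / wm_a, 0.05)
})

test_that("the weighted median interpolates the weighted CDF at one half", {
  # hand-computed 3-variant fixture: theta (1,2,3), normalised weights
  # (.6,.2,.2) -> s = (.3,.7,.9); interpolating at .5 gives 1.5
  h <- make_instrument(beta_x = rep(1, 3), se_x = rep(.1, 3),
                       beta_y = c(1, 2, 3),
                       se_y = 1 / sqrt(c(0.6, 0.2, 0.2)))
  est <- mr_weighted_median(wald_ratios(h), n_boot = 100, seed = 1)
  expect_equal(est$estimate, 1.5)

  # equal weights reduce to the simple median
  he <- make_instrument(beta_x = rep(1, 5), se_x = rep(.1, 5),
                        beta_y = c(5, 1, 4, 2, 3), se_y = rep(0.5, 5))
  re <- wald_ratios(he)
  expect_equal(mr_weighted_median(re, 100, seed = 1)$estimate,
               mr_simple_median(re, 100, seed = 1)$estimate)

  # permuting the input order leaves the estimate unchanged
  perm <- re[c(3, 1, 5, 2, 4), ]
  expect_equal(mr_weighted_median(perm, 100, seed = 1)$estimate,
               mr_weighted_median(re, 100, seed = 1)$estimate)
})

test_that("MR-Egger recovers an exact linear relationship without noise", {
  bx <- c(0.05, 0.1, 0.15, 0.2)
  a <- 0.02; b <- 0.6
  h <- make_instrument(beta_x = bx, se_x = rep(.01, 4),
                       beta_y = a + b * bx, se_y = rep(.02, 4))
  eg <- mr_egger(h)
  expect_equal(eg$slope$estimate, b)
  expect_equal(eg$intercept$estimate, a)
  expect_equal(eg$slope$phi, 1)

  # all beta_x equal: collinear with the intercept
  h_sing <- make_instrument(beta_x = rep(0.1, 4), se_x = rep(.01, 4),
                            beta_y = rnorm(4), se_y = rep(.02, 4))
  expect_error(mr_egger(h_sing), "singular")
  expect_error(mr_egger(h[1:2, ]), "at least 3")
})

test_that("MR-Egger matches the weighted lm oracle when overdispersed", {
  for (seed in c(2, 5, 9)) {
    h <- random_instrument(10, seed = seed)
    oracle <- egger_lm_oracle(h)
    if (oracle$sigma < 1) next # floor engages; lm no longer comparable
    eg <- mr_egger(h)
    expect_equal(eg$slope$estimate, unname(oracle$slope["Estimate"]))
    expect_equal(eg$slope$se, unname(oracle$slope["Std. Error"]))
    expect_equal(eg$slope$pval, unname(oracle$slope["Pr(>|t|)"]))
    expect_equal(eg$intercept$estimate, unname(oracle$intercept["Estimate"]))
    expect_equal(eg$intercept$se, unname(oracle$intercept["Std. Error"]))
    expect_equal(eg$slope$phi, oracle$sigma^2)
  }
})

test_that("Egger orientation is a no-op when all beta_x are positive", {
  h <- random_instrument(8, seed = 12)
  h$beta_x <- abs(h$beta_x)
  eg <- mr_egger(h)
  h_flipped <- h
  h_flipped$beta_x[3] <- -h$beta_x[3]
  h_flipped$beta_y[3] <- -h$beta_y[3]
  eg2 <- mr_egger(h_flipped)
  expect_equal(eg2$slope$estimate, eg$slope$estimate)
  expect_equal(eg2$intercept$estimate, eg$intercept$estimate)
})

test_that("Cochran's Q behaves at homogeneity and scales with the weights", {
  h <- make_instrument(beta_x = c(0.1, 0.2, 0.05), se_x = rep(0.01, 3),
                       beta_y = c(0.05, 0.10, 0.025), se_y = c(.02, .01, .03))
  r <- wald_ratios(h)
  e <- mr_ivw(r)
  cq <- cochran_q(r, e)
  expect_equal(cq$q, 0)
  expect_equal(cq$q_pval, 1)

  h2 <- random_instrument(7, seed = 4)
  r2 <- wald_ratios(h2)
  e2 <- mr_ivw(r2)
  q2 <- cochran_q(r2, e2)
  # doubling every se quarters every weight, hence Q, at fixed theta
  r_half <- r2
  r_half$se_theta <- 2 * r2$se_theta
  r_half$weight <- r_half$se_theta^-2
  expect_equal(cochran_q(r_half, e2)$q, q2$q / 4)

  expect_true(is.na(cochran_q(r2[1, ], e2)$q))
})

test_that("negating all outcome effects negates estimates, preserves spread", {
  h <- random_instrument(9, seed = 6)
  hn <- h
  hn$beta_y <- -h$beta_y
  r <- wald_ratios(h); rn <- wald_ratios(hn)

  a <- mr_ivw(r); b <- mr_ivw(rn)
  expect_equal(b$estimate, -a$estimate)
  expect_equal(b$se, a$se)
  expect_equal(b$q, a$q)
  expect_equal(b$phi, a$phi)

  sm <- mr_simple_median(r, 500, seed = 8)
  smn <- mr_simple_median(rn, 500, seed = 8)
  expect_equal(smn$estimate, -sm$estimate)

  wm <- mr_weighted_median(r, 500, seed = 8)
  wmn <- mr_weighted_median(rn, 500, seed = 8)
  expect_equal(wmn$estimate, -wm$estimate)

  eg <- mr_egger(h); egn <- mr_egger(hn)
  expect_equal(egn$slope$estimate, -eg$slope$estimate)
  expect_equal(egn$slope$se, eg$slope$se)
  expect_equal(egn$intercept$estimate, -eg$intercept$estimate)
})
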