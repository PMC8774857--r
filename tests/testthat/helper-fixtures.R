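# Fixture builders and independent oracles shared across the suite.

# Minimal variant table; defaults give a clean 4-SNP exposure
make_variants <- function(rsid = paste0("rs", 1:4),
                          effect_allele = c("A", "C", "G", "T"),
                          other_allele = c("G", "T", "A", "C"),
                          eaf = c(0.2, 0.3, 0.4, 0.5),
                          beta = c(0.10, 0.08, -0.06, 0.05),
                          se = c(0.010, 0.012, 0.011, 0.013),
                          pval = rep(1e-10, 4),
                          n = 25314, ...) {
  data.frame(rsid = rsid, effect_allele = effect_allele,
             other_allele = other_allele, eaf = eaf, beta = beta, se = se,
             pval = pval, n = n, ..., stringsAsFactors = FALSE)
}

make_dataset <- function(..., trait_name = "trait") {
  summary_dataset(make_variants(...), trait_name = trait_name)
}

# harmonised-instrument fixture straight from numbers (already aligned)
make_instrument <- function(beta_x, se_x, beta_y, se_y,
                            rsid = paste0("rs", seq_along(beta_x))) {
  data.frame(rsid = rsid, beta_x = beta_x, se_x = se_x,
             beta_y = beta_y, se_y = se_y, stringsAsFactors = FALSE)
}

# random aligned instrument for property loops
random_instrument <- function(J, seed) {
  set.seed(seed)
  make_instrument(beta_x = stats::rnorm(J, 0.1, 0.04),
                  se_x = stats::runif(J, 0.005, 0.02),
                  beta_y = stats::rnorm(J, 0, 0.05),
                  se_y = stats::runif(J, 0.01, 0.05))
}

# Independent IVW oracle: zero-intercept weighted least squares via lm()
ivw_wls_oracle <- function(h) {
  unname(stats::coef(stats::lm(beta_y ~ 0 + beta_x, data = h,
                               weights = se_y^-2))[1])
}

# Independent MR-Egger oracle via lm() (valid when overdispersion >= 1)
egger_lm_oracle <- function(h) {
  flip <- h$beta_x < 0
  bx <- ifelse(flip, -h$beta_x, h$beta_x)
  by <- ifelse(flip, -h$beta_y, h$beta_y)
  fit <- stats::lm(by ~ bx, weights = h$se_y^-2)
  s <- summary(fit)$coefficients
  list(intercept = s[1, ], slope = s[2, ], sigma = summary(fit)$sigma)
}

# generate -> select -> harmonise -> ratios, the standard pipeline prefix
pipeline_ratios <- function(cfg) {
  pair <- simulate_pair(cfg)
  h <- harmonise(pair$exposure, pair$outcome)
  wald_ratios(h)
}
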