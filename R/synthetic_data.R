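#' Names of the 42-cytokine outcome panel
#'
#' Abbreviated names of the circulating cytokines, chemokines and growth
#' factors making up the screened outcome panel (41 from the Finnish cytokine
#' GWAS meta-analysis plus CRP from UK Biobank). Used to label synthetic
#' panels so end-to-end fixtures read like the real screen.
#'
#' @return Character vector of length 42.
#' @export
cytokine_panel_names <- function() {
  c("B-NGF", "CTACK", "Eotaxin", "FGF2", "G-CSF", "GROa", "HGF", "IFN-G",
    "IL-1B", "IL-1RA", "IL-2", "IL-2RA", "IL-4", "IL-5", "IL-6", "IL-7",
    "IL-8", "IL-9", "IL-10", "IL-12-P70", "IL-13", "IL-16", "IL-17", "IL-18",
    "IP-10", "M-CSF", "MCP-1/MCAF", "MCP-3", "MIF", "MIG", "MIP-1A", "MIP-1B",
    "PDGF-BB", "RANTES", "SCF", "SCGF-B", "SDF-1A", "TNF-A", "TNF-B", "TRAIL",
    "VEGF", "CRP")
}

#' Pleiotropy models for the generator
#'
#' Per-variant direct (pleiotropic) effects `alpha_j` on the outcome:
#' `pleiotropy_none()` sets every `alpha_j = 0` so the exclusion-restriction
#' assumption holds by construction; `pleiotropy_balanced(tau)` draws
#' `alpha_j ~ Normal(0, tau^2)` (zero mean, IVW remains unbiased);
#' `pleiotropy_directional(mu, tau)` draws `alpha_j ~ Normal(mu, tau^2)` with
#' effects independent of the variant-exposure effects, i.e. directional
#' pleiotropy under InSIDE, which biases IVW but leaves the MR-Egger intercept
#' a consistent estimate of `mu`; `pleiotropy_inside_violated(rho, tau)`
#' correlates `alpha_j` with the variant-exposure effects at correlation
#' `rho`, breaking exactly the independence MR-Egger needs.
#'
#' @param tau SD of the pleiotropic effects (outcome SD units), `tau >= 0`.
#' @param mu Mean directional pleiotropic effect.
#' @param rho Correlation between pleiotropic and variant-exposure effects,
#'   in `[-1, 1]`.
#' @return A list describing the pleiotropy model, for [sim_config()].
#' @export
pleiotropy_none <- function() list(type = "none", tau = 0, mu = 0, rho = 0)

#' @rdname pleiotropy_none
#' @export
pleiotropy_balanced <- function(tau) {
  stopifnot(tau >= 0)
  list(type = "balanced", tau = tau, mu = 0, rho = 0)
}

#' @rdname pleiotropy_none
#' @export
pleiotropy_directional <- function(mu, tau) {
  stopifnot(tau >= 0)
  list(type = "directional", tau = tau, mu = mu, rho = 0)
}

#' @rdname pleiotropy_none
#' @export
pleiotropy_inside_violated <- function(rho, tau) {
  stopifnot(tau >= 0, abs(rho) <= 1)
  list(type = "inside_violated", tau = tau, mu = 0, rho = rho)
}

#' Configuration for the two-sample summary-statistics generator
#'
#' Defaults emulate the cortisol-cytokine screen's design: a four-variant
#' instrument explaining just under 1% of exposure variance estimated in an
#' exposure GWAS of 25,314 (the cortisol consortium scale), outcome GWAS of
#' 8,293 (the Finnish cytokine cohorts), and a 42-outcome panel.
#'
#' @param seed Integer master seed (required).
#' @param J Number of instrument variants (default 4).
#' @param theta True causal effect, outcome SD per exposure SD (default 0);
#'   in panels it applies to the causal outcomes.
#' @param n_x,n_y Exposure / outcome GWAS sample sizes (defaults 25314, 8293).
#' @param maf_range Minor-allele-frequency interval within (0, 0.5]; default
#'   `c(0.1, 0.5)` (common variants, as in a clumped instrument).
#' @param target_r2 Total exposure variance explained by the instrument
#'   (default 0.0095, i.e. ~1%).
#' @param pleiotropy One of the `pleiotropy_*()` models (default none).
#' @param n_outcomes Panel size (default 42).
#' @param n_causal Outcomes with `theta != 0` (default 0).
#' @param scramble_alleles Re-code outcome alleles (swapped and/or
#'   strand-complemented at random) to exercise harmonisation; palindromic
#'   pairs are only ever swapped, so the forward-strand assumption recovers
#'   the generating orientation exactly. Default `TRUE`.
#' @param positive_gamma If `TRUE`, code every effect allele as the
#'   exposure-increasing allele (`gamma_j >= 0`), the convention real
#'   instruments are usually reported in. This matters for MR-Egger: its
#'   intercept estimates the mean pleiotropic effect in the
#'   exposure-increasing orientation, so directional pleiotropy is only
#'   recoverable as a nonzero intercept when the generating orientation is
#'   consistent. Default `FALSE` (random signs).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed, J = 4, theta = 0, n_x = 25314, n_y = 8293,
                       maf_range = c(0.1, 0.5), target_r2 = 0.0095,
                       pleiotropy = pleiotropy_none(), n_outcomes = 42,
                       n_causal = 0, scramble_alleles = TRUE,
                       positive_gamma = FALSE) {
  if (missing(seed)) stop("an explicit integer seed is required", call. = FALSE)
  stopifnot(is.numeric(seed), length(seed) == 1L,
            J >= 1, n_x > 2, n_y > 2,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            is.list(pleiotropy),
            pleiotropy$type %in% c("none", "balanced", "directional",
                                   "inside_violated"),
            n_outcomes >= 1, n_causal >= 0, n_causal <= n_outcomes)
  if (!(target_r2 > 0 && target_r2 < 1)) {
    stop("target_r2 must lie in (0, 1)", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), J = as.integer(J), theta = theta,
                 n_x = n_x, n_y = n_y, maf_range = maf_range,
                 target_r2 = target_r2, pleiotropy = pleiotropy,
                 n_outcomes = as.integer(n_outcomes),
                 n_causal = as.integer(n_causal),
                 scramble_alleles = isTRUE(scramble_alleles),
                 positive_gamma = isTRUE(positive_gamma)),
            class = "sim_config")
}

# allele pairs; palindromic pairs are A/T, T/A, C/G, G/C
draw_allele_pairs <- function(J) {
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, J, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(bases, a), 1L), character(1))
  data.frame(effect_allele = ea, other_allele = unname(oa),
             stringsAsFactors = FALSE)
}

# shared structural layer of a simulated study: maf, alleles, true gamma,
# standard errors, and the observed exposure associations
draw_exposure_layer <- function(cfg) {
  J <- cfg$J
  maf <- stats::runif(J, cfg$maf_range[1], cfg$maf_range[2])
  het <- 2 * maf * (1 - maf)
  g_raw <- stats::rnorm(J)
  if (isTRUE(cfg$positive_gamma)) g_raw <- abs(g_raw)
  gamma <- g_raw * sqrt(cfg$target_r2 / sum(het * g_raw^2))
  se_x <- sqrt(1 / (het * cfg$n_x))
  se_y <- sqrt(1 / (het * cfg$n_y))
  beta_x <- stats::rnorm(J, gamma, se_x)
  alleles <- draw_allele_pairs(J)
  list(
    snps = data.frame(
      rsid = sprintf("rs%d", 100000 + seq_len(J)),
      chrom = "14", pos = 94500000 + (seq_len(J) - 1L) * 25000L,
      effect_allele = alleles$effect_allele,
      other_allele = alleles$other_allele,
      maf = maf, gamma = gamma, se_x = se_x, se_y = se_y,
      beta_x = beta_x, stringsAsFactors = FALSE),
    het = het
  )
}

draw_pleiotropy <- function(pl, gamma) {
  J <- length(gamma)
  switch(pl$type,
    none = rep(0, J),
    balanced = stats::rnorm(J, 0, pl$tau),
    directional = stats::rnorm(J, pl$mu, pl$tau),
    inside_violated = {
      z <- stats::rnorm(J)
      g_std <- if (stats::sd(gamma) > 0) {
        (gamma - mean(gamma)) / stats::sd(gamma)
      } else {
        rep(0, J)
      }
      pl$tau * (pl$rho * g_std + sqrt(1 - pl$rho^2) * z)
    })
}

exposure_dataset <- function(layer, trait_name = "exposure") {
  s <- layer$snps
  summary_dataset(data.frame(
    rsid = s$rsid, chrom = s$chrom, pos = s$pos,
    effect_allele = s$effect_allele, other_allele = s$other_allele,
    eaf = s$maf, beta = s$beta_x, se = s$se_x,
    pval = two_sided_p(s$beta_x / s$se_x),
    n = layer$n_x %||% NA, stringsAsFactors = FALSE),
    trait_name = trait_name)
}

# one outcome dataset from the shared layer; draws pleiotropy, outcome noise
# and (optionally) scrambled allele coding
draw_outcome_dataset <- function(layer, theta, pleiotropy, scramble,
                                 trait_name) {
  s <- layer$snps
  J <- nrow(s)
  alpha <- draw_pleiotropy(pleiotropy, s$gamma)
  beta_y <- stats::rnorm(J, theta * s$gamma + alpha, s$se_y)

  ea <- s$effect_allele; oa <- s$other_allele
  eaf <- s$maf; beta <- beta_y
  if (scramble) {
    for (j in seq_len(J)) {
      palin <- is_palindromic_pair(ea[j], oa[j])
      codings <- if (palin) c("same", "swap") else
        c("same", "swap", "complement", "swap_complement")
      code <- sample(codings, 1L)
      if (code %in% c("swap", "swap_complement")) {
        tmp <- ea[j]; ea[j] <- oa[j]; oa[j] <- tmp
        beta[j] <- -beta[j]; eaf[j] <- 1 - eaf[j]
      }
      if (code %in% c("complement", "swap_complement")) {
        ea[j] <- complement_alleles(ea[j]); oa[j] <- complement_alleles(oa[j])
      }
    }
  }
  ds <- summary_dataset(data.frame(
    rsid = s$rsid, chrom = s$chrom, pos = s$pos,
    effect_allele = ea, other_allele = oa,
    eaf = eaf, beta = beta, se = s$se_y,
    pval = two_sided_p(beta / s$se_y),
    n = NA, stringsAsFactors = FALSE),
    trait_name = trait_name)
  list(dataset = ds, alpha = alpha)
}

#' Simulate one exposure/outcome pair of GWAS summary datasets
#'
#' Draws minor-allele frequencies uniformly on `maf_range`; true
#' variant-exposure effects scaled so the instrument explains exactly
#' `target_r2` of the exposure variance (`sum 2 maf (1 - maf) gamma^2 =
#' target_r2`); standard errors follow the standardised-trait closed form
#' `se = sqrt(1 / (2 maf (1 - maf) n))`; observed effects are the truth plus
#' Gaussian sampling noise, with the outcome mean `theta * gamma_j + alpha_j`
#' under the configured pleiotropy model. Outcome allele coding is optionally
#' scrambled to exercise harmonisation.
#'
#' @param cfg A [sim_config()].
#' @return List with `exposure` and `outcome` ([summary_dataset()]s) and
#'   `truth` (per-variant `rsid`, `maf`, `gamma`, `alpha` and the scalar
#'   `theta`).
#' @export
simulate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    layer <- draw_exposure_layer(cfg)
    layer$n_x <- cfg$n_x
    exposure <- exposure_dataset(layer)
    out <- draw_outcome_dataset(layer, cfg$theta, cfg$pleiotropy,
                                cfg$scramble_alleles, "outcome")
    truth <- data.frame(rsid = layer$snps$rsid, maf = layer$snps$maf,
                        gamma = layer$snps$gamma, alpha = out$alpha,
                        theta = cfg$theta, stringsAsFactors = FALSE)
    list(exposure = exposure, outcome = out$dataset, truth = truth)
  })
}

#' Simulate a multi-outcome screening panel
#'
#' One shared exposure dataset and `n_outcomes` outcome datasets, of which
#' `n_causal` have true causal effect `theta` (the rest 0). Outcome names are
#' taken from [cytokine_panel_names()] (recycled with numeric suffixes beyond
#' 42). Every outcome's random stream is derived from the master seed plus its
#' name, so adding or removing outcomes never changes another outcome's draws;
#' the causal outcomes are themselves a seeded random subset.
#'
#' @param cfg A [sim_config()].
#' @return List with `exposure`, `outcomes` (named list of
#'   [summary_dataset()]s), `truth` (data frame `outcome`, `theta`) and
#'   `snp_truth` (per-variant `rsid`, `maf`, `gamma`).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  base_names <- cytokine_panel_names()
  nm <- if (cfg$n_outcomes <= length(base_names)) {
    base_names[seq_len(cfg$n_outcomes)]
  } else {
    c(base_names, sprintf("outcome%d", seq_len(cfg$n_outcomes - length(base_names))))
  }
  layer <- with_seed(derive_seed(cfg$seed, "exposure"), {
    l <- draw_exposure_layer(cfg)
    l$n_x <- cfg$n_x
    l
  })
  exposure <- exposure_dataset(layer)
  causal <- with_seed(derive_seed(cfg$seed, "causal-set"),
                      sample(nm, cfg$n_causal))
  thetas <- ifelse(nm %in% causal, cfg$theta, 0)
  outcomes <- vector("list", length(nm))
  names(outcomes) <- nm
  for (i in seq_along(nm)) {
    outcomes[[i]] <- with_seed(derive_seed(cfg$seed, "outcome", nm[i]), {
      draw_outcome_dataset(layer, thetas[i], cfg$pleiotropy,
                           cfg$scramble_alleles, nm[i])$dataset
    })
  }
  list(exposure = exposure, outcomes = outcomes,
       truth = data.frame(outcome = nm, theta = thetas,
                          stringsAsFactors = FALSE),
       snp_truth = layer$snps[c("rsid", "maf", "gamma")])
}

#' Write a simulated panel to disk in the TSV dialect the readers accept
#'
#' @param panel A [simulate_panel()] result.
#' @param dir Output directory (created if needed). Writes `exposure.tsv`,
#'   one `outcome_<i>_<name>.tsv` per outcome, and `truth.tsv`.
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_summary_table(panel$exposure, file.path(dir, "exposure.tsv"))
  nm <- names(panel$outcomes)
  safe <- gsub("[^A-Za-z0-9._-]+", "_", nm)
  for (i in seq_along(nm)) {
    write_summary_table(panel$outcomes[[i]],
                        file.path(dir, sprintf("outcome_%02d_%s.tsv", i, safe[i])))
  }
  utils::write.table(panel$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
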