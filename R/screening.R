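#' Bonferroni-corrected significance threshold
#'
#' Family-wise level divided by the number of tests; at the screen's defaults
#' (`alpha = 0.05`, `m = 42`) this is p < 0.00119.
#'
#' @param alpha Family-wise significance level.
#' @param m Number of tests, at least 1.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Screen configuration
#'
#' @param seed Integer master seed (required); per-outcome, per-method random
#'   streams are derived from it with [derive_seed()].
#' @param alpha Family-wise level (default 0.05).
#' @param m Number of tests for the Bonferroni correction; `NULL` (default)
#'   means the number of outcomes supplied to [run_screen()]. Overridable
#'   because a screen may fix m even when outcomes come from several GWASs.
#' @param p_threshold Instrument selection p-value threshold (default 5e-8).
#' @param r2_threshold LD pruning threshold (default 0.3).
#' @param n_boot Bootstrap replicates for the median estimators (default 1000).
#' @param presso_n_sim MR-PRESSO simulation replicates (default 1000).
#' @param presso_outlier_alpha MR-PRESSO outlier threshold (default 0.05).
#' @return A validated `screen_config` list.
#' @export
screen_config <- function(seed, alpha = 0.05, m = NULL, p_threshold = 5e-8,
                          r2_threshold = 0.3, n_boot = 1000,
                          presso_n_sim = 1000, presso_outlier_alpha = 0.05) {
  if (missing(seed)) stop("an explicit integer seed is required", call. = FALSE)
  stopifnot(is.numeric(seed), length(seed) == 1L,
            alpha > 0, alpha < 1, is.null(m) || m >= 1,
            p_threshold > 0, r2_threshold > 0, n_boot >= 2,
            presso_n_sim >= 100)
  structure(list(seed = as.integer(seed), alpha = alpha, m = m,
                 p_threshold = p_threshold, r2_threshold = r2_threshold,
                 n_boot = n_boot, presso_n_sim = presso_n_sim,
                 presso_outlier_alpha = presso_outlier_alpha),
            class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  cat("<screen_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %-21s %s\n", k,
                if (is.null(x[[k]])) "(number of outcomes)" else format(x[[k]])))
  }
  invisible(x)
}

classify_ivw_p <- function(p, alpha, m) {
  thr <- bonferroni_threshold(alpha, m)
  if (is.na(p)) NA_character_
  else if (p < thr) "significant"
  else if (p < alpha) "suggestive"
  else "non_significant"
}

# run one outcome through every configured method; warnings are captured into
# the row's log rather than surfaced 42 times per screen
screen_one <- function(exposure, outcome, name, cfg, m) {
  log <- character(0)
  note <- function(msg) log <<- c(log, msg)

  if (length(intersect(exposure$rsid, outcome$rsid)) == 0L) {
    return(list(outcome = name, J = 0L, status = "no_overlap",
                estimates = list(), presso = NULL,
                classification = NA_character_, log = "no shared rsids"))
  }
  h <- withCallingHandlers(
    harmonise(exposure, outcome),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
  dl <- attr(h, "drop_log")
  if (nrow(dl) > 0L) {
    note(paste0("dropped: ", paste(dl$rsid, dl$reason, sep = " - ",
                                   collapse = "; ")))
  }
  ratios <- wald_ratios(h)
  J <- nrow(h)

  est <- list(ivw = mr_ivw(ratios))
  quiet <- function(expr) withCallingHandlers(
    expr,
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
  est$simple_median <- quiet(mr_simple_median(
    ratios, n_boot = cfg$n_boot,
    seed = derive_seed(cfg$seed, name, "simple-median")))
  est$weighted_median <- quiet(mr_weighted_median(
    ratios, n_boot = cfg$n_boot,
    seed = derive_seed(cfg$seed, name, "weighted-median")))
  if (J >= 3L) {
    eg <- quiet(mr_egger(h))
    est$egger_slope <- eg$slope
    est$egger_intercept <- eg$intercept
  } else {
    note("MR-Egger skipped: fewer than 3 variants")
  }
  presso <- NULL
  if (J >= 4L) {
    presso <- quiet(mr_presso(h, n_sim = cfg$presso_n_sim,
                              outlier_alpha = cfg$presso_outlier_alpha,
                              seed = derive_seed(cfg$seed, name, "presso")))
    if (!is.null(presso$corrected)) est$presso_corrected <- presso$corrected
  } else {
    note("MR-PRESSO skipped: fewer than 4 variants")
  }

  list(outcome = name, J = J, status = "ok", estimates = est,
       presso = presso,
       classification = classify_ivw_p(est$ivw$pval, cfg$alpha, m),
       log = log)
}

#' Run the multi-outcome Mendelian randomisation screen
#'
#' Harmonises the instrument against every outcome, computes the full
#' estimator suite (multiplicative random-effects IVW, simple and weighted
#' median, MR-Egger where at least 3 variants survive, MR-PRESSO where at
#' least 4 do) and classifies each outcome by its IVW p-value against the
#' Bonferroni-corrected threshold: `significant` below `alpha/m`,
#' `suggestive` in `[alpha/m, alpha)`, `non_significant` otherwise. Sensitivity
#' methods are reported but never drive classification. Outcomes sharing no
#' variant with the instrument yield a `no_overlap` row rather than aborting
#' the screen. Results are deterministic given `cfg$seed`, and per-outcome
#' streams are independent of the panel composition.
#'
#' @param exposure The instrument: a [summary_dataset()] that has already
#'   passed selection/pruning (see [select_instruments()], [ld_prune()]).
#' @param outcomes Named list of outcome [summary_dataset()]s (falls back to
#'   each dataset's `trait_name` attribute when unnamed).
#' @param cfg A [screen_config()].
#' @return An object of class `mr_screen`: list of per-outcome rows plus the
#'   configuration; see [as.data.frame.mr_screen()] and [export_forest()].
#' @export
run_screen <- function(exposure, outcomes, cfg) {
  stopifnot(inherits(exposure, "summary_dataset"), is.list(outcomes),
            inherits(cfg, "screen_config"))
  nm <- names(outcomes)
  if (is.null(nm)) nm <- rep("", length(outcomes))
  for (i in seq_along(outcomes)) {
    if (nm[i] == "") nm[i] <- attr(outcomes[[i]], "trait_name") %||%
        sprintf("outcome%d", i)
  }
  m <- cfg$m %||% length(outcomes)
  rows <- lapply(seq_along(outcomes), function(i) {
    screen_one(exposure, outcomes[[i]], nm[i], cfg, m)
  })
  structure(list(rows = rows, config = cfg, m = m,
                 exposure_name = attr(exposure, "trait_name")),
            class = "mr_screen")
}

#' @export
print.mr_screen <- function(x, ...) {
  counts <- table(factor(
    vapply(x$rows, function(r) {
      if (r$status == "no_overlap") "no_overlap" else r$classification
    }, character(1)),
    levels = c("significant", "suggestive", "non_significant", "no_overlap")))
  cat(sprintf("<mr_screen> %d outcome(s), Bonferroni threshold %.3g\n",
              length(x$rows), bonferroni_threshold(x$config$alpha, x$m)))
  print(counts)
  invisible(x)
}

#' Flatten a screen to a long results table
#'
#' One row per outcome x method with estimate, SE, confidence limits, p-value,
#' heterogeneity statistics and the outcome's IVW-based classification.
#'
#' @param x An [run_screen()] result.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.mr_screen <- function(x, ...) {
  out <- lapply(x$rows, function(r) {
    if (length(r$estimates) == 0L) {
      return(data.frame(outcome = r$outcome, J = r$J, status = r$status,
                        method = NA_character_, estimate = NA_real_,
                        se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        pval = NA_real_, n_snps = NA_integer_, q = NA_real_,
                        q_pval = NA_real_, phi = NA_real_,
                        presso_global_pval = NA_real_,
                        classification = r$classification,
                        stringsAsFactors = FALSE))
    }
    est <- do.call(rbind, lapply(r$estimates, as.data.frame))
    data.frame(outcome = r$outcome, J = r$J, status = r$status, est,
               presso_global_pval =
                 if (is.null(r$presso)) NA_real_ else r$presso$global_pval,
               classification = r$classification,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Export forest-plot-ready IVW records
#'
#' One CSV record per outcome with the IVW estimate, its 95% confidence
#' limits and the classification colour key used in the screen's forest plot:
#' significant after Bonferroni correction = green, suggestive (p < alpha
#' only) = blue, non-significant = red. Outcomes are written in panel order.
#'
#' @param x An [run_screen()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_forest <- function(x, path) {
  stopifnot(inherits(x, "mr_screen"), length(x$rows) > 0L)
  colour_key <- c(significant = "green", suggestive = "blue",
                  non_significant = "red")
  rec <- lapply(x$rows, function(r) {
    ivw <- r$estimates$ivw
    data.frame(outcome = r$outcome,
               estimate = if (is.null(ivw)) NA_real_ else ivw$estimate,
               ci_low = if (is.null(ivw)) NA_real_ else ivw$ci_low,
               ci_high = if (is.null(ivw)) NA_real_ else ivw$ci_high,
               classification = r$classification %||% NA_character_,
               colour = if (is.null(ivw)) NA_character_ else
                 unname(colour_key[r$classification]),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rec), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write the full screen output set
#'
#' Writes `results.tsv` (long outcome x method table), `forest.csv`
#' (forest-plot records), `instrument_qc.tsv` (per-variant F and variance
#' explained) and `screen.log` (per-outcome harmonisation drops and method
#' notes) into `dir`.
#'
#' @param x An [run_screen()] result.
#' @param exposure The instrument [summary_dataset()] used for the screen.
#' @param dir Output directory (created if needed).
#' @param n_exposure Exposure GWAS sample size for the F-approximation when
#'   EAF is missing; optional.
#' @return `dir`, invisibly.
#' @export
write_screen_results <- function(x, exposure, dir, n_exposure = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(x), file.path(dir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  export_forest(x, file.path(dir, "forest.csv"))
  qc <- instrument_diagnostics(exposure, n = n_exposure)
  qc_tab <- qc$per_snp
  qc_tab$mean_f <- qc$mean_f
  qc_tab$total_r2 <- qc$total_r2
  utils::write.table(qc_tab, file.path(dir, "instrument_qc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_lines <- unlist(lapply(x$rows, function(r) {
    if (length(r$log) == 0L) character(0) else paste0(r$outcome, ": ", r$log)
  }))
  writeLines(c(sprintf("screen of %d outcome(s), seed %d", length(x$rows),
                       x$config$seed), log_lines),
             file.path(dir, "screen.log"))
  invisible(dir)
}
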