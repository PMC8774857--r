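#' Select instrument variants by significance and locus window
#'
#' Retains variants whose p-value falls below a genome-wide significance
#' threshold and, optionally, whose position lies within a chromosome window
#' (e.g. within 1000 kB of the SERPINA6/A1 cortisol-binding-globulin locus).
#'
#' @param exposure A [summary_dataset()].
#' @param p_threshold P-value cut-off; variants with `pval < p_threshold` are
#'   kept. Default `5e-8`.
#' @param region Optional `list(chrom =, start =, end =)` restricting to
#'   1-based positions `start <= pos <= end` on `chrom`.
#' @return A [summary_dataset()] of the surviving variants.
#' @export
select_instruments <- function(exposure, p_threshold = 5e-8, region = NULL) {
  stopifnot(inherits(exposure, "summary_dataset"))
  keep <- exposure$pval < p_threshold
  if (!is.null(region)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(region)))
    in_region <- !is.na(exposure$chrom) & exposure$chrom == as.character(region$chrom) &
      !is.na(exposure$pos) & exposure$pos >= region$start & exposure$pos <= region$end
    keep <- keep & in_region
  }
  if (!any(keep)) {
    stop("no variants pass p < ", format(p_threshold),
         if (!is.null(region)) " within the region" else "", call. = FALSE)
  }
  subset_dataset(exposure, keep)
}

# Subset a summary_dataset preserving attributes
subset_dataset <- function(x, keep) {
  out <- as.data.frame(x)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(x),
            trait_name = attr(x, "trait_name"),
            trait_unit = attr(x, "trait_unit"),
            drop_log = attr(x, "drop_log"))
}

#' Read a square LD (r-squared) matrix from a delimited table
#'
#' Expects a header row of rsids and a leading rsid column; values are r² in
#' `[0, 1]`, symmetric with unit diagonal.
#'
#' @param path Path to a tab- or comma-delimited table.
#' @return A symmetric numeric matrix with rsid dimnames.
#' @export
read_ld_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop("LD matrix must be square and symmetric", call. = FALSE)
  }
  m
}

#' Greedy LD pruning of candidate instrument variants
#'
#' Emulates standard clumping semantics: candidates are ranked by ascending
#' p-value (ties broken by rsid lexicographic order); the best remaining
#' variant is kept and every other remaining variant with r² at or above the
#' threshold against it is discarded, until none remain. The kept set is
#' mutually uncorrelated below the threshold and invariant to input row order.
#'
#' @param candidates A [summary_dataset()].
#' @param ld Square symmetric r² matrix with unit diagonal, rsid dimnames
#'   covering every candidate.
#' @param r2_threshold Variants with `r2 >= r2_threshold` against a kept
#'   variant are pruned. Default 0.3.
#' @return A [summary_dataset()] of the kept variants, in kept order.
#' @export
ld_prune <- function(candidates, ld, r2_threshold = 0.3) {
  stopifnot(inherits(candidates, "summary_dataset"))
  if (!is.matrix(ld) || nrow(ld) != ncol(ld)) {
    stop("ld must be a square matrix", call. = FALSE)
  }
  ids <- candidates$rsid
  if (is.null(rownames(ld)) || is.null(colnames(ld)) ||
      !all(ids %in% rownames(ld)) || !all(ids %in% colnames(ld))) {
    stop("LD matrix dimnames do not cover all candidate rsids", call. = FALSE)
  }
  ld <- ld[ids, ids, drop = FALSE]
  if (max(abs(ld - t(ld))) > 1e-8 || any(abs(diag(ld) - 1) > 1e-8)) {
    stop("LD matrix must be symmetric with unit diagonal", call. = FALSE)
  }

  ord <- order(candidates$pval, ids)
  remaining <- ord
  kept <- integer(0)
  while (length(remaining) > 0L) {
    best <- remaining[1L]
    kept <- c(kept, best)
    remaining <- remaining[ld[ids[best], ids[remaining]] < r2_threshold]
  }
  # kept order follows the p-value ranking, so the output is invariant to the
  # input row order
  subset_dataset(candidates, kept)
}

#' Per-variant F-statistics and instrument strength
#'
#' The per-variant F-statistic is `(beta/se)^2`; a mean F above 10 is the
#' conventional marker of a strong instrument.
#'
#' @param exposure A [summary_dataset()] of instrument variants.
#' @return An `instrument_diagnostics` object: per-variant table (`rsid`,
#'   `f_stat`) plus aggregates `mean_f` and `J`.
#' @export
f_statistics <- function(exposure) {
  stopifnot(inherits(exposure, "summary_dataset"), all(exposure$se > 0))
  f <- (exposure$beta / exposure$se)^2
  structure(list(per_snp = data.frame(rsid = exposure$rsid, f_stat = f,
                                      stringsAsFactors = FALSE),
                 mean_f = mean(f), J = nrow(exposure)),
            class = "instrument_diagnostics")
}

#' Instrument variance explained in the exposure
#'
#' For standardised (SD-unit) traits the variance explained by variant j is
#' `2 * eaf_j * (1 - eaf_j) * beta_j^2` when the effect-allele frequency is
#' available, and the F-statistic approximation `F_j / (F_j + n - 2)`
#' otherwise. Per-variant values are summed, which is valid for uncorrelated
#' instruments.
#'
#' @param exposure A [summary_dataset()] of instrument variants.
#' @param n Exposure GWAS sample size; required when any variant lacks EAF.
#' @return An `instrument_diagnostics` object: per-variant table (`rsid`,
#'   `r2`) plus aggregates `total_r2` and `J`.
#' @export
variance_explained <- function(exposure, n = NULL) {
  stopifnot(inherits(exposure, "summary_dataset"))
  have_eaf <- !is.na(exposure$eaf)
  if (!all(have_eaf)) {
    if (is.null(n) || !is.numeric(n) || n <= 2) {
      stop("sample size n > 2 required when eaf is missing", call. = FALSE)
    }
  }
  r2 <- numeric(nrow(exposure))
  r2[have_eaf] <- 2 * exposure$eaf[have_eaf] * (1 - exposure$eaf[have_eaf]) *
    exposure$beta[have_eaf]^2
  if (any(!have_eaf)) {
    f <- (exposure$beta[!have_eaf] / exposure$se[!have_eaf])^2
    r2[!have_eaf] <- f / (f + n - 2)
  }
  structure(list(per_snp = data.frame(rsid = exposure$rsid, r2 = r2,
                                      stringsAsFactors = FALSE),
                 total_r2 = sum(r2), J = nrow(exposure)),
            class = "instrument_diagnostics")
}

#' Combined instrument QC table
#'
#' Convenience wrapper joining [f_statistics()] and [variance_explained()].
#'
#' @inheritParams variance_explained
#' @return An `instrument_diagnostics` object with per-variant `f_stat` and
#'   `r2`, and aggregates `mean_f`, `total_r2`, `J`.
#' @export
instrument_diagnostics <- function(exposure, n = NULL) {
  f <- f_statistics(exposure)
  r <- variance_explained(exposure, n = n)
  per <- merge(f$per_snp, r$per_snp, by = "rsid", sort = FALSE)
  structure(list(per_snp = per, mean_f = f$mean_f, total_r2 = r$total_r2,
                 J = f$J),
            class = "instrument_diagnostics")
}

#' @export
print.instrument_diagnostics <- function(x, ...) {
  cat(sprintf("<instrument_diagnostics> J = %d", x$J))
  if (!is.null(x$mean_f)) cat(sprintf(", mean F = %.1f", x$mean_f))
  if (!is.null(x$total_r2)) {
    cat(sprintf(", total R2 = %.4g (%.3g%%)", x$total_r2, 100 * x$total_r2))
  }
  cat("\n")
  print(x$per_snp, ...)
  invisible(x)
}
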