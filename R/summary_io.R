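#' Construct a summary-statistics dataset
#'
#' A `summary_dataset` holds one trait's per-variant GWAS associations: rsid,
#' optional chromosome/position, effect and other allele, optional effect-allele
#' frequency, effect size in SD units of the trait, its standard error, p-value
#' and optional sample size. Rows violating the per-variant invariants
#' (identical alleles, non-ACGT allele codes, `se <= 0`, `eaf` outside (0,1),
#' `pval` outside (0,1]) are dropped with a warning, as are duplicated rsids
#' (first occurrence kept).
#'
#' @param variants Data frame with columns `rsid`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval` and optionally `chrom`, `pos`, `eaf`,
#'   `n`.
#' @param trait_name Trait label.
#' @param trait_unit Unit of `beta` (expected `"SD"`).
#' @return An object of class `summary_dataset`: the validated variant table
#'   with attributes `trait_name`, `trait_unit` and `drop_log` (a data frame of
#'   dropped rsids and reasons).
#' @export
summary_dataset <- function(variants, trait_name = "trait", trait_unit = "SD") {
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  for (col in c("chrom", "pos", "eaf", "n")) {
    if (!col %in% names(v)) v[[col]] <- NA
  }
  v <- v[c("rsid", "chrom", "pos", "effect_allele", "other_allele",
           "eaf", "beta", "se", "pval", "n")]
  v$rsid <- as.character(v$rsid)
  v$chrom <- as.character(v$chrom)
  v$pos <- as.numeric(v$pos)
  v$effect_allele <- toupper(as.character(v$effect_allele))
  v$other_allele <- toupper(as.character(v$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n")) v[[col]] <- as.numeric(v[[col]])

  reason <- rep(NA_character_, nrow(v))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- FALSE
    reason[bad & is.na(reason)] <<- why
  }
  flag(is.na(v$rsid) | v$rsid == "", "missing rsid")
  flag(!(v$effect_allele %in% c("A", "C", "G", "T")) |
         !(v$other_allele %in% c("A", "C", "G", "T")), "allele not in A/C/G/T")
  flag(v$effect_allele == v$other_allele, "identical alleles")
  flag(is.na(v$beta), "missing beta")
  flag(is.na(v$se) | v$se <= 0, "se not > 0")
  flag(is.na(v$pval) | v$pval <= 0 | v$pval > 1, "pval outside (0,1]")
  flag(!is.na(v$eaf) & (v$eaf <= 0 | v$eaf >= 1), "eaf outside (0,1)")
  flag(duplicated(v$rsid), "duplicate rsid (first kept)")

  dropped <- !is.na(reason)
  drop_log <- data.frame(rsid = v$rsid[dropped], reason = reason[dropped],
                         stringsAsFactors = FALSE)
  if (nrow(drop_log) > 0L) {
    warning(sprintf("dropped %d of %d row(s): %s", nrow(drop_log), nrow(v),
                    paste(unique(drop_log$reason), collapse = "; ")),
            call. = FALSE)
  }
  v <- v[!dropped, , drop = FALSE]
  if (nrow(v) == 0L) stop("no variants survive validation", call. = FALSE)
  rownames(v) <- NULL
  structure(v, class = c("summary_dataset", "data.frame"),
            trait_name = trait_name, trait_unit = trait_unit,
            drop_log = drop_log)
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("<summary_dataset> %s (%s units): %d variant(s)\n",
              attr(x, "trait_name"), attr(x, "trait_unit"), nrow(x)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Canonical column names understood by [read_summary_table()]
#' @return Character vector of canonical column names.
#' @export
summary_columns <- function() {
  c(snp = "rsid", chr = "chrom", pos = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", pval = "pval", n = "n")
}

#' Read a delimited GWAS summary-statistics table
#'
#' Reads a tab- or comma-delimited text table with a header and maps its
#' columns onto the canonical schema, so any GWAS export dialect can be read
#' without code changes. Rows failing the variant invariants are dropped and
#' recorded in the returned object's `drop_log` attribute.
#'
#' @param path Path to the delimited file. The delimiter is taken from the
#'   header line (tab if present, otherwise comma).
#' @param column_map Named character vector mapping canonical names (`snp`,
#'   `chr`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pval`, `n`) to the file's column names. Unmapped canonical names default
#'   to themselves. `snp`, `effect_allele`, `other_allele`, `beta`, `se` and
#'   `pval` must resolve to existing columns; the others are optional.
#' @param trait_name Trait label; defaults to the file name.
#' @param trait_unit Unit of `beta`.
#' @return A [summary_dataset()].
#' @export
read_summary_table <- function(path, column_map = character(),
                               trait_name = NULL, trait_unit = "SD") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)

  canonical <- names(summary_columns())
  map <- stats::setNames(canonical, canonical)
  if (length(column_map) > 0L) {
    unknown <- setdiff(names(column_map), canonical)
    if (length(unknown) > 0L) {
      stop("unknown column_map key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    map[names(column_map)] <- column_map
  }
  required <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_cols <- required[!(map[required] %in% names(tab))]
  if (length(missing_cols) > 0L) {
    stop("column(s) not found in ", path, ": ",
         paste(map[missing_cols], collapse = ", "), call. = FALSE)
  }

  out <- data.frame(rsid = tab[[map["snp"]]], stringsAsFactors = FALSE)
  pick <- function(key) if (map[key] %in% names(tab)) tab[[map[key]]] else NA
  out$chrom <- as.character(pick("chr"))
  out$pos <- pick("pos")
  out$effect_allele <- pick("effect_allele")
  out$other_allele <- pick("other_allele")
  out$eaf <- pick("eaf")
  out$beta <- pick("beta")
  out$se <- pick("se")
  out$pval <- pick("pval")
  out$n <- pick("n")
  summary_dataset(out, trait_name = trait_name %||% basename(path),
                  trait_unit = trait_unit)
}

#' Write a summary dataset as TSV
#'
#' @param x A [summary_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Harmonise exposure and outcome associations onto a common effect allele
#'
#' For each rsid shared between the two datasets the outcome association is
#' re-oriented to the exposure's effect allele: identical coding is kept as-is;
#' swapped coding (effect and other allele exchanged) negates the outcome beta
#' and replaces its EAF by 1 − EAF; coding that matches only after strand
#' complement (A<->T, C<->G) is complemented and then treated the same way.
#' Palindromic variants (A/T or G/C) are retained under a forward-strand
#' assumption and flagged `is_palindromic` — no exclusions are made, matching
#' the screen's harmonisation policy — so users can filter post hoc.
#' Irreconcilable allele pairs are dropped with a logged reason.
#'
#' @param exposure,outcome [summary_dataset()] objects.
#' @return An object of class `harmonised_instrument`: a data frame with one
#'   row per harmonised variant (`rsid`, `beta_x`, `se_x`, `beta_y`, `se_y`,
#'   `eaf` — the exposure EAF — `eaf_y`, `was_flipped`, `is_palindromic`) and a
#'   `drop_log` attribute recording shared rsids that could not be reconciled.
#' @export
#' @examples
#' exp <- summary_dataset(data.frame(
#'   rsid = "rs1", effect_allele = "A", other_allele = "G",
#'   beta = 0.10, se = 0.01, pval = 1e-10, eaf = 0.3))
#' out <- summary_dataset(data.frame(
#'   rsid = "rs1", effect_allele = "G", other_allele = "A",
#'   beta = -0.05, se = 0.02, pval = 0.01, eaf = 0.7))
#' harmonise(exp, out) # beta_y = +0.05, was_flipped = TRUE
harmonise <- function(exposure, outcome) {
  stopifnot(inherits(exposure, "summary_dataset"),
            inherits(outcome, "summary_dataset"))
  shared <- intersect(exposure$rsid, outcome$rsid)
  if (length(shared) == 0L) {
    stop("no shared rsids between exposure and outcome", call. = FALSE)
  }
  ex <- exposure[match(shared, exposure$rsid), , drop = FALSE]
  ou <- outcome[match(shared, outcome$rsid), , drop = FALSE]

  n <- length(shared)
  beta_y <- ou$beta
  eaf_y <- ou$eaf
  was_flipped <- logical(n)
  keep <- logical(n)
  reason <- rep(NA_character_, n)

  ea_o <- ou$effect_allele
  oa_o <- ou$other_allele
  for (j in seq_len(n)) {
    ea_x <- ex$effect_allele[j]; oa_x <- ex$other_allele[j]
    ea <- ea_o[j]; oa <- oa_o[j]
    direct <- (ea == ea_x && oa == oa_x) || (ea == oa_x && oa == ea_x)
    if (!direct) {
      # try the opposite strand; a palindromic pair never reaches this branch
      # because its complement is the same allele set
      ea <- complement_alleles(ea); oa <- complement_alleles(oa)
      direct <- (ea == ea_x && oa == oa_x) || (ea == oa_x && oa == ea_x)
      if (!direct) {
        reason[j] <- "alleles irreconcilable"
        next
      }
    }
    keep[j] <- TRUE
    if (ea != ea_x) { # swapped relative to the exposure's effect allele
      beta_y[j] <- -beta_y[j]
      eaf_y[j] <- 1 - eaf_y[j]
      was_flipped[j] <- TRUE
    }
  }

  drop_log <- data.frame(rsid = shared[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  if (nrow(drop_log) > 0L) {
    warning(sprintf("dropped %d shared variant(s) with irreconcilable alleles",
                    nrow(drop_log)), call. = FALSE)
  }
  if (!any(keep)) stop("no variant could be harmonised", call. = FALSE)

  h <- data.frame(
    rsid = shared[keep],
    beta_x = ex$beta[keep], se_x = ex$se[keep],
    beta_y = beta_y[keep], se_y = ou$se[keep],
    eaf = ex$eaf[keep], eaf_y = eaf_y[keep],
    was_flipped = was_flipped[keep],
    is_palindromic = is_palindromic_pair(ex$effect_allele[keep],
                                         ex$other_allele[keep]),
    stringsAsFactors = FALSE
  )
  rownames(h) <- NULL
  structure(h, class = c("harmonised_instrument", "data.frame"),
            exposure_name = attr(exposure, "trait_name"),
            outcome_name = attr(outcome, "trait_name"),
            drop_log = drop_log)
}

#' @export
print.harmonised_instrument <- function(x, ...) {
  cat(sprintf("<harmonised_instrument> %s -> %s: %d variant(s)\n",
              attr(x, "exposure_name") %||% "exposure",
              attr(x, "outcome_name") %||% "outcome", nrow(x)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Write a harmonised instrument as TSV for audit
#'
#' @param h A [harmonise()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonised <- function(h, path) {
  utils::write.table(as.data.frame(h), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
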