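#' @keywords internal
"_PACKAGE"

# z quantile fixed at print precision so confidence limits reproduce exactly
# across platforms
Z975 <- 1.959964

#' Derive a deterministic child seed from a master seed and string labels
#'
#' Per-outcome and per-method random streams are derived from the master seed
#' plus string labels (outcome name, method name), so adding or removing an
#' outcome or a method never perturbs another's draws.
#'
#' @param seed Master integer seed.
#' @param ... Character or numeric labels mixed into the hash.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "IL-8", "presso")
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, Mersenne prime modulus
  h <- as.double(seed) %% m
  for (lab in list(...)) {
    for (code in utf8ToInt(paste0("|", paste(as.character(lab), collapse = ",")))) {
      # 31-ary polynomial rolling hash, kept in double-safe range
      h <- (h * 31 + code) %% m
    }
  }
  as.integer(h)
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Nucleotide strand complement for allele codes
complement_alleles <- function(x) chartr("ACGT", "TGCA", x)

is_palindromic_pair <- function(a1, a2) a2 == complement_alleles(a1)

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-sided normal p-value, floored so extreme z never underflows to an
# invalid p = 0
two_sided_p <- function(z) pmax(2 * stats::pnorm(-abs(z)), 1e-300)
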