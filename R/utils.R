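# Internal helpers shared across modules.

#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Genotype call vocabulary. Two-letter codes over the alphabet {I, J, X}:
# I = indica-reference allele, J = japonica-reference allele, X = a scored
# band matching neither reference (e.g. the third band of a triallelic
# marker). NN marks a null (no amplification).
call_codes <- function() c("II", "JJ", "IJ", "NN", "IX", "JX", "XX")

# Allele-letter order used to canonicalise heterozygous codes (JI -> IJ).
allele_order <- c("I", "J", "X")

#' Canonicalise genotype call codes
#'
#' Uppercases, trims, maps missing-cell synonyms ("", "NA", NA) to "NN" and
#' sorts the two allele letters so that e.g. "JI" becomes "IJ". Invalid codes
#' are returned as NA_character_ so callers can report them.
#' @param x character vector of raw cell values
#' @return character vector of canonical codes or NA for invalid input
#' @keywords internal
canonical_call <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[is.na(x) | x == "" | x == "NA"] <- "NN"
  two <- nchar(x) == 2L & x != "NN"
  parts <- strsplit(x[two], "", fixed = TRUE)
  x[two] <- vapply(parts, function(p) {
    p <- p[order(match(p, allele_order))]
    paste(p, collapse = "")
  }, character(1))
  x[!(x %in% call_codes())] <- NA_character_
  x
}

is_het_call <- function(x) x %in% c("IJ", "IX", "JX")
is_null_call <- function(x) x == "NN"

# Count of I / J alleles carried by each call (X contributes to neither).
allele_count <- function(x, letter) {
  vapply(strsplit(x, "", fixed = TRUE), function(p) sum(p == letter), integer(1))
}

stop_validation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "indelindex_validation_error")
}

stop_computation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "indelindex_computation_error")
}

# Evaluate `expr` with the RNG seeded by `seed` (when non-NULL), restoring
# the caller's RNG state afterwards so analysis calls do not perturb the
# global random stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
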