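# Internal helpers shared across modules.

#' Evaluate an expression under a temporary, isolated RNG state
#'
#' All stochastic steps in the package (down-sampling, splitting, fold
#' assignment, model fitting, sequence simulation) run through this wrapper so
#' that results are reproducible from an integer seed and never perturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Stop with a formatted message, no call in output.
abort <- function(...) stop(sprintf(...), call. = FALSE)

# Round half away from zero, the convention used for printed percentages.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a proportion as a percentage string
#'
#' @param x proportion in \[0, 1\].
#' @param digits decimal places (default 1, matching reported accuracies).
#' @return character, e.g. `"79.7%"`.
#' @export
#' @examples
#' format_percent((0.791 + 0.802) / 2) # "79.7%"
format_percent <- function(x, digits = 1) {
  sprintf(paste0("%.", digits, "f%%"), round_half_up(100 * x, digits))
}

# Validate a vector of DNA sequences: uppercase and check the strict
# {A,C,G,T} alphabet. `ids` are used to name offenders in error messages.
validate_sequences <- function(sequences, ids = NULL) {
  if (is.null(ids)) ids <- as.character(seq_along(sequences))
  sequences <- toupper(sequences)
  if (any(!nzchar(sequences))) {
    abort("empty sequence for record '%s'", ids[which(!nzchar(sequences))[1]])
  }
  bad <- regmatches(sequences, regexpr("[^ACGT]", sequences))
  offenders <- which(grepl("[^ACGT]", sequences))
  if (length(offenders)) {
    abort(
      "record '%s' contains invalid character '%s' (alphabet is A/C/G/T)",
      ids[offenders[1]], bad[1]
    )
  }
  sequences
}
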