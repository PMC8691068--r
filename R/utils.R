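#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

# Tolerance for sibling-probability groups summing to one. Published
# transition tables are rounded, so load_parameters() renormalizes groups
# that are off by more than this but within [0.99, 1.01]; validation rejects
# anything worse.
PROB_TOL <- 1e-9

stop_nassim <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# round half away from zero to integer (printed percent-difference convention)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
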