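# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stop_input <- function(...) stop(..., call. = FALSE)

# message() wrapper used for drop/removal counters so callers can silence
# the package uniformly via suppressMessages().
pes_log <- function(fmt, ...) message(sprintf(fmt, ...))

# Validate a probability-like scalar.
check_prob <- function(x, name, open_left = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x > 1 || x < 0 || (open_left && x == 0)) {
    stop_input(name, " must be a single value in ", if (open_left) "(0,1]" else "[0,1]")
  }
  invisible(x)
}

# Upper-case allele strings and check ACGT-ish content is not enforced:
# indel alleles are allowed, only case is normalised.
norm_allele <- function(a) toupper(trimws(as.character(a)))

is_palindromic <- function(a1, a2) {
  flip <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(flip[a1]) & flip[a1] == a2
}

# Deterministic seed stream: derive child seeds from a master seed without
# exhausting the 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 8191) %% 2147483647)
}
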