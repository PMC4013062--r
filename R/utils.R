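#' @keywords internal
"_PACKAGE"

# stop() without the call, so error messages read as validation messages
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_prop <- function(x, open_left = TRUE, closed_right = FALSE) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x))) return(FALSE)
  lo <- if (open_left) x > 0 else x >= 0
  hi <- if (closed_right) x <= 1 else x < 1
  lo && hi
}

# Derive independent sub-seeds from one master seed so each generator
# component is individually reproducible. Kept below 2^31 - 1.
derive_seeds <- function(seed, n) {
  stopifnot(is_count(seed + 1))  # allow 0
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
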