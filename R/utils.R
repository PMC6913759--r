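# Internal helpers shared across the pipeline.

# Derive `n` child seeds from one master seed. Children are drawn inside an
# isolated RNG scope so the caller's RNG stream is untouched; all derived
# seeds stay below .Machine$integer.max.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(min), format(max)),
          class = "painvol_config_error")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min),
          class = "painvol_config_error")
  }
  invisible(as.integer(x))
}

# Two-level class factor used throughout: "low" is the reference/majority
# class, "high" the positive class (sensitivity is accuracy on "high").
class_factor <- function(x) {
  factor(as.character(x), levels = c("low", "high"))
}
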