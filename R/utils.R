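# Internal helpers shared across modules.

VESSEL_LABELS <- c("vessel", "out_of_plane", "debris")

stop_validation <- function(...) {
  stop(structure(
    class = c("vesseltrace_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_io <- function(...) {
  stop(structure(
    class = c("vesseltrace_io_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation(name, " must be a single finite number")
  if (strict_lower && x <= lower)
    stop_validation(name, " must be > ", lower)
  if (!strict_lower && x < lower)
    stop_validation(name, " must be >= ", lower)
  if (strict_upper && x >= upper)
    stop_validation(name, " must be < ", upper)
  if (!strict_upper && x > upper)
    stop_validation(name, " must be <= ", upper)
  invisible(x)
}

assert_label <- function(label) {
  if (!is.character(label) || length(label) != 1L || !(label %in% VESSEL_LABELS))
    stop_validation("label must be one of: ", paste(VESSEL_LABELS, collapse = ", "),
                    " (got '", paste(label, collapse = ","), "')")
  invisible(label)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route their `seed` argument
# through this so that global RNG state is never disturbed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_validation("seed must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a per-item child seed from a master seed; keeps results reproducible
# under any iteration order and stays inside 32-bit integer range.
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 7919 + as.numeric(index) * 104729) %%
               2147483647)
}
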