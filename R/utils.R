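#' @keywords internal
"_PACKAGE"

# Validation helpers -----------------------------------------------------

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE,
                         integer = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop_field(field, "must be supplied")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (strict_min && x <= min) stop_field(field, sprintf("must be > %g", min))
  if (!strict_min && x < min) stop_field(field, sprintf("must be >= %g", min))
  if (strict_max && x >= max) stop_field(field, sprintf("must be < %g", max))
  if (!strict_max && x > max) stop_field(field, sprintf("must be <= %g", max))
  if (integer && x != round(x)) stop_field(field, "must be a whole number")
  invisible(NULL)
}

# Deterministic seed streams ---------------------------------------------

# Submodule RNG streams are derived from the single top-level seed with a
# Lehmer step, so that e.g. adding permutation shuffles never perturbs the
# simulation draws. Arithmetic stays exact in doubles (< 2^53) and the
# result is a valid 32-bit seed.
derive_seed <- function(seed, stream) {
  m <- 2147483647 # 2^31 - 1
  s <- (abs(as.numeric(seed)) %% m)
  as.integer((s * 48271 + as.numeric(stream)) %% m)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
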