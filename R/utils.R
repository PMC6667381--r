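# Shared validation and condition helpers. All user-facing errors are classed
# so callers (and the CLI) can distinguish domain errors from schema errors.

stop_rostrack <- function(msg, class = "rostrack_error", ...) {
  stop(errorCondition(msg, ..., class = unique(c(class, "rostrack_error"))))
}

stop_domain <- function(msg, ...) stop_rostrack(msg, class = c("rostrack_domain_error", "rostrack_error"), ...)
stop_schema <- function(msg, ...) stop_rostrack(msg, class = c("rostrack_schema_error", "rostrack_error"), ...)

warn_rostrack <- function(msg, class = "rostrack_warning") {
  warning(warningCondition(msg, class = unique(c(class, "rostrack_warning"))))
}

check_scalar <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE,
                         allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L) {
    stop_domain(sprintf("`%s` must be a single number", name))
  }
  if (is.na(x)) {
    if (allow_na) return(invisible(x))
    stop_domain(sprintf("`%s` must not be NA", name))
  }
  if (strict_min && x <= min) {
    stop_domain(sprintf("`%s` must be > %g (got %g)", name, min, x))
  }
  if (!strict_min && x < min) {
    stop_domain(sprintf("`%s` must be >= %g (got %g)", name, min, x))
  }
  if (x > max) stop_domain(sprintf("`%s` must be <= %g (got %g)", name, max, x))
  invisible(x)
}

check_numeric_vec <- function(x, name, min = -Inf, strict_min = FALSE,
                              min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len) {
    stop_domain(sprintf("`%s` must be a numeric vector with at least %d values",
                        name, min_len))
  }
  if (anyNA(x)) stop_domain(sprintf("`%s` must not contain NA", name))
  if (strict_min && any(x <= min)) {
    stop_domain(sprintf("all values of `%s` must be > %g", name, min))
  }
  if (!strict_min && any(x < min)) {
    stop_domain(sprintf("all values of `%s` must be >= %g", name, min))
  }
  invisible(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  check_scalar(seed, "seed")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}
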