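# internal helpers: input checking, seeded evaluation, logging

abort_input <- function(msg, class = "tptcr_invalid_input", ...) {
  rlang::abort(msg, class = c(class, "tptcr_error"), ...)
}

check_number <- function(x, name, positive = FALSE, integerish = FALSE,
                         min = NULL) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x)) {
    abort_input(sprintf("`%s` must be a non-missing number.", name))
  }
  if (positive && any(x <= 0)) {
    abort_input(sprintf("`%s` must be > 0 (got %s).", name,
                        paste(signif(x[x <= 0], 6), collapse = ", ")))
  }
  if (integerish && any(x != round(x))) {
    abort_input(sprintf("`%s` must be a whole number.", name))
  }
  if (!is.null(min) && any(x < min)) {
    abort_input(sprintf("`%s` must be >= %s.", name, min))
  }
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL uses (and advances) the current RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  check_number(seed, "seed", integerish = TRUE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Structured log line on stderr; level in DEBUG < INFO < WARN < ERROR.
tptcr_log <- function(level, ...) {
  msg <- paste0(...)
  cat(sprintf("[%s] %s %s\n", level,
              format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), msg),
      file = stderr())
  invisible(msg)
}
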