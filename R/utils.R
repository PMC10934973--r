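# Internal helpers: structured error conditions and seeded evaluation.

cb3d_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "cb3d_error", "error")))
}

abort_parameter <- function(message, ...) {
  cb3d_abort(message, "cb3d_parameter_error", ...)
}

abort_detection <- function(message, stage = NULL, ...) {
  msg <- if (is.null(stage)) message else sprintf("[%s] %s", stage, message)
  cb3d_abort(msg, "cb3d_detection_error", stage = stage, ...)
}

abort_estimation <- function(message, ...) {
  cb3d_abort(message, "cb3d_estimation_error", ...)
}

abort_ambiguity <- function(message, ...) {
  cb3d_abort(message, c("cb3d_ambiguity_error", "cb3d_estimation_error"), ...)
}

abort_metric <- function(message, ...) {
  cb3d_abort(message, "cb3d_metric_error", ...)
}

abort_io <- function(message, ...) {
  cb3d_abort(message, "cb3d_io_error", ...)
}

abort_format <- function(message, ...) {
  cb3d_abort(message, c("cb3d_format_error", "cb3d_io_error"), ...)
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so generators never perturb user-level randomness.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
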