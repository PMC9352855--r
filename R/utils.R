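# Internal helpers: classed conditions, seeded evaluation, logging.

usem_abort <- function(class, message, data = list(), call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "usemnet_error", "error", "condition"),
    c(list(message = message, call = call), data)
  )
  stop(cond)
}

config_error <- function(message, ...) usem_abort("usemnet_config_error", message, list(...))
input_error <- function(message, ...) usem_abort("usemnet_input_error", message, list(...))
load_error <- function(message, ...) usem_abort("usemnet_load_error", message, list(...))
generation_error <- function(message, ...) usem_abort("usemnet_generation_error", message, list(...))
estimation_error <- function(message, ...) usem_abort("usemnet_estimation_error", message, list(...))

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

log_msg <- function(level, ...) {
  threshold <- getOption("usemnet.log_level", "warn")
  if (.log_levels[[level]] >= .log_levels[[threshold]] && threshold != "quiet") {
    message(sprintf("[usemnet %s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
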