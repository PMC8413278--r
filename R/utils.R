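# Internal helpers shared across modules.

# stopifnot-style check with a typed rlang error
check_that <- function(ok, msg, class = "phasedeath_validation_error") {
  if (!isTRUE(ok)) rlang::abort(msg, class = class)
  invisible(TRUE)
}

check_condition <- function(condition) {
  check_that(
    is.character(condition) && length(condition) >= 1L &&
      all(condition %in% CONDITIONS),
    paste0(
      "`condition` must be one of ",
      paste(sQuote(CONDITIONS), collapse = ", "), "."
    )
  )
  condition
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded sub-steps never perturb the global stream.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Derive a child seed from a parent seed and a stream index, staying well
# below .Machine$integer.max.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream) * 7919L) %% 2147483L + 1L
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}
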