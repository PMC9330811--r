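#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Deterministic 32-bit sub-seed stream: one global seed drives all phantom
# randomness; item i of a run gets its own reproducible seed.
sub_seed <- function(seed, i) {
  as.integer((abs(as.double(seed)) * 48271 + as.double(i) * 8191) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Noiseless designed cohorts make lm's perfect-fit warning expected noise.
quiet_perfect <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}
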