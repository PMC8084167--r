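# internal helpers: seeding, rounding, validation

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  seed = NULL means "use the current RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Stage-offset seed derivation: one global seed, deterministic independent
# streams per pipeline stage.
stage_seed <- function(seed, stage, index = 0L) {
  offset <- switch(stage,
    autoencoder = 0L,
    subnetwork  = 1L + as.integer(index),
    stacker     = 1000L,
    splits      = 2000L,
    folds       = 3000L,
    stop("unknown stage: ", stage)
  )
  (as.integer(seed) + offset) %% 2147483647L
}

# Round half away from zero (tables use half-up on positive percentages).
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x) && x >= min
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
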