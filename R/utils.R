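# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators never disturb user code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derived from the global seed and the stage
# name (characters folded into a 31-bit integer).
stage_seed <- function(global_seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer((as.numeric(global_seed) %% 2147483647 + h) %% 2147483647)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

# Truncated-normal draws by inverse-CDF; exact on [lo, hi].
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}
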