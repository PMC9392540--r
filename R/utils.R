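#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Hierarchical seeding: every stochastic component of a run draws its own
#' seed deterministically from one master seed plus a short component label,
#' so stages can be re-run independently without sharing RNG state.
#'
#' @param master integer master seed.
#' @param label character label naming the component (e.g. "lesions").
#' @return An integer seed in \code{[1, 2^31 - 1]}.
#' @export
derive_seed <- function(master, label) {
  stopifnot(length(master) == 1, is.finite(master), length(label) == 1)
  m <- 2147483647  # 2^31 - 1, keeps seeds valid 32-bit integers
  s <- abs(as.numeric(master)) %% m
  for (b in utf8ToInt(as.character(label))) {
    s <- (s * 69069 + b) %% m
  }
  as.integer(s) + 1L
}

# Evaluate `code` under a local RNG seed, restoring global RNG state after.
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
  code
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
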