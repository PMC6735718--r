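#' @importFrom stats median rlnorm runif
#' @importFrom utils write.table head tail
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so library code never perturbs user code.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Population (not sample) standard deviation; 0 for a single observation.
pop_sd <- function(x) {
  if (length(x) <= 1L) return(0)
  sqrt(mean((x - mean(x))^2))
}

# Most frequent value; ties broken by first occurrence.
modal_value <- function(x) {
  ux <- unique(x)
  ux[which.max(tabulate(match(x, ux)))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
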