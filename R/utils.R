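#' @importFrom stats approx coef complete.cases convolve cor dnorm lm median
#'   p.adjust pf quantile rbinom rlnorm rnorm rpois runif sd t.test var aov
#' @importFrom utils head tail
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards (so seeded helpers do not perturb user code).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# One global stream per session, split into named substreams: each generator
# component draws from its own derived seed, so adding a component (or turning
# noise off) never perturbs the event schedule.
substream_seeds <- function(seed) {
  with_seed(seed, {
    s <- sample.int(.Machine$integer.max - 1L, 8L)
    names(s) <- c("events", "latencies", "motion", "noise",
                  "spikes", "hazard", "shuffle", "misc")
    s
  })
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stopf("configuration error: `%s` must be a single positive number", name)
  invisible(x)
}
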