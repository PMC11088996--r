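# internal helpers

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# set RNG state locally when a seed is given, restoring on exit
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# sampling interval from a time vector (robust to float noise)
sample_dt <- function(t) {
  if (length(t) < 2L) stop("need at least two samples to infer a rate")
  stats::median(diff(t))
}

# indices of runs of TRUE lasting at least min_len; returns list of ranges
true_runs <- function(x, min_len = 1L) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  if (!any(keep)) return(list(starts = integer(), ends = integer()))
  list(starts = starts[keep], ends = ends[keep])
}

stop_stage <- function(stage, e) {
  stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
}
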