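#' @useDynLib vasculm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# internal assertion helpers ------------------------------------------------

stop_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
}

assert_scalar_num <- function(x, name, positive = FALSE) {
  stop_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
          sprintf("`%s` must be a finite numeric scalar", name))
  if (positive) stop_if(x <= 0, sprintf("`%s` must be > 0", name))
  invisible(x)
}

# centered moving average; the window shrinks symmetrically at the edges so
# linear sequences are preserved exactly
moving_average <- function(x, window) {
  if (window <= 1L || length(x) < 2L) return(x)
  half <- window %/% 2L
  n <- length(x)
  out <- numeric(n)
  cs <- cumsum(c(0, x))
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    out[i] <- (cs[i + h + 1L] - cs[i - h]) / (2L * h + 1L)
  }
  out
}

# run fun() with a temporary RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, fun) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}
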