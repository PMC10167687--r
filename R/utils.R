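# internal helpers shared across modules

# run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched so pipeline results do not depend on call order
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# centered moving average of length `k` (odd); edges use the partial window
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  h <- (k - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# length of the longest run of TRUE
longest_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

# mean pairwise Pearson correlation between rows of `m`; undefined pairs
# (zero variance) count as 0
mean_pairwise_cor <- function(m) {
  if (nrow(m) < 2L) return(NA_real_)
  cc <- suppressWarnings(cor(t(m)))
  vals <- cc[upper.tri(cc)]
  vals[is.na(vals)] <- 0
  mean(vals)
}

# indices of strict-or-plateau local maxima of x restricted to idx range
local_maxima <- function(x) {
  n <- length(x)
  if (n == 1L) return(1L)
  out <- integer(0)
  for (i in seq_len(n)) {
    left_ok <- i == 1L || x[i] >= x[i - 1L]
    right_ok <- i == n || x[i] >= x[i + 1L]
    strict <- (i > 1L && x[i] > x[i - 1L]) || (i < n && x[i] > x[i + 1L]) ||
      (i == 1L && n > 1L && x[i] > x[i + 1L]) || (i == n && n > 1L && x[i] > x[i - 1L])
    if (left_ok && right_ok && strict) out <- c(out, i)
  }
  if (!length(out)) out <- which.max(x)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
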