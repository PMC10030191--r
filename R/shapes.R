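# Shape-constrained least squares on a small grid of rigidities.
#
# Weighted pool-adjacent-violators (PAVA) plus the derived umbrella (rise-fall)
# and valley (fall-rise) fits used by the meandering test. Written here rather
# than wrapped from stats::isoreg because the test needs weights, decreasing
# fits and split-point (umbrella) variants; stats::isoreg serves as an
# independent cross-check in the test suite.

#' Weighted isotonic regression (pool-adjacent-violators)
#'
#' @param y Response values.
#' @param w Positive weights, same length.
#' @param decreasing Fit a nonincreasing sequence instead.
#' @return Fitted values, same length as `y`.
#' @keywords internal
pava <- function(y, w = rep(1, length(y)), decreasing = FALSE) {
  if (decreasing) return(-pava(-y, w))
  n <- length(y)
  if (n <= 1L) return(y)
  val <- numeric(n); wt <- numeric(n); len <- integer(n)
  b <- 0L
  for (i in seq_len(n)) {
    b <- b + 1L
    val[b] <- y[i]; wt[b] <- w[i]; len[b] <- 1L
    while (b > 1L && val[b - 1L] > val[b]) {
      val[b - 1L] <- (wt[b - 1L] * val[b - 1L] + wt[b] * val[b]) /
        (wt[b - 1L] + wt[b])
      wt[b - 1L] <- wt[b - 1L] + wt[b]
      len[b - 1L] <- len[b - 1L] + len[b]
      b <- b - 1L
    }
  }
  rep(val[seq_len(b)], len[seq_len(b)])
}

wrss <- function(y, fit, w) sum(w * (y - fit)^2)

# Best monotone fit (increasing or decreasing, whichever is closer).
fit_monotone <- function(y, w) {
  up <- pava(y, w); dn <- pava(y, w, decreasing = TRUE)
  if (wrss(y, up, w) <= wrss(y, dn, w)) {
    list(fit = up, rss = wrss(y, up, w), direction = "increasing")
  } else {
    list(fit = dn, rss = wrss(y, dn, w), direction = "decreasing")
  }
}

# Rise-fall (umbrella) fit: increasing on 1..k, decreasing on (k+1)..m,
# minimised over the split point. Contains every monotone fit as a special
# case, so its RSS never exceeds the monotone RSS.
fit_rise_fall <- function(y, w) {
  m <- length(y)
  best <- NULL
  for (k in seq_len(m - 1L)) {
    f <- c(pava(y[1:k], w[1:k]),
           pava(y[(k + 1L):m], w[(k + 1L):m], decreasing = TRUE))
    r <- wrss(y, f, w)
    if (is.null(best) || r < best$rss) best <- list(fit = f, rss = r, split = k)
  }
  best
}

fit_fall_rise <- function(y, w) {
  m <- length(y)
  best <- NULL
  for (k in seq_len(m - 1L)) {
    f <- c(pava(y[1:k], w[1:k], decreasing = TRUE),
           pava(y[(k + 1L):m], w[(k + 1L):m]))
    r <- wrss(y, f, w)
    if (is.null(best) || r < best$rss) best <- list(fit = f, rss = r, split = k)
  }
  best
}
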