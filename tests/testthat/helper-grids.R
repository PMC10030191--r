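# Shared fixtures for the model tests.

default_panel <- c(0.5, 2, 8, 16, 32, 64)

log_grid <- function(lo, hi, n = 512) exp(seq(log(lo), log(hi), length.out = n))

# Count strict local maxima at interior grid positions.
n_interior_maxima <- function(v) {
  n <- length(v)
  sum(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n])
}

# Number of sign changes of the discrete derivative (flat steps ignored).
n_sign_changes <- function(v) {
  d <- sign(diff(v))
  d <- d[d != 0]
  sum(diff(d) != 0)
}
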