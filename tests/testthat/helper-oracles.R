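# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: closed forms, dense-grid search, brute-force
# numerical integration and direct geometric tests.

# Ideal triangle wave with period 2*pi in x, unit peak at x = pi/2.
triangle_wave <- function(x) (2 / pi) * asin(sin(x))

# Brute-force marginal log-likelihood of a random-intercept logistic model:
# per-cluster trapezoid integration over the random intercept.
brute_force_loglik <- function(beta, sigma, X, y, id, grid_n = 20001,
                               span = 12) {
  ll <- 0
  bg <- seq(-span * max(sigma, 0.1), span * max(sigma, 0.1),
            length.out = grid_n)
  h <- bg[2] - bg[1]
  phi <- stats::dnorm(bg, 0, sigma)
  eta0 <- drop(X %*% beta)
  for (i in unique(id)) {
    sel <- id == i
    # log-likelihood of cluster i at each grid value of the intercept
    lp <- outer(bg, eta0[sel], "+")
    loglik_b <- rowSums(stats::plogis(lp, log.p = TRUE) * rep(y[sel],
                                                              each = grid_n) +
                        stats::plogis(-lp, log.p = TRUE) *
                          rep(1 - y[sel], each = grid_n))
    f <- exp(loglik_b) * phi
    ll <- ll + log(sum((f[-1] + f[-grid_n]) / 2) * h)
  }
  ll
}

# TRUE when the closed polygon (last vertex repeats the first) has any pair
# of properly crossing non-adjacent edges.
polygon_self_intersects <- function(v) {
  n <- nrow(v) - 1L
  a <- v[seq_len(n), , drop = FALSE]
  b <- v[c(2:n, 1L), , drop = FALSE]
  idx <- t(utils::combn(n, 2L))
  adjacent <- idx[, 2L] - idx[, 1L] == 1L |
    (idx[, 1L] == 1L & idx[, 2L] == n)
  idx <- idx[!adjacent, , drop = FALSE]
  p1 <- a[idx[, 1L], , drop = FALSE]; p2 <- b[idx[, 1L], , drop = FALSE]
  p3 <- a[idx[, 2L], , drop = FALSE]; p4 <- b[idx[, 2L], , drop = FALSE]
  cross2 <- function(o, p, q)
    (p[, 1L] - o[, 1L]) * (q[, 2L] - o[, 2L]) -
    (p[, 2L] - o[, 2L]) * (q[, 1L] - o[, 1L])
  d1 <- cross2(p3, p4, p1); d2 <- cross2(p3, p4, p2)
  d3 <- cross2(p1, p2, p3); d4 <- cross2(p1, p2, p4)
  any(((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

# Bounding box (rows, cols) of the dark foreground of a grayscale PNG matrix.
foreground_bbox <- function(img) {
  fg <- which(img < 0.5, arr.ind = TRUE)
  c(height = diff(range(fg[, 1L])) + 1L, width = diff(range(fg[, 2L])) + 1L)
}

# Small factorial design for fast fitting tests.
mini_design <- function() {
  stimulus_design(frequency = c(4L, 6L, 9L), amplitude = c(0.1, 0.4),
                  spikiness = c(0L, 30L))
}
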