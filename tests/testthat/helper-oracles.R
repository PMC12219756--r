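# Independent oracles used across the suite.

# Uniform field shortcut
uniform_field <- function(value, N = 16, L = 1, t = 0) {
  order_parameter_field(matrix(value, N, N), L = L, t = t)
}

# Closed-form solution of the spatially uniform model with phi_bar = 0.5:
# with v = (phi - 1/2)^2 the cubic reduces to the logistic
# v' = (1/(2 eps^2)) v (1 - 4 v), hence
# v(t) = (1/4) / (1 + (1/(4 v0) - 1) exp(-t / (2 eps^2))).
# (Verified against deSolve::ode at atol = rtol = 1e-12.)
closed_form_uniform <- function(t, phi0, eps) {
  v0 <- (phi0 - 0.5)^2
  if (v0 == 0) return(rep(0.5, length(t)))
  v <- 0.25 / (1 + (0.25 / v0 - 1) * exp(-t / (2 * eps^2)))
  0.5 + sign(phi0 - 0.5) * sqrt(v)
}

# Scalar classical RK4 for u' = eps^-2 u (1 - u) (u - phi_bar)
scalar_rk4 <- function(phi0, phi_bar, eps, dt, nsteps) {
  f <- function(u) u * (1 - u) * (u - phi_bar) / eps^2
  u <- phi0
  for (k in seq_len(nsteps)) {
    k1 <- f(u)
    k2 <- f(u + dt / 2 * k1)
    k3 <- f(u + dt / 2 * k2)
    k4 <- f(u + dt * k3)
    u <- u + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  u
}

# Brute-force flood fill: number of 4-connected TRUE components with at
# least `min_cells` cells. Deliberately naive (repeated scans).
flood_fill_count <- function(mask, min_cells = 1) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j] || seen[i, j]) next
      stack <- list(c(i, j))
      seen[i, j] <- TRUE
      size <- 0L
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        size <- size + 1L
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
              mask[q[1], q[2]] && !seen[q[1], q[2]]) {
            seen[q[1], q[2]] <- TRUE
            stack[[length(stack) + 1]] <- q
          }
        }
      }
      if (size >= min_cells) count <- count + 1L
    }
  }
  count
}

# Restrict a fine cell-centered field to a grid half as fine by averaging
# each 2x2 block (exact cell-average coarsening).
coarsen2 <- function(values) {
  N <- nrow(values)
  idx <- seq(1, N, by = 2)
  (values[idx, idx] + values[idx + 1, idx] +
     values[idx, idx + 1] + values[idx + 1, idx + 1]) / 4
}
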