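test_that("Laplacian of a constant field is identically zero", {
  f <- uniform_field(0.37, N = 12)
  expect_identical(laplacian_neumann(f), matrix(0, 12, 12))
})

test_that("Laplacian applies the 5-point stencil with mirror ghosts", {
  # unit spike at an interior cell, h = 0.5 (N = 4, L = 1)
  v <- matrix(0, 4, 4)
  v[2, 2] <- 1
  f <- order_parameter_field(v, L = 1)
  expect_identical(f$h, 0.5)
  lap <- laplacian_neumann(f)
  expect_identical(lap[2, 2], -16)
  expect_identical(lap[1, 2], 4)
  expect_identical(lap[3, 2], 4)
  expect_identical(lap[2, 1], 4)
  expect_identical(lap[2, 3], 4)
  expect_identical(sum(lap != 0), 5L)
  # mirror ghosts: a spike at a corner loses two stencil neighbours
  w <- matrix(0, 4, 4)
  w[1, 1] <- 1
  lapw <- laplacian_neumann(order_parameter_field(w, L = 1))
  expect_identical(lapw[1, 1], -8)  # (1 + 1 + 0 + 0 - 4) / h^2 with mirrors
})

test_that("Laplacian converges at second order on an analytic test", {
  # g = cos(pi x / L) cos(pi y / L) is Neumann-compatible; lap g = -2 (pi/L)^2 g
  err <- function(N) {
    L <- 1
    x <- -L + 2 * L / N * (seq_len(N) - 0.5)
    g <- outer(x, x, function(a, b) cos(pi * a / L) * cos(pi * b / L))
    f <- order_parameter_field(g, L = L)
    exact <- -2 * (pi / L)^2 * g
    max(abs(laplacian_neumann(f) - exact))
  }
  order_est <- log2(err(32) / err(64))
  expect_gt(order_est, 1.9)
  expect_lt(order_est, 2.1)
})

test_that("rhs combines diffusion and reaction as D(t) lap + eps^-2 f", {
  p <- model_parameters()  # D0 = 0.01, T = 0.8, eps = 0.1, phi_bar = 0.5
  # uniform at phi_bar: both terms vanish at any t
  f <- uniform_field(0.5, N = 8)
  expect_identical(model_rhs(f, 0, p), matrix(0, 8, 8))
  expect_identical(model_rhs(f, 0.9, p), matrix(0, 8, 8))
  # uniform at 0.6: Laplacian zero, reaction 100 * 0.6 * 0.4 * 0.1 = 2.4
  g <- uniform_field(0.6, N = 8)
  expect_equal(model_rhs(g, 0, p), matrix(2.4, 8, 8))
  # past T the diffusion contribution is exactly absent
  set.seed(1)
  v <- matrix(runif(64, 0.3, 0.7), 8, 8)
  h <- order_parameter_field(v)
  expect_equal(model_rhs(h, 0.8, p),
               reaction(v, p$phi_bar) / p$epsilon^2, tolerance = 1e-13)
  expect_false(identical(model_rhs(h, 0.79, p),
                         reaction(v, p$phi_bar) / p$epsilon^2))
})

test_that("uniform fixed points 0, phi_bar, 1 are bit-stable under RK4", {
  p <- model_parameters(c = 0.02)
  for (val in c(0, p$phi_bar, 1)) {
    f <- uniform_field(val, N = 8)
    g <- f
    for (k in 1:100) g <- rk4_step(g, (k - 1) * 1e-3, 1e-3, p)
    expect_identical(g$values, f$values)
  }
})

test_that("grid RK4 on a uniform field equals the scalar RK4 oracle", {
  p <- model_parameters()
  f <- uniform_field(0.6, N = 8)
  g <- rk4_step(f, 0, 1e-3, p)
  expect_equal(g$values,
               matrix(scalar_rk4(0.6, 0.5, 0.1, 1e-3, 1), 8, 8),
               tolerance = 1e-15)
  # several steps, general threshold
  q <- model_parameters(phi_bar = 0.45)
  u <- uniform_field(0.52, N = 8)
  for (k in 1:20) u <- rk4_step(u, (k - 1) * 1e-3, 1e-3, q)
  expect_equal(u$values[1, 1], scalar_rk4(0.52, 0.45, 0.1, 1e-3, 20),
               tolerance = 1e-15)
})

test_that("RK4 commutes with left-right reflection", {
  set.seed(42)
  N <- 16
  v <- matrix(runif(N * N, 0.4, 0.6), N, N)
  v <- (v + v[, N:1]) / 2  # symmetric under column reflection
  p <- model_parameters()
  f <- order_parameter_field(v)
  g <- rk4_step(f, 0, 1e-3, p)
  expect_identical(g$values, g$values[, N:1])
})

test_that("a step straddling the switch time is refused", {
  p <- model_parameters(T = 0.8)
  f <- uniform_field(0.6, N = 8)
  expect_error(rk4_step(f, 0.79, 0.02, p), "straddles")
  # landing exactly on T is fine
  expect_silent(rk4_step(f, 0.79, 0.01, p))
  expect_silent(rk4_step(f, 0.8, 0.01, p))
})

test_that("integration of a stationary uniform state stays put", {
  p <- model_parameters(c = 0.02)
  f <- uniform_field(p$phi_bar, N = 8)
  cfg <- numerics_config(N = 8, t_end = 1)
  out <- integrate_model(f, p, cfg)
  for (fl in out$fields) expect_identical(fl$values, f$values)
})

test_that("uniform trajectories match the logistic closed form to 1e-8", {
  p <- model_parameters()  # phi_bar = 0.5, eps = 0.1
  cfg <- numerics_config(N = 8, t_end = 1)  # dt = 0.1/64
  for (phi0 in c(0.6, 0.45)) {
    out <- integrate_model(uniform_field(phi0, N = 8), p, cfg)
    for (i in seq_along(out$times)) {
      u <- out$fields[[i]]$values
      expect_lt(diff(range(u)), 1e-14)  # stays uniform
      expect_lt(abs(u[1, 1] -
                      closed_form_uniform(out$times[i], phi0, 0.1)), 1e-8)
    }
  }
})

test_that("uniform trajectories match an adaptive ODE oracle off 0.5", {
  # general phi_bar: no closed form; deSolve lsoda at 1e-12 as oracle
  p <- model_parameters(phi_bar = 0.45)
  cfg <- numerics_config(N = 8, t_end = 1)
  out <- integrate_model(uniform_field(0.52, N = 8), p, cfg)
  oracle <- deSolve::ode(
    y = 0.52, times = out$times,
    func = function(t, y, parms) list(100 * y * (1 - y) * (y - 0.45)),
    parms = NULL, atol = 1e-12, rtol = 1e-12)
  for (i in seq_along(out$times)) {
    expect_lt(abs(out$fields[[i]]$values[1, 1] -
                  as.numeric(oracle[i, 2])), 1e-8)
  }
})

test_that("snapshots are recorded exactly at the requested times", {
  p <- model_parameters()
  cfg <- numerics_config(N = 8, dt = 3e-4, t_end = 0.5,
                         snapshot_times = c(0.1, 0.25, 0.5))
  out <- integrate_model(uniform_field(0.55, N = 8), p, cfg)
  expect_identical(out$times, c(0, 0.1, 0.25, 0.5))
  expect_identical(out$fields[[1]]$values, matrix(0.55, 8, 8))
  # dt = 3e-4 does not divide 0.1: landing must still be exact
  expect_equal(out$fields[[2]]$t, 0.1)
})

test_that("divergence aborts with a diagnostic instead of clamping", {
  p <- model_parameters(epsilon = 0.01)
  cfg <- numerics_config(N = 8, dt = 10, t_end = 50, snapshot_times = 50)
  expect_error(integrate_model(uniform_field(0.6, N = 8), p, cfg),
               "diverged")
})

test_that("stability-checked policy rejects an oversized step", {
  p <- model_parameters()
  cfg <- numerics_config(N = 32, dt = 0.01, t_end = 1,
                         dt_policy = "stability-checked")
  expect_error(integrate_model(uniform_field(0.5, N = 32), p, cfg),
               "stability bound")
  expect_equal(stability_dt_bound(p, 32), 1e-3)  # 0.1 * eps^2 binds
})

test_that("discrete energy matches hand values on uniform states", {
  p <- model_parameters()
  expect_identical(discrete_energy(uniform_field(0, N = 16), 0, p), 0)
  expect_equal(discrete_energy(uniform_field(1, N = 16), 0, p), 0)
  # W(0.5) = 1/64, area 4, eps^-2 = 100 -> 6.25
  expect_equal(discrete_energy(uniform_field(0.5, N = 16), 0, p), 6.25)
})

test_that("energy is non-increasing along constant-D trajectory segments", {
  p <- model_parameters()
  N <- 32
  dt <- 1e-3
  f <- noisy_uniform_field(noise_spec(seed = 4), N = N)
  # pre-switch segment (D = D0)
  e_prev <- discrete_energy(f, 0, p)
  g <- f
  for (k in 1:150) {
    g <- rk4_step(g, (k - 1) * dt, dt, p)
    e <- discrete_energy(g, k * dt, p)
    expect_lte(e, e_prev + 1e-10)
    e_prev <- e
  }
  # post-switch segment (D = 0): pointwise flow also dissipates
  t0 <- 0.85
  e_prev <- discrete_energy(g, t0, p)
  for (k in 1:50) {
    g <- rk4_step(g, t0 + (k - 1) * dt, dt, p)
    e <- discrete_energy(g, t0 + k * dt, p)
    expect_lte(e, e_prev + 1e-10)
    e_prev <- e
  }
})

test_that("snapshot values stay within [0,1] for interior initial data", {
  p <- model_parameters()
  N <- 32
  set.seed(10)
  v <- matrix(runif(N * N, 0.25, 0.75), N, N)
  cfg <- numerics_config(N = N, dt = 1e-3, t_end = 1,
                         dt_policy = "stability-checked")
  out <- integrate_model(order_parameter_field(v), p, cfg)
  for (fl in out$fields) {
    expect_true(all(fl$values >= -1e-6 & fl$values <= 1 + 1e-6))
  }
})

test_that("after switch-off every cell flows monotonically to its well", {
  p <- model_parameters()
  N <- 24
  f <- noisy_uniform_field(noise_spec(seed = 21, amplitude_fraction = 0.3),
                           N = N)
  cfg <- numerics_config(N = N, dt = 5e-4, t_end = 1,
                         snapshot_times = c(0.8, 0.85, 0.9, 0.95, 1.0))
  out <- integrate_model(f, p, cfg)
  at_T <- snapshot_field(out, 0.8)$values
  up <- at_T > p$phi_bar
  dn <- at_T < p$phi_bar
  prev <- at_T
  for (tt in c(0.85, 0.9, 0.95, 1.0)) {
    cur <- snapshot_field(out, tt)$values
    expect_true(all(cur[up] >= prev[up] - 1e-12))
    expect_true(all(cur[dn] <= prev[dn] + 1e-12))
    prev <- cur
  }
})
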