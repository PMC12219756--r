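#' Numerical configuration of a simulation run
#'
#' @param N Grid cells per side (default 200, the reference resolution).
#' @param dt Time increment; defaults to `0.1 / N^2`, the very
#'   conservative reference choice.
#' @param t_end Final time of the integration (default 1).
#' @param snapshot_times Times at which the field is recorded; must lie in
#'   `(0, t_end]`, sorted and unique. Default `0.2, 0.4, 0.6, 0.8, 1.0`.
#' @param dt_policy `"fixed"` accepts `dt` as given; `"stability-checked"`
#'   additionally requires `dt <= min(h^2 / (4 D0), 0.1 epsilon^2)` and is
#'   intended for faster exploratory runs with larger steps.
#' @return An object of class `cpc_numerics`.
#' @export
numerics_config <- function(N = 200, dt = NULL, t_end = 1,
                            snapshot_times = c(0.2, 0.4, 0.6, 0.8, 1.0),
                            dt_policy = c("fixed", "stability-checked")) {
  N <- as.integer(N)
  if (is.na(N) || N < 3L) stop("`N` must be an integer >= 3", call. = FALSE)
  if (is.null(dt)) dt <- 0.1 / N^2
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0) {
    stop("`t_end` must be a single positive number", call. = FALSE)
  }
  snapshot_times <- as.numeric(snapshot_times)
  if (length(snapshot_times) == 0L) {
    stop("`snapshot_times` must contain at least one time", call. = FALSE)
  }
  if (is.unsorted(snapshot_times, strictly = TRUE)) {
    stop("`snapshot_times` must be strictly increasing", call. = FALSE)
  }
  if (any(snapshot_times <= 0) || any(snapshot_times > t_end + 1e-12)) {
    stop("`snapshot_times` must lie in (0, t_end]", call. = FALSE)
  }
  dt_policy <- match.arg(dt_policy)
  structure(
    list(N = N, dt = dt, t_end = t_end, snapshot_times = snapshot_times,
         dt_policy = dt_policy),
    class = "cpc_numerics"
  )
}

#' @export
print.cpc_numerics <- function(x, ...) {
  cat(sprintf("<cpc_numerics> N = %d, dt = %g (%s), t in [0, %g]\n",
              x$N, x$dt, x$dt_policy, x$t_end))
  cat("  snapshots at:", paste(x$snapshot_times, collapse = ", "), "\n")
  invisible(x)
}

#' Explicit stability bound on the time step
#'
#' `min(h^2 / (4 D0), 0.1 * epsilon^2)`: the diffusive CFL limit of the
#' 5-point stencil together with a tenth of the reaction time scale.
#'
#' @param params A [model_parameters()] object.
#' @param N Grid cells per side.
#' @param L Half-width of the domain.
#' @return The largest admissible `dt` under the stability-checked policy.
#' @export
stability_dt_bound <- function(params, N, L = 1) {
  stopifnot(inherits(params, "cpc_params"))
  h <- 2 * L / N
  min(h^2 / (4 * params$D0), 0.1 * params$epsilon^2)
}

#' 5-point Neumann Laplacian of a field
#'
#' Applies the stencil `(phi_E + phi_W + phi_N + phi_S - 4 phi_C) / h^2`
#' with boundary neighbours supplied by mirror reflection (the ghost cell
#' carries the interior neighbour's value), which realizes the
#' zero-normal-derivative boundary condition to second order on the
#' cell-centered grid.
#'
#' @param field A `cpc_field`.
#' @return Numeric matrix of the same shape.
#' @export
laplacian_neumann <- function(field) {
  stopifnot(inherits(field, "cpc_field"))
  laplacian_neumann_cpp(field$values, field$h)
}

#' Right-hand side of the semi-discrete model
#'
#' `D(t) * Lap(phi) + epsilon^-2 * f(phi)` evaluated elementwise on the
#' grid; after the switch-off time `T` the diffusion term is absent and
#' the dynamics decouple per cell.
#'
#' @param field A `cpc_field`.
#' @param t Evaluation time.
#' @param params A [model_parameters()] object.
#' @return Numeric matrix of time derivatives, same shape as the field.
#' @export
model_rhs <- function(field, t, params) {
  stopifnot(inherits(field, "cpc_field"), inherits(params, "cpc_params"))
  rhs_cpp(field$values, t, params$D0, params$T, params$epsilon,
          params$phi_bar, field$h)
}

#' One classical fourth-order Runge-Kutta step
#'
#' Advances the field from `t` to `t + dt` with stage evaluations of the
#' right-hand side at `t`, `t + dt/2`, `t + dt/2` and `t + dt`. A step
#' whose interior contains the diffusion switch-off time `T` is refused
#' (the stages would mix the two diffusion regimes with ambiguous order);
#' callers split such a step at `T`, as [integrate_model()] does
#' automatically. Uniform fields at the reaction roots 0, `phi_bar`, 1
#' are preserved exactly.
#'
#' @param field A `cpc_field` at time `t`.
#' @param t Current time.
#' @param dt Step size (> 0).
#' @param params A [model_parameters()] object.
#' @return A `cpc_field` at `t + dt`.
#' @export
rk4_step <- function(field, t, dt, params) {
  stopifnot(inherits(field, "cpc_field"), inherits(params, "cpc_params"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  values <- rk4_step_cpp(field$values, t, dt, params$D0, params$T,
                         params$epsilon, params$phi_bar, field$h)
  order_parameter_field(values, L = field$L, t = t + dt)
}

#' Integrate the setting model over time
#'
#' Method-of-lines integration from `t = 0` to `t_end` with fixed-step
#' classical RK4. Steps are aligned so that every snapshot time, the
#' switch-off time `T`, and `t_end` land exactly on step boundaries (the
#' step before each is shortened); the discontinuous diffusion
#' coefficient is therefore crossed without any RK4 stage straddling it
#' and without switching equations. The result is deterministic given
#' `(initial, params, config)`.
#'
#' @param initial A `cpc_field` at `t = 0` (e.g. from
#'   [noisy_uniform_field()]).
#' @param params A [model_parameters()] object.
#' @param config A [numerics_config()]; its `N` must match the initial
#'   field. Under the `"stability-checked"` policy `dt` must satisfy
#'   [stability_dt_bound()].
#' @return An object of class `cpc_snapshots`: a list with `times`
#'   (starting at 0), `fields` (list of `cpc_field`, first entry the
#'   initial condition), `params`, `config`, `seed` (the initial
#'   condition's seed, or `NA` for user-supplied fields) and `steps`
#'   taken.
#' @export
integrate_model <- function(initial, params, config) {
  stopifnot(inherits(initial, "cpc_field"), inherits(params, "cpc_params"),
            inherits(config, "cpc_numerics"))
  if (initial$N != config$N) {
    stop(sprintf("initial field has N = %d but the configuration has N = %d",
                 initial$N, config$N), call. = FALSE)
  }
  if (config$dt_policy == "stability-checked") {
    bound <- stability_dt_bound(params, config$N, initial$L)
    if (config$dt > bound) {
      stop(sprintf(paste0(
        "dt = %g exceeds the stability bound %g = min(h^2/(4 D0), ",
        "0.1 epsilon^2) under the stability-checked policy"),
        config$dt, bound), call. = FALSE)
    }
  }
  res <- integrate_cpp(initial$values, initial$h, params$D0, params$T,
                       params$epsilon, params$phi_bar, config$dt,
                       config$t_end, config$snapshot_times)
  fields <- vector("list", length(res$fields) + 1L)
  fields[[1L]] <- initial
  for (i in seq_along(res$fields)) {
    fields[[i + 1L]] <- order_parameter_field(res$fields[[i]],
                                              L = initial$L,
                                              t = res$times[i])
  }
  structure(
    list(times = c(0, as.numeric(res$times)), fields = fields,
         params = params, config = config,
         seed = if (is.null(initial$seed)) NA_integer_ else initial$seed,
         steps = res$steps),
    class = "cpc_snapshots"
  )
}

#' @export
print.cpc_snapshots <- function(x, ...) {
  cat(sprintf("<cpc_snapshots> %d snapshots, N = %d, %.0f RK4 steps\n",
              length(x$times), x$config$N, as.numeric(x$steps)))
  cat("  times:", paste(format(x$times), collapse = ", "), "\n")
  print(x$params)
  invisible(x)
}

#' Extract the snapshot at a given time
#'
#' @param series A `cpc_snapshots` object.
#' @param time One of the recorded times.
#' @return The `cpc_field` recorded at that time.
#' @export
snapshot_field <- function(series, time) {
  stopifnot(inherits(series, "cpc_snapshots"))
  i <- which(abs(series$times - time) <= 1e-9)
  if (length(i) != 1L) {
    stop(sprintf("no snapshot recorded at t = %g (available: %s)", time,
                 paste(format(series$times), collapse = ", ")),
         call. = FALSE)
  }
  series$fields[[i]]
}

#' Discrete Ginzburg-Landau energy of a field
#'
#' The Lyapunov functional of the gradient-flow structure:
#' `sum over cells of [ D(t)/2 |grad phi|^2 + epsilon^-2 W(phi) ] h^2`,
#' with the gradient term accumulated over nearest-neighbour edges
#' (one-sided differences consistent with the Neumann stencil; boundary
#' mirror edges contribute zero). On any interval where `D` is constant
#' the semi-discrete dynamics are the exact gradient flow of this energy,
#' so it is non-increasing along accurately integrated trajectories.
#'
#' @param field A `cpc_field`.
#' @param t Time at which `D(t)` is evaluated.
#' @param params A [model_parameters()] object.
#' @return A single nonnegative number (for fields in `[0, 1]`).
#' @export
discrete_energy <- function(field, t, params) {
  stopifnot(inherits(field, "cpc_field"), inherits(params, "cpc_params"))
  u <- field$values
  N <- field$N
  h <- field$h
  D <- diffusion_coefficient(t, params)
  grad2 <- 0
  if (D > 0) {
    dx <- (u[-1, , drop = FALSE] - u[-N, , drop = FALSE]) / h
    dy <- (u[, -1, drop = FALSE] - u[, -N, drop = FALSE]) / h
    grad2 <- sum(dx^2) + sum(dy^2)
  }
  wsum <- sum(potential(u, params$phi_bar))
  (D / 2 * grad2 + wsum / params$epsilon^2) * h^2
}
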