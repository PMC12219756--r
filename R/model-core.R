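#' Solid-formation threshold as a function of IP6 concentration
#'
#' The unstable middle root of the cubic reaction term, modelled as a
#' decreasing function of the IP6 (inositol phosphate) concentration:
#' more IP6 lowers the threshold, so more of the paste flows towards the
#' solid state.
#'
#' @param c IP6 concentration, a nonnegative numeric vector. The value is
#'   used on whatever scale the caller works in (ppm-scale as in cement
#'   experiments, or small model-scale values); it is fed to the formula
#'   `0.5 / (1 + c/1000)` unchanged.
#' @return Threshold value(s) in `(0, 0.5]`, strictly decreasing in `c`.
#' @examples
#' phi_bar(0)      # 0.5: water, no IP6
#' phi_bar(1000)   # 0.25
#' phi_bar(3000)   # 0.125
#' @export
phi_bar <- function(c) {
  if (!is.numeric(c) || anyNA(c)) {
    stop("`c` must be numeric with no missing values", call. = FALSE)
  }
  if (any(c < 0)) {
    stop("IP6 concentration `c` must be nonnegative", call. = FALSE)
  }
  0.5 / (1 + c / 1000)
}

#' Bistable reaction term of the setting model
#'
#' The cubic `f(phi) = phi (1 - phi) (phi - phi_bar)` with stable roots at
#' 0 (void) and 1 (solid) and the unstable threshold `phi_bar` between
#' them. Under the pointwise dynamics `d phi/dt = f(phi)`, states above the
#' threshold set (flow to 1) and states below it collapse into voids
#' (flow to 0).
#'
#' @param phi Order parameter value(s); may transiently lie outside
#'   `[0, 1]` during time integration.
#' @param phi_bar Threshold in `(0, 1)`.
#' @return `phi * (1 - phi) * (phi - phi_bar)`, recycled elementwise.
#' @export
reaction <- function(phi, phi_bar) {
  check_threshold(phi_bar)
  phi * (1 - phi) * (phi - phi_bar)
}

#' Double-well potential of the reaction term
#'
#' Antiderivative `W` with `W'(phi) = -f(phi)`:
#' `W(phi) = phi^4/4 - (1 + phi_bar) phi^3/3 + phi_bar phi^2/2`.
#' `W` has local minima at the pure phases 0 and 1 and a barrier at
#' `phi_bar`; it is the well term of the discrete Ginzburg-Landau energy
#' used to monitor dissipation (see [discrete_energy()]).
#'
#' @inheritParams reaction
#' @return Potential value(s), elementwise.
#' @export
potential <- function(phi, phi_bar) {
  check_threshold(phi_bar)
  phi^4 / 4 - (1 + phi_bar) * phi^3 / 3 + phi_bar * phi^2 / 2
}

#' Switch-off diffusion coefficient D(t)
#'
#' The model takes diffusion as the carrier of the setting process: the
#' coefficient equals `D0` while the initial setting is underway
#' (`0 <= t < T`) and drops to exactly 0 from the initial-setting
#' completion time `T` onwards (right-continuous step; no smoothing).
#'
#' @param t Time(s), nonnegative.
#' @param params A [model_parameters()] object (fields `D0` and `T` are
#'   used).
#' @return `D0` where `t < T`, `0` where `t >= T`.
#' @export
diffusion_coefficient <- function(t, params) {
  stopifnot(inherits(params, "cpc_params"))
  if (!is.numeric(t) || anyNA(t)) {
    stop("`t` must be numeric with no missing values", call. = FALSE)
  }
  if (any(t < 0)) {
    stop("time `t` must be nonnegative", call. = FALSE)
  }
  ifelse(t < params$T, params$D0, 0)
}

#' Bundle the model parameters of one simulation run
#'
#' @param D0 Diffusion magnitude while setting is underway (> 0).
#' @param T Initial-setting completion time (> 0); diffusion switches off
#'   at `t = T`.
#' @param epsilon Phase-separation strength (> 0); the reaction term is
#'   scaled by `epsilon^-2`.
#' @param c IP6 concentration (>= 0), used to derive the solid-formation
#'   threshold via [phi_bar()] unless `phi_bar` is given explicitly.
#' @param phi_bar Optional explicit threshold in `(0, 1)`, overriding the
#'   value derived from `c`.
#' @return An object of class `cpc_params` with fields `D0`, `T`,
#'   `epsilon`, `c`, `phi_bar` and `phi_bar_source`
#'   (`"formula"` or `"override"`).
#' @examples
#' model_parameters()                 # the default water-case run
#' model_parameters(c = 3000)         # threshold from the formula
#' model_parameters(phi_bar = 0.49)   # explicit override
#' @export
model_parameters <- function(D0 = 0.01, T = 0.8, epsilon = 0.1, c = 0,
                             phi_bar = NULL) {
  for (nm in c("D0", "T", "epsilon")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive number", nm),
           call. = FALSE)
    }
  }
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c < 0) {
    stop("`c` must be a single nonnegative number", call. = FALSE)
  }
  if (is.null(phi_bar)) {
    pb <- phi_bar(c)
    src <- "formula"
  } else {
    pb <- phi_bar
    check_threshold(pb)
    src <- "override"
  }
  structure(
    list(D0 = D0, T = T, epsilon = epsilon, c = c,
         phi_bar = pb, phi_bar_source = src),
    class = "cpc_params"
  )
}

#' @export
print.cpc_params <- function(x, ...) {
  cat("<cpc_params>\n")
  cat(sprintf("  D0 = %g, T = %g, epsilon = %g\n", x$D0, x$T, x$epsilon))
  cat(sprintf("  c = %g, phi_bar = %.6g (%s)\n", x$c, x$phi_bar,
              x$phi_bar_source))
  invisible(x)
}

#' Nondimensionalizing scale transform of the model parameters
#'
#' The model assumes the initial-setting time scales with the square of
#' the phase-separation strength, `T(c) ~ epsilon(c)^2`. Under that
#' assumption, rescaling time by `lambda = epsilon^2 / epsilon0^2 =
#' T / tau0` and space by `sqrt(mu)` with `mu = (D0/d0) * lambda` maps the
#' run onto reference parameters `(d0, tau0, epsilon0)` while leaving the
#' equation's form unchanged; only the threshold `phi_bar(c)` retains the
#' IP6 dependence.
#'
#' The two expressions for `lambda` must agree: a mismatch means the
#' parameter quadruple violates the proportionality assumption and is
#' reported as an error, never silently adjusted.
#'
#' @param params A [model_parameters()] object supplying `D0`, `T`,
#'   `epsilon`.
#' @param epsilon0,tau0,d0 Reference phase-separation strength, setting
#'   time and diffusion magnitude (> 0).
#' @param rtol Relative tolerance for the consistency check between
#'   `epsilon^2/epsilon0^2` and `T/tau0`.
#' @return An object of class `cpc_scale` with fields `epsilon0`, `tau0`,
#'   `d0`, `lambda`, `mu`. Map dimensionless coordinates back with
#'   [map_time()] / [map_space()], and obtain the reference-parameter set
#'   with [transformed_parameters()].
#' @examples
#' p <- model_parameters(D0 = 0.01, T = 0.8, epsilon = 0.2)
#' scale_parameters(p, epsilon0 = 0.1, tau0 = 0.2, d0 = 0.01)
#' @export
scale_parameters <- function(params, epsilon0, tau0, d0, rtol = 1e-12) {
  stopifnot(inherits(params, "cpc_params"))
  for (nm in c("epsilon0", "tau0", "d0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive number", nm),
           call. = FALSE)
    }
  }
  lambda_eps <- params$epsilon^2 / epsilon0^2
  lambda_T <- params$T / tau0
  if (abs(lambda_eps - lambda_T) > rtol * max(abs(lambda_eps), abs(lambda_T))) {
    stop(sprintf(paste0(
      "inconsistent scaling: epsilon^2/epsilon0^2 = %.15g but T/tau0 = ",
      "%.15g; the proportionality T ~ epsilon^2 does not hold for these ",
      "references"), lambda_eps, lambda_T), call. = FALSE)
  }
  lambda <- lambda_eps
  mu <- (params$D0 / d0) * lambda
  structure(
    list(epsilon0 = epsilon0, tau0 = tau0, d0 = d0,
         lambda = lambda, mu = mu),
    class = "cpc_scale"
  )
}

#' @export
print.cpc_scale <- function(x, ...) {
  cat("<cpc_scale>\n")
  cat(sprintf("  references: epsilon0 = %g, tau0 = %g, d0 = %g\n",
              x$epsilon0, x$tau0, x$d0))
  cat(sprintf("  lambda = %g (t = lambda * tau), mu = %g (x = sqrt(mu) * xi)\n",
              x$lambda, x$mu))
  invisible(x)
}

#' Coordinate maps of a scale transform
#'
#' `map_time()` converts dimensionless time `tau` to physical time
#' `t = lambda * tau`; `map_space()` converts a dimensionless coordinate
#' `xi` to `x = sqrt(mu) * xi`. Set `inverse = TRUE` for the opposite
#' direction.
#'
#' @param transform A `cpc_scale` object from [scale_parameters()].
#' @param tau,xi Coordinate value(s) to map.
#' @param inverse Map from physical to dimensionless instead.
#' @return Mapped coordinate value(s).
#' @export
map_time <- function(transform, tau, inverse = FALSE) {
  stopifnot(inherits(transform, "cpc_scale"))
  if (inverse) tau / transform$lambda else transform$lambda * tau
}

#' @rdname map_time
#' @export
map_space <- function(transform, xi, inverse = FALSE) {
  stopifnot(inherits(transform, "cpc_scale"))
  if (inverse) xi / sqrt(transform$mu) else sqrt(transform$mu) * xi
}

#' Reference-parameter set realized by a scale transform
#'
#' Returns the [model_parameters()] object of the transformed
#' (dimensionless) run: diffusion `d0`, setting time `tau0`,
#' phase-separation strength `epsilon0`, with the threshold carried over
#' unchanged (only `phi_bar` keeps the IP6 dependence under the
#' transform).
#'
#' @inheritParams map_time
#' @param params The original [model_parameters()] object.
#' @return A `cpc_params` object with the reference values.
#' @export
transformed_parameters <- function(transform, params) {
  stopifnot(inherits(transform, "cpc_scale"), inherits(params, "cpc_params"))
  model_parameters(D0 = transform$d0, T = transform$tau0,
                   epsilon = transform$epsilon0, c = params$c,
                   phi_bar = params$phi_bar)
}

#' Invert a scale transform
#'
#' Recovers the original `(D0, T, epsilon)` from the reference values and
#' the scale factors: `D0 = d0 * mu / lambda`, `T = lambda * tau0`,
#' `epsilon = epsilon0 * sqrt(lambda)`.
#'
#' @inheritParams map_time
#' @param c,phi_bar Passed through to [model_parameters()].
#' @return A `cpc_params` object with the original values.
#' @export
original_parameters <- function(transform, c = 0, phi_bar = NULL) {
  stopifnot(inherits(transform, "cpc_scale"))
  model_parameters(D0 = transform$d0 * transform$mu / transform$lambda,
                   T = transform$lambda * transform$tau0,
                   epsilon = transform$epsilon0 * sqrt(transform$lambda),
                   c = c, phi_bar = phi_bar)
}

check_threshold <- function(phi_bar) {
  if (!is.numeric(phi_bar) || length(phi_bar) != 1L || !is.finite(phi_bar) ||
      phi_bar <= 0 || phi_bar >= 1) {
    stop("`phi_bar` must be a single number strictly between 0 and 1",
         call. = FALSE)
  }
  invisible(phi_bar)
}
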