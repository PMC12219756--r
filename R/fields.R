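#' Discrete order-parameter field on the square domain
#'
#' The state of the paste is an order parameter `phi` on the cell-centered
#' `N x N` grid covering `Omega = [-L, L]^2`: `phi = 1` is set cement
#' (solid), `phi = 0` a void, `phi = 0.5` liquid paste, and intermediate
#' values incomplete setting. Cell centers sit at `-L + h/2 + i*h` with
#' spacing `h = 2L/N`.
#'
#' @param values Square numeric matrix of order-parameter values (row `i`,
#'   column `j` is the cell at `x_i`, `y_j`).
#' @param L Half-width of the domain (> 0).
#' @param t Time stamp of the field.
#' @return An object of class `cpc_field`: a list with `values`, `N`, `L`,
#'   `h`, `t`.
#' @export
order_parameter_field <- function(values, L = 1, t = 0) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) != ncol(values) || nrow(values) < 3L) {
    stop("`values` must be a square matrix with N >= 3", call. = FALSE)
  }
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0) {
    stop("`L` must be a single positive number", call. = FALSE)
  }
  N <- nrow(values)
  structure(
    list(values = values, N = N, L = L, h = 2 * L / N, t = t),
    class = "cpc_field"
  )
}

#' @export
print.cpc_field <- function(x, ...) {
  cat(sprintf(
    "<cpc_field> %d x %d on [-%g, %g]^2 (h = %g), t = %g, range [%.4g, %.4g]\n",
    x$N, x$N, x$L, x$L, x$h, x$t, min(x$values), max(x$values)))
  invisible(x)
}

#' Grid cell-center coordinates of a field
#'
#' @param field A `cpc_field`.
#' @return Numeric vector of the `N` cell-center coordinates along one
#'   axis (the grid is the tensor product of this vector with itself).
#' @export
cell_centers <- function(field) {
  stopifnot(inherits(field, "cpc_field"))
  -field$L + field$h / 2 + field$h * (seq_len(field$N) - 1)
}

#' Diagnostic range check of a field
#'
#' Physically meaningful states take values in `[0, 1]`; the integrator
#' may transiently leave the interval by round-off. This reports whether
#' all values lie in `[-tol, 1 + tol]` (no clamping is ever applied).
#'
#' @param field A `cpc_field`.
#' @param tol Tolerance beyond `[0, 1]` still considered physical.
#' @return `TRUE`/`FALSE`.
#' @export
field_in_range <- function(field, tol = 1e-6) {
  stopifnot(inherits(field, "cpc_field"))
  all(field$values >= -tol & field$values <= 1 + tol)
}

#' Noise specification for the initial order-parameter field
#'
#' The reference initial condition is a liquid at `phi0 = 0.5` perturbed
#' by small-amplitude spatial noise: each cell receives an independent
#' uniform draw on `[-a, a]` with `a = amplitude_fraction * h`. The
#' default 5%-of-`h` amplitude gives `a = 5e-4` on the 200-cell unit
#' domain.
#'
#' @param base_value Unperturbed order-parameter value `phi0`.
#' @param amplitude_fraction Noise half-width as a fraction of the grid
#'   spacing `h` (>= 0).
#' @param seed Integer RNG seed; identical seeds give identical fields.
#' @return An object of class `cpc_noise_spec`.
#' @export
noise_spec <- function(base_value = 0.5, amplitude_fraction = 0.05,
                       seed = 1L) {
  if (!is.numeric(base_value) || length(base_value) != 1L ||
      base_value <= 0 || base_value >= 1) {
    stop("`base_value` must be a single number in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(amplitude_fraction) || length(amplitude_fraction) != 1L ||
      amplitude_fraction < 0) {
    stop("`amplitude_fraction` must be a single nonnegative number",
         call. = FALSE)
  }
  seed <- as.integer(seed)
  if (length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  structure(
    list(base_value = base_value, amplitude_fraction = amplitude_fraction,
         seed = seed, distribution = "uniform-symmetric"),
    class = "cpc_noise_spec"
  )
}

#' Noisy uniform initial field
#'
#' Builds the reference initial condition: constant `base_value` plus
#' independent symmetric uniform noise of half-width
#' `amplitude_fraction * h` per cell. Cells are filled in row-major order
#' from a single seeded stream, so a given `(seed, N, L, spec)` always
#' reproduces the same field; the caller's RNG state is left untouched.
#'
#' @param spec A [noise_spec()].
#' @param N Grid cells per side.
#' @param L Half-width of the domain.
#' @return A `cpc_field` at `t = 0`.
#' @export
noisy_uniform_field <- function(spec, N = 200, L = 1) {
  stopifnot(inherits(spec, "cpc_noise_spec"))
  N <- as.integer(N)
  if (N < 3L) stop("`N` must be at least 3", call. = FALSE)
  h <- 2 * L / N
  a <- spec$amplitude_fraction * h
  if (spec$base_value - a <= 0 || spec$base_value + a >= 1) {
    stop(sprintf(paste0(
      "noise amplitude %g pushes initial values outside (0, 1); reduce ",
      "`amplitude_fraction` or move `base_value` away from the ends"), a),
      call. = FALSE)
  }
  u <- with_local_seed(spec$seed, {
    if (a > 0) runif(N * N, min = -a, max = a) else numeric(N * N)
  })
  values <- matrix(spec$base_value + u, nrow = N, ncol = N, byrow = TRUE)
  field <- order_parameter_field(values, L = L, t = 0)
  field$seed <- spec$seed
  field
}

#' Initial field with setting started at the boundary
#'
#' Optional alternative initial condition emulating setting that begins
#' near the domain boundary while the interior is still liquid-like: all
#' cells whose center lies within `rim_width` of the boundary of
#' `[-L, L]^2` are set to `rim_value`; interior cells follow
#' [noisy_uniform_field()].
#'
#' @inheritParams noisy_uniform_field
#' @param rim_width Width of the boundary rim, `0 < rim_width < L`.
#' @param rim_value Order-parameter value in the rim, in `(0, 1]`.
#' @return A `cpc_field` at `t = 0`.
#' @export
boundary_set_field <- function(spec, N = 200, L = 1, rim_width = 0.1,
                               rim_value = 1) {
  if (!is.numeric(rim_width) || length(rim_width) != 1L ||
      rim_width <= 0 || rim_width >= L) {
    stop("`rim_width` must satisfy 0 < rim_width < L", call. = FALSE)
  }
  if (!is.numeric(rim_value) || length(rim_value) != 1L ||
      rim_value <= 0 || rim_value > 1) {
    stop("`rim_value` must lie in (0, 1]", call. = FALSE)
  }
  field <- noisy_uniform_field(spec, N = N, L = L)
  x <- cell_centers(field)
  rim <- (L - abs(x)) < rim_width
  values <- field$values
  values[rim, ] <- rim_value
  values[, rim] <- rim_value
  out <- order_parameter_field(values, L = L, t = 0)
  out$seed <- spec$seed
  out
}

#' Read an initial field from delimited text
#'
#' Reads a whitespace- or comma-delimited `N x N` numeric grid (one grid
#' row per line, no header) as written by [write_field()].
#'
#' @param path Path to the text file.
#' @param L Half-width of the domain the grid covers.
#' @param t Time stamp to attach.
#' @param expect_N Optional grid size; a mismatch is an error.
#' @return A `cpc_field`.
#' @export
read_field <- function(path, L = 1, t = 0, expect_N = NULL) {
  values <- as.matrix(read.table(path, header = FALSE,
                                 sep = "", colClasses = "numeric"))
  dimnames(values) <- NULL
  if (!is.null(expect_N) && nrow(values) != expect_N) {
    stop(sprintf("field file has %d rows but the configuration expects N = %d",
                 nrow(values), expect_N), call. = FALSE)
  }
  order_parameter_field(values, L = L, t = t)
}

#' Write a field as delimited text
#'
#' @param field A `cpc_field`.
#' @param path Output path; one grid row per line, tab-separated, full
#'   double precision.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "cpc_field"))
  write.table(format(field$values, digits = 17, scientific = TRUE,
                     trim = TRUE),
              path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

# Run `expr` under a deterministic seed without disturbing the caller's
# RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
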