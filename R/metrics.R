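#' Classify grid cells as solid, void or intermediate
#'
#' In the snapshot colour convention, `phi = 1` (yellow) is set cement,
#' `phi = 0` (black) a void and intermediate values incomplete setting.
#' Since computed fields only approach the pure states, classification
#' uses bands: a cell is `void` when `phi <= theta_void`, `solid` when
#' `phi >= theta_solid`, otherwise `intermediate`.
#'
#' @param field A `cpc_field`.
#' @param thresholds Numeric vector `c(void, solid)` with
#'   `0 < void < solid < 1`; defaults `c(0.1, 0.9)`, symmetric about the
#'   liquid value 0.5.
#' @return An object of class `cpc_phase_map`: a list with a character
#'   matrix `labels` (values `"void"`, `"intermediate"`, `"solid"`),
#'   `thresholds`, `N` and the field's time stamp `t`.
#' @export
classify_phase <- function(field, thresholds = c(void = 0.1, solid = 0.9)) {
  stopifnot(inherits(field, "cpc_field"))
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != 2L || anyNA(thresholds) ||
      thresholds[1] <= 0 || thresholds[2] >= 1 ||
      thresholds[1] >= thresholds[2]) {
    stop("`thresholds` must be c(void, solid) with 0 < void < solid < 1",
         call. = FALSE)
  }
  u <- field$values
  labels <- matrix("intermediate", nrow = field$N, ncol = field$N)
  labels[u <= thresholds[1]] <- "void"
  labels[u >= thresholds[2]] <- "solid"
  structure(
    list(labels = labels, thresholds = c(void = thresholds[1],
                                         solid = thresholds[2]),
         N = field$N, t = field$t),
    class = "cpc_phase_map"
  )
}

#' @export
print.cpc_phase_map <- function(x, ...) {
  counts <- table(factor(x$labels, levels = c("void", "intermediate",
                                              "solid")))
  cat(sprintf("<cpc_phase_map> %d x %d at t = %g (void <= %g, solid >= %g)\n",
              x$N, x$N, x$t, x$thresholds["void"], x$thresholds["solid"]))
  cat(sprintf("  void %d | intermediate %d | solid %d\n",
              counts[["void"]], counts[["intermediate"]],
              counts[["solid"]]))
  invisible(x)
}

#' Fraction of the domain occupied by voids
#'
#' @param map A `cpc_phase_map`.
#' @return `(# void cells) / N^2`, in `[0, 1]`.
#' @export
void_area_fraction <- function(map) {
  stopifnot(inherits(map, "cpc_phase_map"))
  mean(map$labels == "void")
}

#' Count connected void regions
#'
#' Number of 4-connected components of void-labelled cells containing at
#' least `min_cells` cells. The size filter discards single-cell speckle
#' from noise, so a counted "void" is a spatially coherent region;
#' 4-connectivity is the conservative choice (diagonal contact does not
#' join regions).
#'
#' @param map A `cpc_phase_map`.
#' @param min_cells Minimum component size in cells (>= 1, default 4).
#' @return Nonnegative integer count.
#' @export
connected_void_components <- function(map, min_cells = 4) {
  stopifnot(inherits(map, "cpc_phase_map"))
  min_cells <- as.integer(min_cells)
  if (is.na(min_cells) || min_cells < 1L) {
    stop("`min_cells` must be an integer >= 1", call. = FALSE)
  }
  lab <- label_components_cpp(map$labels == "void")
  n <- attr(lab, "n_components")
  if (n == 0L) return(0L)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  sum(sizes >= min_cells)
}

#' Void onset, persistence and the fragmentation verdict of a run
#'
#' Scans the snapshots of one integration for coherent void regions and
#' reduces them to the run's outcome: `fragmentation` when a detected
#' void persists through the final snapshot, `non-fragmentation` when
#' voids appeared but had all vanished by the final snapshot, and
#' `indeterminate` when no void was ever detected.
#'
#' @param series A `cpc_snapshots` from [integrate_model()].
#' @param thresholds Phase-classification bands, see [classify_phase()].
#' @param min_cells Minimum void-component size, see
#'   [connected_void_components()].
#' @param include_initial Whether the `t = 0` entry participates in void
#'   detection (default `FALSE`: the initial noise is not a setting
#'   outcome).
#' @return An object of class `cpc_void_report`: a list with
#'   `per_snapshot` (data frame of `time`, `void_area_fraction`,
#'   `void_component_count`), `onset_time` (first snapshot with a
#'   counted void, or `NA`), `vanish_time` (first later snapshot with
#'   none, or `NA`), `verdict`, and the parameters used.
#' @export
void_timeline <- function(series, thresholds = c(void = 0.1, solid = 0.9),
                          min_cells = 4, include_initial = FALSE) {
  stopifnot(inherits(series, "cpc_snapshots"))
  idx <- seq_along(series$times)
  if (!include_initial && length(idx) > 1L) idx <- idx[-1L]
  times <- series$times[idx]
  frac <- numeric(length(idx))
  count <- integer(length(idx))
  for (k in seq_along(idx)) {
    map <- classify_phase(series$fields[[idx[k]]], thresholds)
    frac[k] <- void_area_fraction(map)
    count[k] <- connected_void_components(map, min_cells)
  }
  per_snapshot <- data.frame(time = times, void_area_fraction = frac,
                             void_component_count = count)
  onset_i <- which(count >= 1L)[1]
  onset_time <- if (is.na(onset_i)) NA_real_ else times[onset_i]
  vanish_time <- NA_real_
  if (!is.na(onset_i)) {
    later <- which(count == 0L & seq_along(count) > onset_i)[1]
    if (!is.na(later)) vanish_time <- times[later]
  }
  verdict <- if (is.na(onset_time)) {
    "indeterminate"
  } else if (count[length(count)] >= 1L) {
    "fragmentation"
  } else {
    "non-fragmentation"
  }
  structure(
    list(per_snapshot = per_snapshot, onset_time = onset_time,
         vanish_time = vanish_time, verdict = verdict,
         thresholds = thresholds, min_cells = min_cells),
    class = "cpc_void_report"
  )
}

#' @export
print.cpc_void_report <- function(x, ...) {
  cat("<cpc_void_report>\n")
  print(x$per_snapshot, row.names = FALSE)
  cat(sprintf("  onset: %s  vanish: %s  verdict: %s\n",
              format(x$onset_time), format(x$vanish_time), x$verdict))
  invisible(x)
}

#' Vicat needle penetration series
#'
#' @param time Measurement times (minutes), strictly increasing.
#' @param depth Penetration depths (mm), nonnegative.
#' @return An object of class `cpc_penetration`: a data frame with
#'   columns `time` and `depth`.
#' @export
penetration_series <- function(time, depth) {
  time <- as.numeric(time)
  depth <- as.numeric(depth)
  if (length(time) == 0L || length(time) != length(depth)) {
    stop("`time` and `depth` must be nonempty vectors of equal length",
         call. = FALSE)
  }
  if (anyNA(time) || anyNA(depth)) {
    stop("penetration data must not contain missing values", call. = FALSE)
  }
  if (is.unsorted(time, strictly = TRUE)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  if (any(depth < 0)) {
    stop("penetration depths must be nonnegative", call. = FALSE)
  }
  structure(data.frame(time = time, depth = depth),
            class = c("cpc_penetration", "data.frame"))
}

#' Read a penetration series from delimited text
#'
#' Expects a two-column table (time, depth) with a one-line header;
#' the delimiter is sniffed by [utils::read.table()] defaults unless
#' given.
#'
#' @param path Path to the text file.
#' @param sep Field separator (default: any whitespace).
#' @return A [penetration_series()].
#' @examples
#' path <- system.file("extdata", "vicat_synthetic.tsv", package = "cpcset")
#' estimate_setting_time(read_penetration_series(path))
#' @export
read_penetration_series <- function(path, sep = "") {
  tab <- read.table(path, header = TRUE, sep = sep)
  if (ncol(tab) < 2L) {
    stop("penetration file must have two columns: time and depth",
         call. = FALSE)
  }
  penetration_series(tab[[1]], tab[[2]])
}

#' Setting time from a Vicat penetration series
#'
#' The setting time is the earliest measurement at which the needle no
#' longer penetrates the paste, i.e. the first time with depth exactly
#' 0 mm (no interpolation, matching the operational definition of the
#' needle test).
#'
#' @param series A [penetration_series()].
#' @return The setting time, or `NA` (with a warning) when the paste
#'   never reached 0 mm within the observation window.
#' @export
estimate_setting_time <- function(series) {
  stopifnot(inherits(series, "cpc_penetration"))
  i <- which(series$depth == 0)[1]
  if (is.na(i)) {
    warning("paste did not set within the observation window ",
            "(no measurement reached 0 mm)", call. = FALSE)
    return(NA_real_)
  }
  series$time[i]
}

#' Wire a measured setting time into the simulation schedule
#'
#' Builds the [model_parameters()] whose diffusion coefficient runs at
#' `D0` until the supplied setting time `T` and is zero afterwards,
#' connecting a Vicat-style measurement to the switch-off schedule of the
#' model.
#'
#' @param T Setting time (> 0), e.g. from [estimate_setting_time()].
#' @param D0 Diffusion magnitude (> 0).
#' @param ... Further arguments passed to [model_parameters()]
#'   (`epsilon`, `c`, `phi_bar`).
#' @return A `cpc_params` object.
#' @export
build_setting_schedule <- function(T, D0, ...) {
  if (!is.numeric(T) || length(T) != 1L || is.na(T) || T <= 0) {
    stop("`T` must be a single positive setting time", call. = FALSE)
  }
  if (!is.numeric(D0) || length(D0) != 1L || is.na(D0) || D0 <= 0) {
    stop("`D0` must be a single positive diffusion magnitude",
         call. = FALSE)
  }
  model_parameters(D0 = D0, T = T, ...)
}
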