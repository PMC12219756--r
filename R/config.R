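#' Default run configuration
#'
#' The defaults reproduce the reference simulation exactly: `T = 0.8`,
#' `epsilon = 0.1`, `L = 1`, `D0 = 0.01`, `N = 200`, `dt = 0.1/N^2`,
#' integration over `[0, 1]` with snapshots at `0.2, 0.4, 0.6, 0.8, 1.0`,
#' and an initial liquid at 0.5 with 5%-of-`h` uniform noise.
#'
#' @return An object of class `cpc_config`, a nested list with sections
#'   `model`, `numerics`, `initial`, `metrics` and `output`.
#' @export
default_config <- function() {
  validate_config(list())
}

# NB: YAML 1.1 reads a bare `N`/`y`/`no` key as a boolean, so the grid
# size key is spelled `n_cells` in configurations.
config_schema <- list(
  model = list(D0 = 0.01, T = 0.8, epsilon = 0.1, c = 0, phi_bar = NULL,
               L = 1),
  numerics = list(n_cells = 200L, dt = NULL, t_end = 1,
                  snapshot_times = c(0.2, 0.4, 0.6, 0.8, 1.0),
                  dt_policy = "fixed"),
  initial = list(base_value = 0.5, amplitude_fraction = 0.05, seed = 1L,
                 field_path = NULL),
  metrics = list(theta_void = 0.1, theta_solid = 0.9, min_cells = 4L),
  output = list(formats = c("tsv", "png", "json"), png_scale = 1L)
)

#' Validate a run configuration given as a list
#'
#' Applies the reference defaults to every unset key, normalizes types,
#' rejects unknown sections or keys, and cross-checks the model/numerics
#' combination (threshold bands ordered, stability bound under the
#' stability-checked policy).
#'
#' @param user A possibly empty nested list with any of the sections
#'   `model`, `numerics`, `initial`, `metrics`, `output`.
#' @return A validated `cpc_config`.
#' @export
validate_config <- function(user) {
  if (!is.list(user)) {
    stop("configuration must be a (possibly empty) list of sections",
         call. = FALSE)
  }
  bad <- setdiff(names(user), names(config_schema))
  if (length(bad) > 0) {
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg <- config_schema
  for (sec in names(user)) {
    if (!is.list(user[[sec]])) {
      stop(sprintf("configuration section `%s` must be a list", sec),
           call. = FALSE)
    }
    badkey <- setdiff(names(user[[sec]]), names(config_schema[[sec]]))
    if (length(badkey) > 0) {
      stop(sprintf("unknown key(s) in section `%s`: %s", sec,
                   paste(badkey, collapse = ", ")), call. = FALSE)
    }
    # keep explicit NULLs (modifyList would drop the slot and expose
    # partial-matching surprises such as $dt finding dt_policy)
    for (k in names(user[[sec]])) {
      cfg[[sec]][k] <- user[[sec]][k]
    }
  }
  # normalize types so identical configs compare identical
  cfg$numerics$n_cells <- as.integer(cfg$numerics$n_cells)
  cfg$numerics$snapshot_times <- as.numeric(cfg$numerics$snapshot_times)
  cfg$initial$seed <- as.integer(cfg$initial$seed)
  cfg$metrics$min_cells <- as.integer(cfg$metrics$min_cells)
  cfg$output$png_scale <- as.integer(cfg$output$png_scale)
  cfg$output$formats <- as.character(cfg$output$formats)
  if (!is.null(cfg$numerics$dt)) cfg$numerics$dt <- as.numeric(cfg$numerics$dt)
  for (nm in c("D0", "T", "epsilon", "c", "L")) {
    cfg$model[[nm]] <- as.numeric(cfg$model[[nm]])
  }
  if (!is.null(cfg$model$phi_bar)) {
    cfg$model$phi_bar <- as.numeric(cfg$model$phi_bar)
  }
  # construct the component objects once; their validators report errors
  params <- config_params(cfg)
  numerics <- config_numerics(cfg)
  if (numerics$dt_policy == "stability-checked") {
    bound <- stability_dt_bound(params, numerics$N, cfg$model$L)
    # (numerics$N is the cpc_numerics field; the config key is n_cells)
    if (numerics$dt > bound) {
      stop(sprintf(paste0(
        "numerics.dt = %g exceeds the stability bound %g under the ",
        "stability-checked policy"), numerics$dt, bound), call. = FALSE)
    }
  }
  if (is.null(cfg$initial$field_path)) {
    noise_spec(cfg$initial$base_value, cfg$initial$amplitude_fraction,
               cfg$initial$seed)
  }
  if (cfg$metrics$theta_void <= 0 || cfg$metrics$theta_solid >= 1 ||
      cfg$metrics$theta_void >= cfg$metrics$theta_solid) {
    stop("metrics thresholds must satisfy 0 < theta_void < theta_solid < 1",
         call. = FALSE)
  }
  structure(cfg, class = "cpc_config")
}

#' Model parameters and numerics of a configuration
#'
#' `config_params()` builds the [model_parameters()] object a
#' configuration describes (applying the threshold formula or override);
#' `config_numerics()` builds the corresponding [numerics_config()] with
#' `dt` resolved to `0.1/N^2` when unset.
#'
#' @param cfg A `cpc_config`.
#' @return A `cpc_params` / `cpc_numerics` object respectively.
#' @export
config_params <- function(cfg) {
  model_parameters(D0 = cfg$model$D0, T = cfg$model$T,
                   epsilon = cfg$model$epsilon, c = cfg$model$c,
                   phi_bar = cfg$model$phi_bar)
}

#' @rdname config_params
#' @export
config_numerics <- function(cfg) {
  numerics_config(N = cfg$numerics$n_cells, dt = cfg$numerics$dt,
                  t_end = cfg$numerics$t_end,
                  snapshot_times = cfg$numerics$snapshot_times,
                  dt_policy = cfg$numerics$dt_policy)
}

#' Load a run configuration from a YAML file
#'
#' Reads a (possibly empty) YAML file, applies the reference defaults of
#' [default_config()] to every unset key, validates the result and
#' rejects unknown keys with their paths. An empty file therefore yields
#' exactly the reference run.
#'
#' @param path Path to the YAML configuration file.
#' @return A validated `cpc_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("configuration file `%s` does not exist", path),
         call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  # yaml reads vectors of length one as scalars and lists; flatten
  user <- lapply(user, function(sec) {
    if (is.list(sec)) {
      lapply(sec, function(v) if (is.list(v)) unlist(v) else v)
    } else {
      sec
    }
  })
  validate_config(user)
}

#' Save a run configuration to a YAML file
#'
#' Writes every key explicitly so that [load_config()] round-trips the
#' configuration losslessly.
#'
#' @param config A `cpc_config`.
#' @param path Output path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "cpc_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @export
print.cpc_config <- function(x, ...) {
  cat("<cpc_config>\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Render a snapshot with the solid/liquid/void colormap
#'
#' Writes a PNG using the fixed piecewise-linear colormap of the
#' snapshot figures: `phi = 0` black (void), `phi = 0.5` white (liquid),
#' `phi = 1` yellow (solid), interpolated linearly on each half. Values
#' are clipped to `[0, 1]` for display only. One pixel per grid cell,
#' optionally upscaled by an integer factor; the first grid axis runs
#' left to right and the second bottom to top.
#'
#' @param field A `cpc_field`.
#' @param path Output PNG path.
#' @param scale Integer upscaling factor (>= 1).
#' @return The colour array, invisibly.
#' @export
render_snapshot <- function(field, path, scale = 1L) {
  stopifnot(inherits(field, "cpc_field"))
  scale <- as.integer(scale)
  if (is.na(scale) || scale < 1L) {
    stop("`scale` must be an integer >= 1", call. = FALSE)
  }
  rgb <- snapshot_colors(field$values)
  if (scale > 1L) {
    idx <- rep(seq_len(dim(rgb)[1]), each = scale)
    rgb <- rgb[idx, rep(seq_len(dim(rgb)[2]), each = scale), , drop = FALSE]
  }
  png::writePNG(rgb, target = path)
  invisible(rgb)
}

# Map order-parameter values to the black/white/yellow colormap.
# Returns an [rows, cols, 3] array oriented for png::writePNG
# (first grid axis horizontal, second vertical upward).
snapshot_colors <- function(values) {
  v <- pmin(pmax(values, 0), 1)
  low <- v <= 0.5
  r <- ifelse(low, 2 * v, 1)
  g <- ifelse(low, 2 * v, 1)
  b <- ifelse(low, 2 * v, 2 - 2 * v)
  N1 <- nrow(v)
  N2 <- ncol(v)
  img <- array(0, dim = c(N2, N1, 3))
  flip <- function(m) t(m)[N2:1, , drop = FALSE]
  img[, , 1] <- flip(r)
  img[, , 2] <- flip(g)
  img[, , 3] <- flip(b)
  img
}

#' Run a configured simulation end to end
#'
#' Executes initial condition -> integration -> void metrics ->
#' rendering, and writes the run artifacts into `output_dir`: one
#' delimited-text grid per snapshot (`phi_t*.tsv`), one PNG per snapshot
#' (`phi_t*.png`), the void report (`void_report.json` and
#' `void_report.tsv`), a JSON run manifest (`manifest.json`, recording
#' parameters, seed, the `dt` actually used, the threshold provenance and
#' the package version) and a plain-text log.
#'
#' @param config A `cpc_config` from [load_config()] /
#'   [default_config()].
#' @param output_dir Directory for the artifacts (created if absent).
#'   `NULL` skips all file output.
#' @return Invisibly, a list with `series` (the `cpc_snapshots`),
#'   `report` (the `cpc_void_report`) and `manifest`.
#' @export
run_simulation <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "cpc_config"))
  t_start <- proc.time()[["elapsed"]]
  params <- config_params(config)
  numerics <- config_numerics(config)
  L <- config$model$L

  if (!is.null(config$initial$field_path)) {
    initial <- read_field(config$initial$field_path, L = L,
                          expect_N = numerics$N)
  } else {
    spec <- noise_spec(config$initial$base_value,
                       config$initial$amplitude_fraction,
                       config$initial$seed)
    initial <- noisy_uniform_field(spec, N = numerics$N, L = L)
  }

  series <- integrate_model(initial, params, numerics)
  thresholds <- c(void = config$metrics$theta_void,
                  solid = config$metrics$theta_solid)
  report <- void_timeline(series, thresholds, config$metrics$min_cells)
  energies <- vapply(seq_along(series$times), function(i) {
    discrete_energy(series$fields[[i]], series$times[i], params)
  }, numeric(1))

  manifest <- list(
    package = "cpcset",
    version = as.character(utils::packageVersion("cpcset")),
    model = list(D0 = params$D0, T = params$T, epsilon = params$epsilon,
                 c = params$c, phi_bar = params$phi_bar,
                 phi_bar_source = params$phi_bar_source, L = L),
    numerics = list(N = numerics$N, dt = numerics$dt,
                    t_end = numerics$t_end,
                    snapshot_times = numerics$snapshot_times,
                    dt_policy = numerics$dt_policy,
                    steps = as.numeric(series$steps)),
    initial = if (is.null(config$initial$field_path)) {
      list(kind = "noisy-uniform",
           base_value = config$initial$base_value,
           amplitude_fraction = config$initial$amplitude_fraction,
           noise_convention = "additive uniform on +/- fraction*h",
           seed = config$initial$seed)
    } else {
      list(kind = "file", path = config$initial$field_path)
    },
    metrics = list(theta_void = config$metrics$theta_void,
                   theta_solid = config$metrics$theta_solid,
                   min_cells = config$metrics$min_cells),
    colormap = list(void = c(0, 0, 0), liquid = c(1, 1, 1),
                    solid = c(1, 1, 0)),
    verdict = report$verdict
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    fmt <- config$output$formats
    for (i in seq_along(series$times)) {
      stem <- file.path(output_dir,
                        sprintf("phi_t%.3f", series$times[i]))
      if ("tsv" %in% fmt) write_field(series$fields[[i]],
                                      paste0(stem, ".tsv"))
      if ("png" %in% fmt) render_snapshot(series$fields[[i]],
                                          paste0(stem, ".png"),
                                          config$output$png_scale)
    }
    if ("json" %in% fmt) {
      jsonlite::write_json(report_to_list(report),
                           file.path(output_dir, "void_report.json"),
                           auto_unbox = TRUE, digits = NA)
      write.table(report$per_snapshot,
                  file.path(output_dir, "void_report.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      jsonlite::write_json(manifest,
                           file.path(output_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    elapsed <- proc.time()[["elapsed"]] - t_start
    log_lines <- c(
      sprintf("cpcset run: N=%d dt=%g t_end=%g seed=%s", numerics$N,
              numerics$dt, numerics$t_end, format(series$seed)),
      sprintf("phi_bar=%.8g (%s), c=%g", params$phi_bar,
              params$phi_bar_source, params$c),
      sprintf("steps=%.0f wall_s=%.2f verdict=%s",
              as.numeric(series$steps), elapsed, report$verdict),
      sprintf("t=%g energy=%.10g", series$times, energies)
    )
    writeLines(log_lines, file.path(output_dir, "run.log"))
  }

  invisible(list(series = series, report = report, manifest = manifest,
                 energies = energies))
}

report_to_list <- function(report) {
  list(
    per_snapshot = report$per_snapshot,
    onset_time = if (is.na(report$onset_time)) NULL else report$onset_time,
    vanish_time = if (is.na(report$vanish_time)) NULL else
      report$vanish_time,
    verdict = report$verdict,
    thresholds = as.list(report$thresholds),
    min_cells = report$min_cells
  )
}
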