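#' Default simulation configuration
#'
#' Builds the full configuration of a structural-plasticity simulation with
#' every parameter at its published default. Two scales are shipped:
#' \code{"full"} is the original 20 x 16 excitatory grid with 80 inhibitory
#' neurons, 8000 growth updates and 12000 post-lesion updates; \code{"mini"}
#' is a 10 x 8 grid with 20 inhibitory neurons, 2000 growth and 3000
#' post-lesion updates and a central 4 x 4 lesion projection zone, small
#' enough for routine testing while preserving the qualitative dynamics.
#'
#' @param scale either \code{"full"} or \code{"mini"}.
#' @param ... named overrides of the form \code{section.key = value},
#'   e.g. \code{growth.eta_A = 0.1} or \code{schedule.total_updates = 100}.
#' @return a validated object of class \code{msp_config}: a named list with
#'   sections \code{network}, \code{neuron}, \code{growth}, \code{schedule}.
#' @examples
#' cfg <- msp_config("mini", growth.kernel = "flat")
#' cfg$network$n_in
#' @export
msp_config <- function(scale = c("full", "mini"), ...) {
  scale <- match.arg(scale)
  cfg <- if (scale == "full") config_defaults_full() else config_defaults_mini()
  overrides <- list(...)
  for (nm in names(overrides)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L || is.null(cfg[[parts[1]]]))
      stop("unknown configuration key: ", nm, call. = FALSE)
    if (!parts[2] %in% names(cfg[[parts[1]]]))
      stop("unknown configuration key: ", nm, call. = FALSE)
    cfg[[parts[1]]][[parts[2]]] <- overrides[[nm]]
  }
  validate_config(cfg)
}

config_defaults_full <- function() {
  structure(list(
    network = list(
      grid_nx = 20L, grid_ny = 16L,    # excitatory lattice
      spacing = 150,                   # um between grid points
      n_in = 80L,
      jitter = 0.1                     # uniform jitter, fraction of spacing
    ),
    neuron = list(
      k1 = 0.04, k2 = 5, k3 = 140,     # mV^-1 ms^-1, ms^-1, mV ms^-1
      a = 0.1, b = 0.2, c = -65, d = 2,
      v_spike = 30,                    # mV threshold for the reset
      v0 = -65, u0 = -13,              # initial conditions (u0 = b * v0)
      syn_strength = 1,                # mV ms^-1 per synapse
      mu = 5,                          # ms, synaptic filter decay
      beta = 0.001,                    # ms^-1, calcium increment per spike
      tau_ca = 10000                   # ms, calcium decay
    ),
    growth = list(
      nu = 1e-4,                       # elements ms^-1
      eta_A = 0.4, eta_D = 0.1,        # minimum calcium for element formation
      eps_center = 0.7,                # homeostatic set-point
      eps_lo = 0.65, eps_hi = 0.75,    # homeostatic range (dz/dt = 0 inside)
      use_range = TRUE,
      tau_vac = 10,                    # connectivity updates
      kernel = "gaussian",
      sigma = 150                      # um, kernel width
    ),
    schedule = list(
      lesion_onset = 8000L,
      total_updates = 20000L,
      lpz_rect = c(750, 750, 1800, 1800),  # x1, y1, x2, y2 in um
      window_ms = 500,
      dt_ms = 0.5,
      updates_per_day = 1000 / 14,     # 1000 updates == 14 days post-lesion
      ext_high = 8, ext_low = 5,       # mV ms^-1, growth plateau and baseline
      ramp_mid = 500, ramp_tau = 200,  # logistic ramp of the external input
      ext_sd = 1                       # mV ms^-1, white-noise SD
    )
  ), class = "msp_config")
}

config_defaults_mini <- function() {
  cfg <- config_defaults_full()
  cfg$network$grid_nx <- 10L
  cfg$network$grid_ny <- 8L
  cfg$network$n_in <- 20L
  # central 4 x 4 block of grid points: x index 3..6, y index 2..5
  cfg$schedule$lpz_rect <- c(450, 300, 900, 750)
  cfg$schedule$lesion_onset <- 2000L
  cfg$schedule$total_updates <- 5000L
  cfg
}

#' @export
print.msp_config <- function(x, ...) {
  nex <- x$network$grid_nx * x$network$grid_ny
  cat("<msp_config>\n")
  cat(sprintf("  network : %d excitatory (%d x %d grid, %g um), %d inhibitory\n",
              nex, x$network$grid_nx, x$network$grid_ny,
              x$network$spacing, x$network$n_in))
  cat(sprintf("  growth  : nu=%g, eta_A=%g, eta_D=%g, eps=[%g, %g], kernel=%s\n",
              x$growth$nu, x$growth$eta_A, x$growth$eta_D,
              x$growth$eps_lo, x$growth$eps_hi, x$growth$kernel))
  cat(sprintf("  schedule: lesion at T=%d of %d updates, window %g ms, dt %g ms\n",
              x$schedule$lesion_onset, x$schedule$total_updates,
              x$schedule$window_ms, x$schedule$dt_ms))
  invisible(x)
}

#' Validate a configuration
#'
#' Checks every structural invariant of the configuration: positive counts
#' and time constants, ordered homeostatic bounds, the lesion rectangle lying
#' inside the grid extent, and the lesion onset preceding the end of the
#' schedule. Called by every constructor and loader; users only need it after
#' editing a config by hand.
#'
#' @param cfg an \code{msp_config} (or plain list with the same sections).
#' @return the config, invisibly classed as \code{msp_config}.
#' @export
validate_config <- function(cfg) {
  need <- c("network", "neuron", "growth", "schedule")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("configuration is missing section(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  nw <- cfg$network; g <- cfg$growth; s <- cfg$schedule; nr <- cfg$neuron
  fail <- function(msg) stop("invalid configuration: ", msg, call. = FALSE)

  if (nw$grid_nx < 1 || nw$grid_ny < 1) fail("grid dimensions must be >= 1")
  if (nw$n_in < 0) fail("n_in must be >= 0")
  if (nw$spacing <= 0) fail("spacing must be > 0")
  if (nw$jitter < 0 || nw$jitter >= 0.5) fail("jitter must be in [0, 0.5)")

  if (nr$tau_ca <= 0) fail("tau_ca must be > 0")
  if (nr$mu <= 0) fail("mu must be > 0")
  if (nr$v_spike <= nr$c) fail("v_spike must exceed the reset potential c")
  if (nr$beta < 0) fail("beta must be >= 0")

  if (g$nu <= 0) fail("nu must be > 0")
  if (g$eta_A < 0 || g$eta_A >= g$eps_center)
    fail("eta_A must satisfy 0 <= eta_A < eps_center")
  if (g$eta_D < 0 || g$eta_D >= g$eps_center)
    fail("eta_D must satisfy 0 <= eta_D < eps_center")
  if (g$eps_lo >= g$eps_hi) fail("eps_lo must be < eps_hi")
  if (g$tau_vac <= 0) fail("tau_vac must be > 0")
  if (!g$kernel %in% c("gaussian", "flat"))
    fail("kernel must be 'gaussian' or 'flat'")
  if (g$kernel == "gaussian" && g$sigma <= 0) fail("sigma must be > 0")

  if (s$lesion_onset >= s$total_updates)
    fail("lesion_onset must be < total_updates")
  if (s$window_ms <= 0 || s$dt_ms <= 0) fail("window_ms and dt_ms must be > 0")
  if (abs(s$window_ms / s$dt_ms - round(s$window_ms / s$dt_ms)) > 1e-9)
    fail("window_ms must be a multiple of dt_ms")
  r <- s$lpz_rect
  if (length(r) != 4L || r[1] >= r[3] || r[2] >= r[4])
    fail("lpz_rect must be c(x1, y1, x2, y2) with x1 < x2 and y1 < y2")
  xmax <- (nw$grid_nx - 1) * nw$spacing
  ymax <- (nw$grid_ny - 1) * nw$spacing
  if (r[1] < 0 || r[2] < 0 || r[3] > xmax || r[4] > ymax)
    fail("lpz_rect must lie within the grid extent")
  structure(cfg, class = "msp_config")
}

#' Load a configuration file
#'
#' Reads a YAML configuration with sections \code{network}, \code{neuron},
#' \code{growth}, \code{schedule}. Keys that are absent fall back to the
#' defaults of the requested scale; unknown sections or keys are rejected so
#' that typos cannot silently revert a parameter to its default.
#'
#' @param path path to a YAML file. An empty file yields the pure defaults.
#' @param scale base defaults to fill from, see [msp_config()].
#' @return a validated \code{msp_config}.
#' @seealso [write_config()] for the round-trip companion.
#' @export
load_config <- function(path, scale = "full") {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("failed to parse config '", path, "': ", conditionMessage(e),
         call. = FALSE))
  cfg <- if (identical(scale, "full")) config_defaults_full()
         else config_defaults_mini()
  if (is.null(raw)) raw <- list()
  bad_sections <- setdiff(names(raw), names(cfg))
  if (length(bad_sections))
    stop("unknown configuration section(s): ",
         paste(bad_sections, collapse = ", "), call. = FALSE)
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), names(cfg[[sec]]))
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    for (k in names(raw[[sec]])) cfg[[sec]][[k]] <- raw[[sec]][[k]]
  }
  validate_config(cfg)
}

#' Write a configuration file
#'
#' Serializes a configuration to YAML such that
#' \code{load_config(write_config(cfg, f))} reproduces \code{cfg} exactly.
#' Used by the experiment driver to echo the fully resolved configuration
#' next to its outputs.
#'
#' @param cfg an \code{msp_config}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
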