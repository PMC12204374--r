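# Parameter sets: definition, validation, config-file I/O.
#
# Internal unit conventions: nucleoid dimensions and diffusivities are in um
# and um^2/s; all other lengths in nm; times in s; stiffnesses in pN/nm;
# energies in pN*nm. The engine converts to nm internally.

# Flat key -> (unit, comment) used by save_params() and the docs.
.param_keys <- function() {
  c(
    "geometry.nucleoid_length"      = "um; length of the rectangular nucleoid domain",
    "geometry.nucleoid_width"       = "um; width of the nucleoid domain",
    "geometry.lattice_spacing"      = "nm; McdA lattice constant (one particle per site)",
    "geometry.carboxysome_diameter" = "nm; hard-disk diameter of a carboxysome",
    "kinetics.k_off_intrinsic"      = "1/s; intrinsic nucleoid unbinding of unbonded McdA",
    "kinetics.k_rebind"             = "1/s; cytoplasm -> nucleoid rebinding per McdA",
    "kinetics.k_bond_on"            = "1/s; McdA-McdB bond formation rate within capture radius",
    "kinetics.k_bond_off"           = "1/s; McdA-McdB bond breaking rate (with McdA ejection)",
    "kinetics.D_mcdA_nucleoid"      = "um^2/s; McdA surface diffusion coefficient",
    "kinetics.D_carb"               = "um^2/s; carboxysome diffusion coefficient",
    "kinetics.n_mcdA"               = "count; total McdA particles (nucleoid + cytoplasm)",
    "kinetics.n_mcdB_per_carb"      = "count; McdB sites fixed on each carboxysome",
    "kinetics.capture_radius"       = "nm; max McdA-McdB distance for bond formation",
    "kinetics.kBT"                  = "pN*nm; thermal energy",
    "springs.k_AB"                  = "pN/nm; McdA-McdB bond stiffness",
    "springs.k_self"                = "pN/nm; carboxysome self-association stiffness",
    "springs.rest_length_AB"        = "nm; bond rest length (0 = pure tether)",
    "springs.rest_length_self"      = "nm; self-association rest length (contact)",
    "springs.self_range"            = "nm; self-association engagement cutoff",
    "springs.max_extension_AB"      = "nm; hard bond-extension guard (instant break)",
    "run.duration"                  = "s; simulated time per trajectory",
    "run.dt"                        = "s; integration time step",
    "run.n_carboxysomes"            = "count",
    "run.n_trajectories"            = "count; ensemble size",
    "run.seed"                      = "integer; base random seed",
    "run.record_interval"           = "s; sampling interval for the trajectory",
    "classify.clustered_time_fraction"  = "fraction; in-range time share defining 'clustered'",
    "classify.positioned_range_fraction" = "fraction of nucleoid length defining 'positioned'"
  )
}

#' Calibrated reference parameter set
#'
#' Returns the calibrated default model parameters. The study conditions are:
#' two 150 nm carboxysomes on a 2.0 x 0.5 um nucleoid, self-association
#' stiffness `k_self = 0.6` pN/nm, 300 s trajectories recorded every 0.1 s,
#' ensembles of 64 trajectories, and the regime thresholds (clustered if the
#' pair is within the self-association range > 90% of recorded time,
#' positioned if the movement range is < 0.25 x nucleoid length). Microscopic
#' rates and diffusivities are calibration choices documented in the methods
#' vignette; all values can be overridden via [load_params()].
#'
#' @return An object of class `mcd_params`: a nested list with components
#'   `geometry`, `kinetics`, `springs`, `run`, `classify`.
#' @examples
#' p <- default_params()
#' p$springs$k_self
#' @export
default_params <- function() {
  p <- list(
    geometry = list(
      nucleoid_length = 2.0,
      nucleoid_width = 0.5,
      lattice_spacing = 25,
      carboxysome_diameter = 150
    ),
    kinetics = list(
      k_off_intrinsic = 0.03,
      k_rebind = 0.05,
      k_bond_on = 50,
      k_bond_off = 3,
      D_mcdA_nucleoid = 0.05,
      D_carb = 1e-3,
      n_mcdA = 500,
      n_mcdB_per_carb = 100,
      capture_radius = 25,
      kBT = 4.1
    ),
    springs = list(
      k_AB = 0.3,
      k_self = 0.6,
      rest_length_AB = 0,
      rest_length_self = 150,
      self_range = 167,
      max_extension_AB = 200
    ),
    run = list(
      duration = 300,
      dt = 5e-4,
      n_carboxysomes = 2,
      n_trajectories = 64,
      seed = 1,
      record_interval = 0.1
    ),
    classify = list(
      clustered_time_fraction = 0.90,
      positioned_range_fraction = 0.25
    )
  )
  class(p) <- "mcd_params"
  p
}

.is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  abs(x - round(x)) < 1e-9

.is_near_integer <- function(x, tol = 1e-6) abs(x - round(x)) < tol * max(1, abs(x))

#' Validate a parameter set
#'
#' Checks every invariant of the model parameters; errors name the offending
#' configuration key (e.g. `springs.k_AB`).
#'
#' @param params an `mcd_params` object or equivalent nested list.
#' @return `params`, invisibly, if valid.
#' @export
validate_params <- function(params) {
  fail <- function(key, msg, got = NULL) {
    stop(sprintf("invalid parameter %s: %s%s", key, msg,
                 if (is.null(got)) "" else sprintf(" (got %s)", format(got))),
         call. = FALSE)
  }
  need <- function(section, keys) {
    if (is.null(params[[section]]) || !is.list(params[[section]]))
      fail(section, "section missing")
    for (k in keys) {
      v <- params[[section]][[k]]
      key <- paste0(section, ".", k)
      if (is.null(v)) fail(key, "missing")
      if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
        fail(key, "must be a finite numeric scalar")
    }
  }
  need("geometry", c("nucleoid_length", "nucleoid_width", "lattice_spacing",
                     "carboxysome_diameter"))
  need("kinetics", c("k_off_intrinsic", "k_rebind", "k_bond_on", "k_bond_off",
                     "D_mcdA_nucleoid", "D_carb", "n_mcdA", "n_mcdB_per_carb",
                     "capture_radius", "kBT"))
  need("springs", c("k_AB", "k_self", "rest_length_AB", "rest_length_self",
                    "self_range", "max_extension_AB"))
  need("run", c("duration", "dt", "n_carboxysomes", "n_trajectories", "seed",
                "record_interval"))
  need("classify", c("clustered_time_fraction", "positioned_range_fraction"))

  g <- params$geometry; k <- params$kinetics; s <- params$springs
  r <- params$run; cl <- params$classify

  if (g$lattice_spacing <= 0) fail("geometry.lattice_spacing", "must be > 0", g$lattice_spacing)
  if (g$carboxysome_diameter <= 0) fail("geometry.carboxysome_diameter", "must be > 0")
  if (g$nucleoid_length <= g$nucleoid_width)
    fail("geometry.nucleoid_length", "must exceed nucleoid_width", g$nucleoid_length)
  if (g$nucleoid_width * 1000 <= g$carboxysome_diameter)
    fail("geometry.nucleoid_width", "must exceed the carboxysome diameter", g$nucleoid_width)
  if (!.is_near_integer(g$nucleoid_length * 1000 / g$lattice_spacing))
    fail("geometry.nucleoid_length", "must be an integer multiple of lattice_spacing")
  if (!.is_near_integer(g$nucleoid_width * 1000 / g$lattice_spacing))
    fail("geometry.nucleoid_width", "must be an integer multiple of lattice_spacing")

  for (kk in c("k_off_intrinsic", "k_rebind", "k_bond_on", "k_bond_off",
               "D_mcdA_nucleoid", "D_carb"))
    if (k[[kk]] < 0) fail(paste0("kinetics.", kk), "must be >= 0", k[[kk]])
  if (!.is_count(k$n_mcdA) || k$n_mcdA < 1) fail("kinetics.n_mcdA", "must be a count >= 1", k$n_mcdA)
  if (!.is_count(k$n_mcdB_per_carb) || k$n_mcdB_per_carb < 1)
    fail("kinetics.n_mcdB_per_carb", "must be a count >= 1", k$n_mcdB_per_carb)
  if (k$capture_radius <= 0) fail("kinetics.capture_radius", "must be > 0", k$capture_radius)
  if (k$kBT <= 0) fail("kinetics.kBT", "must be > 0", k$kBT)

  for (kk in c("k_AB", "k_self"))
    if (s[[kk]] < 0) fail(paste0("springs.", kk), "must be >= 0", s[[kk]])
  if (s$rest_length_AB < 0) fail("springs.rest_length_AB", "must be >= 0", s$rest_length_AB)
  if (s$rest_length_self < g$carboxysome_diameter)
    fail("springs.rest_length_self", "must be >= carboxysome_diameter (contact)",
         s$rest_length_self)
  if (s$self_range < s$rest_length_self)
    fail("springs.self_range", "must be >= rest_length_self", s$self_range)
  if (s$max_extension_AB <= k$capture_radius)
    fail("springs.max_extension_AB", "must exceed capture_radius", s$max_extension_AB)

  if (r$duration <= 0) fail("run.duration", "must be > 0", r$duration)
  if (r$dt <= 0) fail("run.dt", "must be > 0", r$dt)
  if (!.is_near_integer(r$duration / r$dt))
    fail("run.duration", "must be an integer number of time steps")
  if (r$record_interval < r$dt) fail("run.record_interval", "must be >= dt", r$record_interval)
  if (!.is_near_integer(r$record_interval / r$dt))
    fail("run.record_interval", "must be an integer multiple of dt")
  if (!.is_count(r$n_carboxysomes) || r$n_carboxysomes < 1)
    fail("run.n_carboxysomes", "must be a count >= 1", r$n_carboxysomes)
  if (!.is_count(r$n_trajectories) || r$n_trajectories < 1)
    fail("run.n_trajectories", "must be a count >= 1", r$n_trajectories)
  if (!.is_count(r$seed)) fail("run.seed", "must be an integer", r$seed)

  for (kk in c("clustered_time_fraction", "positioned_range_fraction"))
    if (cl[[kk]] <= 0 || cl[[kk]] >= 1)
      fail(paste0("classify.", kk), "must lie strictly in (0, 1)", cl[[kk]])

  # tau-leap sanity: per-step hop probability must not exceed 1
  p_hop <- 4 * k$D_mcdA_nucleoid * 1e6 / g$lattice_spacing^2 * r$dt
  if (p_hop > 1)
    fail("run.dt", sprintf(
      "per-step McdA hop probability 4*D*dt/a^2 = %.3g exceeds 1; reduce run.dt or kinetics.D_mcdA_nucleoid",
      p_hop))

  # initial placement feasibility (row of touching disks about the center)
  span <- (r$n_carboxysomes - 1) * s$rest_length_self + g$carboxysome_diameter
  if (span > g$nucleoid_length * 1000)
    fail("run.n_carboxysomes", "carboxysomes do not fit in the domain at contact spacing")

  # lattice capacity for the steady-state bound McdA count
  nsites <- round(g$nucleoid_length * 1000 / g$lattice_spacing) *
    round(g$nucleoid_width * 1000 / g$lattice_spacing)
  denom <- k$k_rebind + k$k_off_intrinsic
  fb <- if (denom > 0) k$k_rebind / denom else 1
  if (round(fb * k$n_mcdA) > nsites)
    fail("kinetics.n_mcdA", "steady-state bound count exceeds lattice capacity")

  invisible(params)
}

.flatten_params <- function(params) {
  out <- list()
  for (sec in names(params))
    for (kk in names(params[[sec]]))
      out[[paste0(sec, ".", kk)]] <- params[[sec]][[kk]]
  out
}

.unflatten_set <- function(params, key, value) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 || is.null(params[[parts[1]]]) ||
      !(parts[2] %in% names(params[[parts[1]]])))
    stop(sprintf("unknown configuration key: %s", key), call. = FALSE)
  params[[parts[1]]][[parts[2]]] <- value
  params
}

#' Load a parameter set from a config file
#'
#' The config format is a flat `section.key = value` file (one key per line,
#' `#` comments allowed). Keys not present take the calibrated defaults of
#' [default_params()]; unknown keys are an error.
#'
#' @param path path to the config file.
#' @param base parameter set supplying defaults for unspecified keys.
#' @return A validated `mcd_params` object.
#' @export
load_params <- function(path, base = default_params()) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  params <- base
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3)
      stop(sprintf("cannot parse config line: '%s'", ln), call. = FALSE)
    key <- m[2]
    val <- suppressWarnings(as.numeric(m[3]))
    if (is.na(val))
      stop(sprintf("value for key %s is not numeric: '%s'", key, m[3]), call. = FALSE)
    params <- .unflatten_set(params, key, val)
  }
  class(params) <- "mcd_params"
  validate_params(params)
}

#' Apply `section.key=value` overrides to a parameter set
#'
#' @param params an `mcd_params` object.
#' @param overrides character vector like `c("springs.k_AB=0.3")`.
#' @return The validated, modified parameter set.
#' @export
set_params <- function(params, overrides) {
  for (ov in overrides) {
    m <- regmatches(ov, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.+)$", ov))[[1]]
    if (length(m) != 3) stop(sprintf("cannot parse override: '%s'", ov), call. = FALSE)
    val <- suppressWarnings(as.numeric(m[3]))
    if (is.na(val)) stop(sprintf("value for key %s is not numeric", m[2]), call. = FALSE)
    params <- .unflatten_set(params, m[2], val)
  }
  class(params) <- "mcd_params"
  validate_params(params)
}

#' Write a parameter set to a config file
#'
#' Writes every key with its unit as a comment; the file round-trips
#' losslessly through [load_params()].
#'
#' @param params a valid `mcd_params` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_params <- function(params, path) {
  validate_params(params)
  flat <- .flatten_params(params)
  info <- .param_keys()
  lines <- c("# mcdratchet parameter file (schema v1)")
  sec_prev <- ""
  for (key in names(info)) {
    sec <- sub("\\..*$", "", key)
    if (sec != sec_prev) {
      lines <- c(lines, "", paste0("# [", sec, "]"))
      sec_prev <- sec
    }
    lines <- c(lines, sprintf("%s = %s  # %s", key,
                              sprintf("%.17g", flat[[key]]), info[[key]]))
  }
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path))
    stop(sprintf("cannot write config file: %s", path), call. = FALSE)
  invisible(path)
}

#' @export
print.mcd_params <- function(x, ...) {
  cat("mcdratchet parameter set\n")
  flat <- .flatten_params(x)
  for (key in names(flat))
    cat(sprintf("  %-36s %s\n", key, format(flat[[key]])))
  invisible(x)
}
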