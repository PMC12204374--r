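# File formats: trajectory CSV (long, um/s), summary JSON, run manifests.
# CSV schema version rides in a leading comment line; JSON schemas carry a
# "schema" field. Coordinates are written with 6 significant digits in um
# (sub-nm, below physical meaning), which keeps outputs byte-stable across
# identical runs.

.traj_schema <- "# mcdratchet trajectory schema v1"
.phase_schema <- "# mcdratchet phase-diagram schema v1"

#' Write a trajectory to CSV
#'
#' Long format: one row per (sample, carboxysome) with columns `time_s`,
#' `carb_id`, `x_um`, `y_um`, `n_bonds`; schema version in a leading `#`
#' comment. Identical trajectories produce byte-identical files.
#'
#' @param traj an `mcd_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  nc <- traj$n_carboxysomes
  n <- length(traj$time)
  time <- rep(traj$time, each = nc)
  carb <- rep(seq_len(nc), times = n)
  x <- as.vector(t(traj$x))
  y <- as.vector(t(traj$y))
  nb <- as.vector(t(traj$n_bonds))
  lines <- c(.traj_schema,
             "time_s,carb_id,x_um,y_um,n_bonds",
             sprintf("%.10g,%d,%.6g,%.6g,%d", time, carb, x, y, as.integer(nb)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' Accepts simulator output or externally tracked foci exported in the same
#' schema (`time_s`, `carb_id`, `x_um`, `y_um`, optional `n_bonds`).
#'
#' @param path CSV path.
#' @return An `mcd_trajectory` (without generating `params`).
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop(sprintf("trajectory file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time_s", "carb_id", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("trajectory CSV lacks required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (is.null(df$n_bonds)) df$n_bonds <- 0L
  ids <- sort(unique(df$carb_id))
  times <- sort(unique(df$time_s))
  n <- length(times); nc <- length(ids)
  if (nrow(df) != n * nc)
    stop("trajectory CSV is not a complete (sample x carboxysome) grid", call. = FALSE)
  x <- matrix(NA_real_, n, nc); y <- matrix(NA_real_, n, nc)
  nb <- matrix(0L, n, nc)
  ord <- order(df$time_s, df$carb_id)
  df <- df[ord, ]
  for (j in seq_len(nc)) {
    sel <- df$carb_id == ids[j]
    x[, j] <- df$x_um[sel]; y[, j] <- df$y_um[sel]; nb[, j] <- df$n_bonds[sel]
  }
  structure(list(time = times, x = x, y = y, n_bonds = nb,
                 n_mcdA_nucleoid = rep(NA_real_, n), n_carboxysomes = nc,
                 params = NULL, seed = NA_integer_),
            class = "mcd_trajectory")
}

#' @export
as.data.frame.mcd_trajectory <- function(x, ...) {
  nc <- x$n_carboxysomes
  data.frame(
    time_s = rep(x$time, times = nc),
    carb_id = rep(seq_len(nc), each = length(x$time)),
    x_um = as.vector(x$x),
    y_um = as.vector(x$y),
    n_bonds = as.vector(x$n_bonds)
  )
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Manifest: enough to re-run an output set bit-identically (params + seeds),
# plus provenance (package version, timestamp, file list).
.write_manifest <- function(path, params, seeds, outputs, command) {
  .write_json(list(
    schema = "mcdratchet-manifest-v1",
    package = "mcdratchet",
    version = as.character(utils::packageVersion("mcdratchet")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    command = command,
    seeds = seeds,
    params = .flatten_params(params),
    outputs = outputs
  ), path)
}

#' Read a run manifest
#'
#' Restores the parameter set and seed schedule recorded alongside an output
#' set, sufficient to reproduce it exactly.
#'
#' @param path manifest JSON path.
#' @return List with `params` (validated `mcd_params`), `seeds`, and the raw
#'   manifest fields.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- default_params()
  for (key in names(m$params))
    params <- .unflatten_set(params, key, as.numeric(m$params[[key]]))
  class(params) <- "mcd_params"
  validate_params(params)
  list(params = params, seeds = m$seeds, manifest = m)
}
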