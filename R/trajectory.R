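#' Construct an ion trajectory
#'
#' An `ion_trajectory` holds per-frame one-dimensional ion positions along
#' the pore axis (z, in Angstrom, increasing from the intracellular to the
#' extracellular side). Each row is one observation of one ion at one frame;
#' an ion absent at a frame is simply not listed there (it is outside the
#' tracked region). Frame times must be evenly spaced and each
#' (frame, ion_id) pair unique.
#'
#' @param frame integer frame indices (>= 0)
#' @param time_ps frame times in picoseconds
#' @param ion_id ion identities, stable across frames (integer or character)
#' @param z axial coordinates in Angstrom
#' @return an `ion_trajectory`: a `data.table` with columns
#'   `frame`, `time_ps`, `ion_id`, `z`, and attributes `frame_interval`
#'   (ps) and `duration` (ps, time span of the analyzed frames)
#' @export
ion_trajectory <- function(frame, time_ps, ion_id, z) {
  dt <- data.table(frame = as.integer(frame),
                   time_ps = as.numeric(time_ps),
                   ion_id = ion_id,
                   z = as.numeric(z))
  validate_ion_trajectory(dt)
}

validate_ion_trajectory <- function(dt) {
  required <- c("frame", "time_ps", "ion_id", "z")
  missing <- setdiff(required, names(dt))
  if (length(missing) > 0L) {
    stop("trajectory table lacks column(s): ", paste(missing, collapse = ", "))
  }
  dt <- as.data.table(dt)[, required, with = FALSE]
  if (nrow(dt) == 0L) stop("empty trajectory")
  if (anyDuplicated(dt, by = c("frame", "ion_id")) > 0L) {
    dup <- dt[duplicated(dt, by = c("frame", "ion_id"))][1L]
    stop(sprintf("duplicate (frame, ion_id) observation: frame %d, ion %s",
                 dup$frame, as.character(dup$ion_id)))
  }
  ft <- unique(dt[, .(frame, time_ps)])
  setorder(ft, frame)
  if (anyDuplicated(ft$frame) > 0L) {
    stop("inconsistent time_ps within a frame")
  }
  if (is.unsorted(ft$time_ps, strictly = TRUE)) {
    stop("frame times must be strictly increasing")
  }
  if (nrow(ft) > 1L) {
    steps <- diff(ft$time_ps) / diff(ft$frame)
    interval <- steps[1L]
    if (any(abs(steps - interval) > 1e-6 * max(interval, 1))) {
      stop("frame times must be evenly spaced")
    }
  } else {
    interval <- NA_real_
  }
  setorder(dt, frame, ion_id)
  setattr(dt, "frame_interval", interval)
  setattr(dt, "duration", diff(range(ft$time_ps)))
  setattr(dt, "class", c("ion_trajectory", class(data.table())))
  dt[]
}

#' @export
print.ion_trajectory <- function(x, ...) {
  cat(sprintf(
    "<ion_trajectory> %d observations, %d frames, %d ions, %.6g ps/frame, %.6g ns\n",
    nrow(x), uniqueN(x$frame), uniqueN(x$ion_id),
    attr(x, "frame_interval"), attr(x, "duration") / 1e3))
  NextMethod()
}

#' Read / write trajectory tables
#'
#' Plain tabular interchange format with header columns
#' `frame,time_ps,ion_id,z` (TSV or CSV; the delimiter is auto-detected on
#' read and chosen by `format` on write). The round trip is lossless.
#'
#' @param path file path
#' @param format `"tsv"` or `"csv"`
#' @return [read_ion_trajectory()] returns an `ion_trajectory`;
#'   [write_ion_trajectory()] returns `path` invisibly.
#' @export
read_ion_trajectory <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, sep = if (format == "tsv") "\t" else ",")
  validate_ion_trajectory(dt)
}

#' @param traj an `ion_trajectory`
#' @rdname read_ion_trajectory
#' @export
write_ion_trajectory <- function(traj, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  fwrite(as.data.table(traj), path,
         sep = if (format == "tsv") "\t" else ",")
  invisible(path)
}

#' Define the pore axis from two reference points
#'
#' The pore axis runs from the centroid of the four Thr carbonyl oxygens at
#' the intracellular end of the selectivity filter (`origin`, mapped to
#' z = 0) towards the centroid of the four Tyr carbonyl oxygens
#' (`tip`); z increases towards the extracellular side.
#'
#' @param origin,tip numeric length-3 points (Angstrom)
#' @return an `axis_definition` list with `origin`, `tip` and the unit
#'   direction vector `u`
#' @export
axis_definition <- function(origin, tip) {
  origin <- as.numeric(origin); tip <- as.numeric(tip)
  stopifnot(length(origin) == 3L, length(tip) == 3L)
  d <- tip - origin
  nrm <- sqrt(sum(d^2))
  if (nrm < 1e-12) stop("degenerate axis: origin equals tip")
  structure(list(origin = origin, tip = tip, u = d / nrm),
            class = "axis_definition")
}

#' Project 3-D ion coordinates onto the pore axis
#'
#' z is the signed distance of each point from the axis origin along the
#' axis unit vector, so the origin maps to z = 0 and the tip to
#' `|tip - origin|`.
#'
#' @param points a data.frame with columns `frame`, `time_ps`, `ion_id`,
#'   `x`, `y`, `z` (laboratory coordinates, Angstrom)
#' @param axis an [axis_definition()]
#' @return an `ion_trajectory` of axial coordinates
#' @export
project_to_axis <- function(points, axis) {
  stopifnot(inherits(axis, "axis_definition"))
  pts <- as.data.table(points)
  required <- c("frame", "time_ps", "ion_id", "x", "y", "z")
  missing <- setdiff(required, names(pts))
  if (length(missing) > 0L) {
    stop("points table lacks column(s): ", paste(missing, collapse = ", "))
  }
  proj <- (pts$x - axis$origin[1]) * axis$u[1] +
          (pts$y - axis$origin[2]) * axis$u[2] +
          (pts$z - axis$origin[3]) * axis$u[3]
  ion_trajectory(pts$frame, pts$time_ps, pts$ion_id, proj)
}

#' Drop the equilibration segment of a trajectory
#'
#' Removes all frames with `time_ps < t_cut`. Production analyses of
#' state statistics typically discard an initial relaxation window (50 ns
#' for the half-microsecond runs this package was designed around), while
#' event counting for currents conventionally uses the full length.
#'
#' @param traj an `ion_trajectory`
#' @param t_cut cut time in ps (frames strictly before it are dropped)
#' @return the trimmed `ion_trajectory`
#' @export
trim_equilibration <- function(traj, t_cut) {
  stopifnot(inherits(traj, "ion_trajectory"), t_cut >= 0)
  if (t_cut == 0) return(traj)
  kept <- as.data.table(traj)[time_ps >= t_cut]
  if (nrow(kept) == 0L) {
    stop(sprintf("t_cut = %g ps removes every frame", t_cut))
  }
  validate_ion_trajectory(kept)
}

#' Membrane voltage from a constant electric field
#'
#' For a constant external field applied across a periodic simulation cell,
#' the membrane voltage is V = L_z * E, with L_z the cell length along the
#' field (membrane normal).
#'
#' @param E field strength in mV/Angstrom
#' @param L_z cell length in Angstrom
#' @return membrane voltage in mV
#' @export
voltage_from_field <- function(E, L_z) {
  stopifnot(L_z > 0)
  L_z * E
}
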