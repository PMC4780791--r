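#' Binding-site model of the pore axis
#'
#' Eight strictly increasing axial thresholds partition the axis into nine
#' half-open regions, from low to high z:
#' `INTRA | S6 | S5 | S4 | S3 | S2 | S1 | S0 | EXTRA`.
#' S0 sits at the extracellular mouth of the selectivity filter, S4 at its
#' intracellular end; S5 is the partially hydrated Thr side-chain site and
#' S6 the hydrated cavity. Each boundary belongs to the region above it
#' (`[lo, hi)` convention, ties to the extracellular side).
#'
#' @param thresholds numeric vector of 8 strictly increasing positions
#'   (Angstrom) delimiting INTRA/S6, S6/S5, ..., S1/S0, S0/EXTRA
#' @param capacity named integer vector of per-site ion capacities; defaults
#'   to 1 for S1--S6 and 2 for S0 (double S0 occupancy is observed when
#'   extracellular ions crowd the pore exit)
#' @return a `site_model` list with `thresholds` (named by the boundary they
#'   mark) and `capacity`
#' @export
site_model <- function(thresholds, capacity = NULL) {
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != 8L) {
    stop("need exactly 8 thresholds (INTRA/S6 ... S0/EXTRA)")
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  default_cap <- stats::setNames(c(2L, rep(1L, 6L)), paste0("S", 0:6))
  if (is.null(capacity)) {
    capacity <- default_cap
  } else {
    capacity <- utils::modifyList(as.list(default_cap), as.list(capacity))
    capacity <- unlist(capacity)[paste0("S", 0:6)]
    storage.mode(capacity) <- "integer"
    if (any(capacity < 1L)) stop("site capacities must be >= 1")
  }
  names(thresholds) <- c("INTRA/S6", "S6/S5", "S5/S4", "S4/S3",
                         "S3/S2", "S2/S1", "S1/S0", "S0/EXTRA")
  structure(list(thresholds = thresholds, capacity = capacity),
            class = "site_model")
}

#' @export
print.site_model <- function(x, ...) {
  cat("<site_model>\n  thresholds (A):",
      paste(sprintf("%s=%.2f", names(x$thresholds), x$thresholds),
            collapse = " "),
      "\n  capacity:",
      paste(sprintf("%s=%d", names(x$capacity), x$capacity), collapse = " "),
      "\n")
  invisible(x)
}

#' Default site model
#'
#' The thresholds shipped here are synthetic package defaults constructed
#' from the canonical pore geometry (a ~14 Angstrom hydrated cavity below
#' the filter and ~3.2 Angstrom spacing between filter sites), matched to
#' the site centers used by [hop_model()]. They are a working definition
#' for synthetic and demonstration data, not measured values; for real
#' trajectories estimate thresholds from the ion density
#' ([estimate_thresholds()]) or supply your own.
#'
#' @return a `site_model`
#' @export
default_site_model <- function() {
  path <- system.file("extdata", "site_model_default.json",
                      package = "permeon", mustWork = TRUE)
  read_site_model(path)
}

#' Serialize a site model
#'
#' JSON with fields `thresholds` (ordered) and `capacity`.
#'
#' @param model a `site_model`
#' @param path file path
#' @return `read_site_model()` returns a `site_model`
#' @export
write_site_model <- function(model, path) {
  stopifnot(inherits(model, "site_model"))
  jsonlite::write_json(
    list(thresholds = unname(model$thresholds),
         capacity = as.list(model$capacity)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_site_model
#' @export
read_site_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  site_model(obj$thresholds, capacity = unlist(obj$capacity))
}

#' Axial ion-density profile
#'
#' Histogram of all (frame, ion) axial positions, used to locate binding
#' sites as density maxima separated by minima.
#'
#' @param traj an `ion_trajectory`
#' @param bin_width bin width in Angstrom
#' @param range optional length-2 axial range; defaults to the data range
#' @return a `density_profile`: data.table with `bin_lo`, `bin_hi`, `mid`,
#'   `count`, `density` (normalized so that sum(density * bin_width) = 1)
#' @export
density_profile <- function(traj, bin_width = 0.5, range = NULL) {
  stopifnot(bin_width > 0)
  z <- traj[["z"]]
  if (is.null(z) || length(z) == 0L) stop("empty trajectory")
  if (is.null(range)) range <- base::range(z)
  lo <- floor(range[1] / bin_width) * bin_width
  hi <- floor(range[2] / bin_width) * bin_width + bin_width
  edges <- seq(lo, hi, by = bin_width)
  counts <- tabulate(findInterval(z, edges, rightmost.closed = FALSE),
                     nbins = length(edges) - 1L)
  out <- data.table(bin_lo = edges[-length(edges)],
                    bin_hi = edges[-1L],
                    count = counts)
  out[, mid := (bin_lo + bin_hi) / 2]
  out[, density := count / (sum(count) * bin_width)]
  setattr(out, "class", c("density_profile", class(data.table())))
  setattr(out, "bin_width", bin_width)
  out[]
}

# moving-average smoothing; width in bins (odd), edges padded by repetition
.smooth_counts <- function(x, width = 3L) {
  if (width <= 1L) return(x)
  half <- width %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 2L))[
    (half + 1L):(half + length(x))]
}

#' Estimate site thresholds from an ion-density profile
#'
#' Smooths the histogram with a 3-bin moving average, finds local maxima
#' (site positions) and places boundaries at the deepest minimum between
#' each pair of retained adjacent maxima. The `n_sites` tallest maxima are
#' kept; the outer pore boundaries are set half a site spacing beyond the
#' outermost maxima.
#'
#' @param profile a [density_profile()]
#' @param n_sites number of binding sites (default 7: S0--S6)
#' @param smooth_width moving-average width in bins
#' @return a `site_model` when `n_sites` is 7; otherwise the bare numeric
#'   vector of `n_sites + 1` boundaries (low to high z)
#' @export
estimate_thresholds <- function(profile, n_sites = 7L, smooth_width = 3L) {
  stopifnot(inherits(profile, "density_profile"), n_sites >= 2L)
  d <- .smooth_counts(profile$density, smooth_width)
  n <- length(d)
  if (n < 2L * n_sites + 1L) stop("profile has too few bins")
  # strict interior local maxima of the smoothed density
  is_max <- c(FALSE, d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n],
              FALSE)
  peaks <- which(is_max & d > 0)
  # collapse plateaus: keep the first bin of any run of adjacent maxima
  if (length(peaks) > 1L) peaks <- peaks[c(TRUE, diff(peaks) > 1L)]
  if (length(peaks) < n_sites) {
    stop(sprintf(paste0("found only %d density mode(s), need %d; ",
                        "use a wider trajectory or supply thresholds"),
                 length(peaks), n_sites))
  }
  keep <- sort(peaks[order(d[peaks], decreasing = TRUE)][seq_len(n_sites)])
  cuts <- numeric(n_sites - 1L)
  for (i in seq_len(n_sites - 1L)) {
    span <- keep[i]:keep[i + 1L]
    cuts[i] <- profile$mid[span[which.min(d[span])]]
  }
  spacing <- mean(diff(profile$mid[keep]))
  lo <- profile$mid[keep[1L]] - spacing / 2
  hi <- profile$mid[keep[n_sites]] + spacing / 2
  bounds <- c(lo, cuts, hi)
  if (n_sites == 7L) site_model(bounds) else bounds
}

#' Assign an axial position to a region
#'
#' Half-open `[lo, hi)` intervals: a z exactly on a boundary belongs to the
#' region on its extracellular (high-z) side. Every real z maps to exactly
#' one of `INTRA`, `S6` ... `S0`, `EXTRA`.
#'
#' @param z numeric axial positions (Angstrom)
#' @param model a `site_model`
#' @return character vector of region labels
#' @export
assign_site <- function(z, model) {
  stopifnot(inherits(model, "site_model"))
  idx <- findInterval(z, model$thresholds, left.open = FALSE,
                      rightmost.closed = FALSE)
  .REGIONS[idx + 1L]
}

# integer site index 0..6 for S0..S6, NA for bulk regions
.site_index <- function(region) {
  idx <- match(region, paste0("S", 0:6))
  idx - 1L
}
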