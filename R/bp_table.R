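# Pressure -> detected-intensity lookup tables: Monte Carlo sweep over the
# working blood-pressure range, monotonization, parametric conditioning,
# and piecewise-linear inversion back to pressure.

#' Construct an intensity table
#'
#' Container for a blood-pressure to detected-photon-intensity lookup
#' table.  Intensities are per-launched-packet normalized total exit
#' weights on the detector side of the slab.
#'
#' @param pressures Strictly ascending pressure grid, mmHg.
#' @param intensities Non-negative detected intensities, same length.
#' @param mc_se Monte Carlo standard error per point (optional).
#' @param wavelength_nm Wavelength the table was generated at.
#' @param mode `"transmission"` or `"reflection"`.
#' @param provenance List of free-form provenance fields (seed, photon
#'   budget, geometry summary).
#' @return Object of class `intensity_table` (a data frame with columns
#'   `pressure`, `intensity`, `mc_se` and metadata attributes).
#' @export
intensity_table <- function(pressures, intensities, mc_se = NA_real_,
                            wavelength_nm = NA_real_,
                            mode = c("transmission", "reflection"),
                            provenance = list()) {
  mode <- match.arg(mode)
  if (length(pressures) != length(intensities))
    stop("pressures and intensities must have equal length")
  if (any(diff(pressures) <= 0))
    stop("pressures must be strictly ascending")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  out <- data.frame(pressure = pressures, intensity = intensities,
                    mc_se = mc_se)
  attr(out, "wavelength_nm") <- wavelength_nm
  attr(out, "mode") <- mode
  attr(out, "provenance") <- provenance
  attr(out, "monotone") <- !is.unsorted(intensities) ||
    !is.unsorted(rev(intensities))
  class(out) <- c("intensity_table", "data.frame")
  out
}

#' Generate the blood-pressure to intensity table by Monte Carlo sweep
#'
#' Rebuilds the voxel finger model at each pressure of the grid (the
#' artery cylinder and its absorption updated) and runs the photon
#' transport simulation, recording the per-packet-normalized total exit
#' weight on the detector side as the intensity.  The default pressure
#' grid covers the working range 42--200 mmHg.
#'
#' By default every pressure point reuses the same per-photon random
#' streams (common random numbers): with the pressure-independent slab,
#' photon histories that never reach the arterial band are identical
#' across pressures, so shared Monte Carlo variance cancels from
#' point-to-point differences while the whole table stays reproducible
#' from one seed.  Set `common_rng = FALSE` for independent per-pressure
#' substreams.
#'
#' @param geometry A [finger_geometry()].
#' @param wavelength_nm 905 or 940.
#' @param mode Detector side: `"transmission"` (exit face) or
#'   `"reflection"` (entry face).
#' @param pressure_min,pressure_max,step Pressure grid, mmHg; the grid has
#'   `floor((max - min) / step) + 1` points.
#' @param n_photons Packets per grid point.
#' @param seed Integer seed for the whole table.
#' @param common_rng Reuse identical photon streams across pressures
#'   (default `TRUE`).
#' @param ... Further arguments passed to [run_simulation()].
#' @return An [intensity_table()].
#' @export
generate_table <- function(geometry = finger_geometry(),
                           wavelength_nm = 940,
                           mode = c("transmission", "reflection"),
                           pressure_min = 42, pressure_max = 200, step = 1,
                           n_photons = 1e5, seed = 1, common_rng = TRUE,
                           ...) {
  mode <- match.arg(mode)
  if (pressure_min > pressure_max) stop("pressure_min must be <= pressure_max")
  if (step <= 0) stop("step must be positive")
  n_pts <- floor((pressure_max - pressure_min) / step) + 1
  pressures <- pressure_min + step * (seq_len(n_pts) - 1)

  intensity <- mc_se <- numeric(n_pts)
  for (i in seq_len(n_pts)) {
    p <- pressures[i]
    seed_i <- if (common_rng) seed
      else (seed + 1000003 * i) %% .Machine$integer.max
    res <- tryCatch({
      grid <- build_voxel_model(geometry, pressure = p,
                                wavelength_nm = wavelength_nm)
      run_simulation(grid, n_photons = n_photons, seed = seed_i,
                     fluence = FALSE, ...)
    }, error = function(e)
      stop("simulation failed at pressure ", p, " mmHg: ",
           conditionMessage(e), call. = FALSE))
    if (mode == "transmission") {
      intensity[i] <- res$transmitted
      mc_se[i] <- res$transmitted_se
    } else {
      intensity[i] <- res$reflected
      mc_se[i] <- res$reflected_se
    }
  }
  intensity_table(pressures, intensity, mc_se,
                  wavelength_nm = wavelength_nm, mode = mode,
                  provenance = list(seed = seed, n_photons = n_photons,
                                    common_rng = common_rng,
                                    generator = "mc_sweep"))
}

table_direction <- function(table) {
  rho <- suppressWarnings(
    stats::cor(table$pressure, table$intensity, method = "spearman"))
  if (is.na(rho) || rho == 0)
    stop("intensity table shows no overall trend with pressure; ",
         "increase the photon budget")
  sign(rho)
}

#' Monotonize an intensity table by isotonic regression
#'
#' Pool-adjacent-violators (isotonic) regression of intensity against
#' pressure, in the direction of the table's overall trend (sign of the
#' Spearman correlation).  Idempotent: an already monotone table is
#' returned unchanged.  Pooled points become exact ties (flats), so a
#' heavily noise-dominated table remains only weakly monotone; see
#' [fit_table()] for a strictly monotone parametric alternative.
#'
#' @param table An [intensity_table()].
#' @return An [intensity_table()] with monotone intensities.
#' @export
monotonize <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  s <- table_direction(table)
  fit <- stats::isoreg(table$pressure, s * table$intensity)
  out <- intensity_table(table$pressure, s * fit$yf, table$mc_se,
                         wavelength_nm = attr(table, "wavelength_nm"),
                         mode = attr(table, "mode"),
                         provenance = c(attr(table, "provenance"),
                                        list(monotonized = TRUE)))
  attr(out, "monotone") <- TRUE
  out
}

#' Fit a strictly monotone parametric table
#'
#' Conditions a noisy Monte Carlo table with the physics of the arterial
#' dilation law: since the lumen diameter scales as `p^0.1023` and the
#' detected intensity responds (log-)linearly to the arterial cross
#' section over the working range, `log(intensity)` is regressed on
#' `p^0.1023`.  The fitted curve pools the statistics of all grid points
#' and is strictly monotone by construction, which a pointwise isotonic
#' fit of a noise-dominated table is not.
#'
#' @param table An [intensity_table()] with positive intensities.
#' @param pressures_out Output pressure grid (default: 1 mmHg steps over
#'   the input range).
#' @return An [intensity_table()] on `pressures_out`.
#' @export
fit_table <- function(table, pressures_out = NULL) {
  stopifnot(inherits(table, "intensity_table"))
  keep <- table$intensity > 0
  if (sum(keep) < 3)
    stop("too few positive intensities to fit; increase the photon budget")
  x <- table$pressure[keep]^0.1023
  y <- log(table$intensity[keep])
  wts <- if (all(is.finite(table$mc_se[keep])) && all(table$mc_se[keep] > 0))
    (table$intensity[keep] / table$mc_se[keep])^2 else NULL
  fit <- stats::lm(y ~ x, weights = wts)
  slope <- stats::coef(fit)[2]
  if (!is.finite(slope) || abs(slope) < 1e-12)
    stop("fitted table has no pressure trend; increase the photon budget")
  if (is.null(pressures_out))
    pressures_out <- seq(min(table$pressure), max(table$pressure), by = 1)
  pred <- stats::predict(fit,
                         newdata = data.frame(x = pressures_out^0.1023),
                         se.fit = TRUE)
  out <- intensity_table(pressures_out, exp(pred$fit),
                         mc_se = exp(pred$fit) * pred$se.fit,
                         wavelength_nm = attr(table, "wavelength_nm"),
                         mode = attr(table, "mode"),
                         provenance = c(attr(table, "provenance"),
                                        list(fitted = "log-linear in p^0.1023")))
  attr(out, "monotone") <- TRUE
  out
}

assert_monotone <- function(table) {
  inc <- !is.unsorted(table$intensity)
  dec <- !is.unsorted(rev(table$intensity))
  if (!inc && !dec)
    stop("intensity table is not monotone; apply monotonize() first")
  if (inc && dec) stop("intensity table is constant; cannot invert")
  if (inc) 1 else -1
}

#' Interpolate table intensity at a pressure
#'
#' Piecewise-linear interpolation of the table at arbitrary pressures.
#' Pressures outside the grid return `NA`.
#'
#' @param table An [intensity_table()].
#' @param pressure Pressure(s), mmHg.
#' @return Interpolated intensity (vector).
#' @export
interp_intensity <- function(table, pressure) {
  stopifnot(inherits(table, "intensity_table"))
  stats::approx(table$pressure, table$intensity, xout = pressure,
                ties = "ordered")$y
}

#' Invert a monotone intensity table back to pressure
#'
#' Piecewise-linear inverse interpolation: returns the pressure whose
#' table intensity equals the given value.  Intensities outside the table
#' range clamp to the nearest endpoint pressure and are flagged.  Within
#' pooled flats of a weakly monotone table the midpoint pressure of the
#' flat is returned (the inverse is not unique there).
#'
#' @param table A monotone [intensity_table()]; a non-monotone table is a
#'   contract error.
#' @param intensity Intensity value(s) on the table's scale.
#' @return Numeric pressure vector (mmHg) with attribute `out_of_range`
#'   (logical vector marking clamped values).
#' @export
invert_intensity <- function(table, intensity) {
  dir <- assert_monotone(table)
  xi <- dir * table$intensity
  yo <- table$pressure
  v <- dir * intensity
  lo <- min(xi); hi <- max(xi)
  oor <- v < lo | v > hi
  vc <- pmin(hi, pmax(lo, v))
  # collapse exact flats to their midpoint pressure, then linear inverse
  p <- stats::approx(xi, yo, xout = vc, ties = mean)$y
  attr(p, "out_of_range") <- oor
  p
}

#' @export
print.intensity_table <- function(x, ...) {
  cat(sprintf(
    "intensity_table: %d points, %g-%g mmHg, %s at %g nm%s\n",
    nrow(x), min(x$pressure), max(x$pressure), attr(x, "mode"),
    attr(x, "wavelength_nm"),
    if (isTRUE(attr(x, "monotone"))) ", monotone" else ""))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...", nrow(x) - 5, "more rows\n")
  invisible(x)
}

#' Write an intensity table to CSV with a JSON sidecar
#'
#' @param table An [intensity_table()].
#' @param path CSV output path; metadata goes to `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_intensity_table <- function(table, path) {
  stopifnot(inherits(table, "intensity_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  meta <- list(wavelength_nm = attr(table, "wavelength_nm"),
               mode = attr(table, "mode"),
               monotone = isTRUE(attr(table, "monotone")),
               provenance = attr(table, "provenance"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an intensity table written by [write_intensity_table()]
#'
#' @param path CSV path.
#' @return An [intensity_table()].
#' @export
read_intensity_table <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
          else list(wavelength_nm = NA_real_, mode = "transmission",
                    provenance = list())
  out <- intensity_table(df$pressure, df$intensity,
                         if ("mc_se" %in% names(df)) df$mc_se else NA_real_,
                         wavelength_nm = as.numeric(meta$wavelength_nm),
                         mode = meta$mode,
                         provenance = meta$provenance)
  out
}
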