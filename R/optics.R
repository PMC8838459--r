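# Wavelength-dependent bio-optical properties of the finger layers and the
# pressure-dependent digital artery.  Coefficients are in mm^-1, wavelengths
# in nm, pressures in mmHg, lengths in mm throughout the package.

# Per-layer defaults at 905 and 940 nm.  These printed constants are the
# authoritative layer properties; the mixture formulas below are exposed as
# utilities for user-defined compositions and do not overwrite them.
.finger_layers <- data.frame(
  layer = c("stratum_corneum", "epidermis", "papillary_dermis",
            "upper_blood_net_dermis", "reticular_dermis",
            "deep_blood_net_dermis", "fat", "muscle", "bone"),
  thickness = c(0.02, 0.25, 0.1, 0.08, 0.2, 0.3, 0.55, 1.5, 2),
  mu_a_905 = c(0.11350, 0.16825, 0.09631, 0.09864, 0.09824, 0.10118,
               0.0142, 0.031, 0.15),
  mu_a_940 = c(0.09745, 0.21397, 0.23308, 0.24202, 0.29906, 0.32549,
               0.0170, 0.0401, 0.0457),
  mu_s_905 = c(100, 45, 30, 35, 25, 30, 6.33, 1.83, 15.2),
  mu_s_940 = c(100, 45, 30, 35, 25, 30, 5.42, 5.81, 24.70),
  g = c(0.86, 0.8, 0.9, 0.95, 0.8, 0.95, 0.8, 0.5, 0.92),
  n = c(1.5, 1.34, 1.4, 1.39, 1.4, 1.38, 1.37, 1.37, 1.37),
  stringsAsFactors = FALSE
)

# Artery scattering properties (shared by lumen and wall) and whole-blood /
# vessel-wall absorption coefficients at the two supported wavelengths.
.artery_scatter <- list(mu_s = 4.85, g = 0.8, n = 1.39)
.blood_wall_mu_a <- data.frame(
  wavelength = c(905, 940),
  mu_blood = c(0.011160, 0.011778),
  mu_vw = c(0.014869, 0.009316)
)

# Water absorption at the two supported wavelengths (mm^-1), interpolated
# from standard pure-water absorption compilations; exposed as a default
# that callers of the mixture utilities may override.
.water_mu_a <- c("905" = 0.0080, "940" = 0.0290)

#' Baseline tissue absorption coefficient
#'
#' Absorption of bloodless, waterless background tissue, modeled as the
#' power law `7.84e7 * lambda^-3.255`.  Used as the residual term of the
#' volume-fraction mixture formulas.
#'
#' @param lambda_nm Wavelength in nanometres (> 0).
#' @return Absorption coefficient in mm^-1 (strictly decreasing in
#'   wavelength).
#' @examples
#' baseline_absorption(c(905, 940))
#' @export
baseline_absorption <- function(lambda_nm) {
  stopifnot(is.numeric(lambda_nm))
  if (any(lambda_nm <= 0)) stop("wavelength must be positive (nm)")
  7.84e7 * lambda_nm^-3.255
}

#' Melanin absorption coefficient
#'
#' Power-law melanin absorption `6.6e10 * lambda^-3.3`.
#'
#' @inheritParams baseline_absorption
#' @return Absorption coefficient in mm^-1.
#' @export
melanin_absorption <- function(lambda_nm) {
  stopifnot(is.numeric(lambda_nm))
  if (any(lambda_nm <= 0)) stop("wavelength must be positive (nm)")
  6.6e10 * lambda_nm^-3.3
}

#' Water absorption coefficient default
#'
#' Default pure-water absorption at the supported wavelengths (905, 940 nm).
#'
#' @inheritParams baseline_absorption
#' @return Absorption coefficient in mm^-1.
#' @export
water_absorption <- function(lambda_nm) {
  key <- as.character(lambda_nm)
  if (!all(key %in% names(.water_mu_a)))
    stop("no default water absorption at ", lambda_nm,
         " nm; supply mu_a_water explicitly")
  unname(.water_mu_a[key])
}

#' General volume-fraction absorption mixture
#'
#' Combines constituent absorption coefficients by their volume fractions,
#' with the baseline coefficient filling the remaining volume:
#' `sum(mu_a_i * V_i) + mu_a0 * (1 - sum(V_i))`.
#'
#' @param component_mu_a Numeric vector of constituent absorption
#'   coefficients (mm^-1).
#' @param volume_fractions Numeric vector of volume fractions in `[0, 1]`,
#'   same length as `component_mu_a`, summing to at most 1.
#' @param baseline_mu_a Baseline absorption coefficient (mm^-1).
#' @return Mixed absorption coefficient in mm^-1.
#' @export
composite_absorption <- function(component_mu_a, volume_fractions,
                                 baseline_mu_a) {
  if (length(component_mu_a) != length(volume_fractions))
    stop("component_mu_a and volume_fractions must have equal length")
  if (any(volume_fractions < 0 | volume_fractions > 1))
    stop("volume fractions must lie in [0, 1]")
  if (sum(volume_fractions) > 1 + 1e-12)
    stop("volume fractions must sum to at most 1")
  sum(component_mu_a * volume_fractions) +
    baseline_mu_a * (1 - sum(volume_fractions))
}

#' Epidermis absorption coefficient
#'
#' Melanin/water mixture for the epidermis:
#' `Vm * mu_a_mel + Vw * mu_a_water + (1 - Vm - Vw) * mu_a0`.
#'
#' @inheritParams baseline_absorption
#' @param v_melanin Melanin volume fraction (default 0.10).
#' @param v_water Water volume fraction (default 0.20).
#' @param mu_a_water Water absorption at `lambda_nm` in mm^-1; defaults to
#'   the packaged constant at 905/940 nm.
#' @return Absorption coefficient in mm^-1.
#' @export
epidermis_absorption <- function(lambda_nm, v_melanin = 0.10,
                                 v_water = 0.20,
                                 mu_a_water = water_absorption(lambda_nm)) {
  if (v_melanin < 0 || v_melanin > 1 || v_water < 0 || v_water > 1 ||
      v_melanin + v_water > 1)
    stop("melanin and water fractions must lie in [0, 1] and sum to at most 1")
  composite_absorption(
    c(melanin_absorption(lambda_nm), mu_a_water),
    c(v_melanin, v_water),
    baseline_absorption(lambda_nm)
  )
}

#' Stratum corneum absorption coefficient
#'
#' `[(0.1 - 0.3e-4 * lambda) + 0.125 * mu_a0(lambda)] * (1 - Vw) +
#' Vw * mu_a_water`.
#'
#' @inheritParams epidermis_absorption
#' @param v_water Water volume fraction (default 0.05).
#' @return Absorption coefficient in mm^-1.
#' @export
stratum_corneum_absorption <- function(lambda_nm, v_water = 0.05,
                                       mu_a_water = water_absorption(lambda_nm)) {
  if (v_water < 0 || v_water > 1) stop("v_water must lie in [0, 1]")
  dry <- (0.1 - 0.3e-4 * lambda_nm) + 0.125 * baseline_absorption(lambda_nm)
  dry * (1 - v_water) + v_water * mu_a_water
}

#' Arterial lumen diameter at a given pressure
#'
#' Empirical pressure-diameter relation for the digital artery,
#' `d = 0.8531 * p^0.1023` with `d` in mm and `p` in mmHg; strictly
#' increasing in pressure.
#'
#' @param pressure Arterial pressure in mmHg (> 0).
#' @return Lumen diameter in mm.
#' @examples
#' artery_diameter(c(42, 100, 200))
#' @export
artery_diameter <- function(pressure) {
  stopifnot(is.numeric(pressure))
  if (any(pressure <= 0)) stop("pressure must be positive (mmHg)")
  0.8531 * pressure^0.1023
}

#' Blood and vessel-wall volume fractions of the artery
#'
#' The artery is modeled as two coaxial cylinders of equal length: a blood
#' lumen of diameter `diameter` inside a wall annulus of thickness
#' `wall_thickness`.  Length cancels, so
#' `v_blood = (d/2)^2 / (d/2 + w)^2` and `v_vw = 1 - v_blood`.
#'
#' @param diameter Lumen diameter in mm (> 0).
#' @param wall_thickness Wall thickness in mm (>= 0, default 0.2).
#' @return Named list with `v_blood` and `v_vw` (summing to 1).
#' @export
artery_volume_fractions <- function(diameter, wall_thickness = 0.2) {
  if (any(diameter <= 0)) stop("diameter must be positive (mm)")
  if (any(wall_thickness < 0)) stop("wall_thickness must be non-negative (mm)")
  r <- diameter / 2
  v_blood <- r^2 / (r + wall_thickness)^2
  list(v_blood = v_blood, v_vw = 1 - v_blood)
}

#' Arterial absorption coefficient
#'
#' Volume-fraction mixture of whole-blood and vessel-wall absorption:
#' `v_blood * mu_blood(lambda) + v_vw * mu_vw(lambda)`.  Default blood and
#' wall coefficients are packaged for 905 and 940 nm; other wavelengths
#' require explicit coefficients.
#'
#' @inheritParams baseline_absorption
#' @param v_blood,v_vw Blood and wall volume fractions (must sum to 1).
#' @param mu_blood,mu_vw Whole-blood and vessel-wall absorption coefficients
#'   in mm^-1; defaults looked up for 905/940 nm.
#' @return Absorption coefficient in mm^-1.
#' @export
artery_absorption <- function(lambda_nm, v_blood, v_vw,
                              mu_blood = NULL, mu_vw = NULL) {
  if (abs(v_blood + v_vw - 1) > 1e-9)
    stop("v_blood + v_vw must equal 1")
  if (is.null(mu_blood) || is.null(mu_vw)) {
    row <- .blood_wall_mu_a[.blood_wall_mu_a$wavelength == lambda_nm, ]
    if (nrow(row) != 1L)
      stop("no packaged blood/wall absorption at ", lambda_nm,
           " nm; supply mu_blood and mu_vw")
    if (is.null(mu_blood)) mu_blood <- row$mu_blood
    if (is.null(mu_vw)) mu_vw <- row$mu_vw
  }
  v_blood * mu_blood + v_vw * mu_vw
}

#' Layer optical properties of the finger model
#'
#' Returns the per-layer absorption, scattering, anisotropy and refractive
#' index used by the voxel model at a supported wavelength, optionally with
#' user overrides.
#'
#' @param wavelength_nm 905 or 940.
#' @param overrides Optional named list: each element is itself a named list
#'   of property values (`mu_a`, `mu_s`, `g`, `n`) replacing the defaults of
#'   that layer, e.g. `list(epidermis = list(mu_a = 0.2))`.
#' @return A data frame with columns `layer`, `thickness`, `mu_a`, `mu_s`,
#'   `g`, `n`.
#' @export
finger_layer_properties <- function(wavelength_nm = 940, overrides = NULL) {
  if (!wavelength_nm %in% c(905, 940))
    stop("packaged layer properties exist only at 905 and 940 nm")
  wl <- as.character(wavelength_nm)
  out <- data.frame(
    layer = .finger_layers$layer,
    thickness = .finger_layers$thickness,
    mu_a = .finger_layers[[paste0("mu_a_", wl)]],
    mu_s = .finger_layers[[paste0("mu_s_", wl)]],
    g = .finger_layers$g,
    n = .finger_layers$n,
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      i <- match(nm, out$layer)
      if (is.na(i)) stop("unknown layer in overrides: ", nm)
      for (p in names(overrides[[nm]])) {
        if (!p %in% c("mu_a", "mu_s", "g", "n", "thickness"))
          stop("unknown property in overrides: ", p)
        out[[p]][i] <- overrides[[nm]][[p]]
      }
    }
  }
  validate_layer_properties(out)
  out
}

# shared sanity checks for a layer-property table
validate_layer_properties <- function(props) {
  stopifnot(all(props$mu_a >= 0), all(props$mu_s >= 0),
            all(props$g >= -1 & props$g <= 1), all(props$n >= 1),
            all(props$thickness > 0))
  invisible(props)
}
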