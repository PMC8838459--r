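# Monte Carlo photon transport: exported sampling/optics primitives (pure
# R, vectorized) and the simulation driver around the compiled voxel
# kernel.  The kernel mirrors the same formulas in C++.

#' Sample a photon step length
#'
#' Free-path sampling from the exponential attenuation law,
#' `l = -ln(xi) / (mu_a + mu_s)`.
#'
#' @param xi Uniform random draw(s) in (0, 1].
#' @param mu_a,mu_s Absorption and scattering coefficients, mm^-1.
#' @return Step length(s) in mm; `Inf` when `mu_a + mu_s` is zero
#'   (ballistic traversal).
#' @export
sample_step <- function(xi, mu_a, mu_s) {
  if (any(xi <= 0 | xi > 1)) stop("xi must lie in (0, 1]")
  if (any(mu_a < 0 | mu_s < 0)) stop("coefficients must be non-negative")
  len <- max(length(xi), length(mu_a), length(mu_s))
  xi <- rep_len(xi, len)
  mu_t <- rep_len(mu_a + mu_s, len)
  out <- numeric(len)
  zero <- mu_t == 0
  out[zero] <- Inf
  out[!zero] <- -log(xi[!zero]) / mu_t[!zero]
  out
}

#' Sample the cosine of the Henyey-Greenstein scattering angle
#'
#' Inverse-CDF sampling of the Henyey-Greenstein phase function.  The
#' isotropic branch (`g = 0`) returns `1 - 2 xi`; otherwise
#' `(1 + g^2 - ((1 - g^2) / (1 - g + 2 g xi))^2) / (2 g)`, clamped to
#' `[-1, 1]` against round-off.  The first moment of the sampled cosine
#' equals `g`.
#'
#' @param xi Uniform random draw(s) in `[0, 1]`.
#' @param g Scattering anisotropy, `|g| < 1`.
#' @return Sampled cosine(s) in `[-1, 1]`.
#' @export
sample_scatter_cos <- function(xi, g) {
  if (abs(g) >= 1) stop("anisotropy g must satisfy |g| < 1")
  if (g == 0) return(1 - 2 * xi)
  f <- (1 - g^2) / (1 - g + 2 * g * xi)
  pmin(1, pmax(-1, (1 + g^2 - f^2) / (2 * g)))
}

#' Rotate a direction by a sampled scattering angle
#'
#' Local-frame rotation of a unit direction vector by polar angle
#' `acos(cos_theta)` and azimuth `phi`.
#'
#' @param direction Unit 3-vector.
#' @param cos_theta Cosine of the polar scattering angle.
#' @param phi Azimuthal angle in `[0, 2*pi)`.
#' @return Unit 3-vector; its dot product with the input equals
#'   `cos_theta` up to round-off.
#' @export
spin_direction <- function(direction, cos_theta, phi) {
  stopifnot(length(direction) == 3)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9)
    stop("direction must be a unit vector")
  ux <- direction[1]; uy <- direction[2]; uz <- direction[3]
  st <- sqrt(max(0, 1 - cos_theta^2))
  cp <- cos(phi); sp <- sin(phi)
  if (abs(uz) > 0.999999) {
    out <- c(st * cp, st * sp, cos_theta * sign(uz))
  } else {
    den <- sqrt(1 - uz^2)
    out <- c(
      st * (ux * uz * cp - uy * sp) / den + ux * cos_theta,
      st * (uy * uz * cp + ux * sp) / den + uy * cos_theta,
      -den * st * cp + uz * cos_theta
    )
  }
  out / sqrt(sum(out^2))
}

#' Fresnel interaction at a refractive-index boundary
#'
#' Computes the unpolarized Fresnel reflectance for a packet hitting a
#' planar boundary and stochastically decides between specular reflection
#' and Snell refraction; beyond the critical angle the packet always
#' reflects.
#'
#' @param n1,n2 Refractive indices of the incident and far media (>= 1).
#' @param direction Incident unit direction.
#' @param surface_normal Unit normal of the boundary (orientation
#'   irrelevant).
#' @param xi Uniform draw in `[0, 1]` deciding the branch.
#' @return List with `action` (`"reflect"` or `"transmit"`),
#'   `reflectance`, and `direction` (the outgoing unit vector).
#' @export
fresnel_interaction <- function(n1, n2, direction, surface_normal, xi) {
  stopifnot(n1 >= 1, n2 >= 1, length(direction) == 3,
            length(surface_normal) == 3)
  nrm <- surface_normal / sqrt(sum(surface_normal^2))
  mu <- sum(direction * nrm)
  if (mu > 0) nrm <- -nrm else mu <- -mu  # normal now opposes travel
  cos_i <- mu
  if (n1 == n2) {
    return(list(action = "transmit", reflectance = 0, direction = direction))
  }
  sin_t2 <- (n1 / n2)^2 * (1 - cos_i^2)
  if (sin_t2 >= 1) {
    R <- 1
  } else {
    cos_t <- sqrt(1 - sin_t2)
    rs <- (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t)
    rp <- (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i)
    R <- (rs^2 + rp^2) / 2
  }
  if (xi < R) {
    out <- direction + 2 * cos_i * nrm
    list(action = "reflect", reflectance = R,
         direction = out / sqrt(sum(out^2)))
  } else {
    cos_t <- sqrt(1 - sin_t2)
    out <- (n1 / n2) * direction + ((n1 / n2) * cos_i - cos_t) * nrm
    list(action = "transmit", reflectance = R,
         direction = out / sqrt(sum(out^2)))
  }
}

#' Source specification
#'
#' Pencil beam entering the grid perpendicular to the entry face.
#'
#' @param x,y Entry position in mm; `NULL` centers the beam on the face.
#' @return Object of class `source_spec`.
#' @export
source_spec <- function(x = NULL, y = NULL) {
  structure(list(x = x, y = y), class = "source_spec")
}

#' Detector specification
#'
#' Square aperture on the entry (reflection) or exit (transmission) face
#' with full-hemisphere acceptance.
#'
#' @param mode `"transmission"` or `"reflection"`.
#' @param offset Lateral (x) offset of the aperture center from the
#'   source, mm; default 0.4 for reflection, 0 for transmission.
#' @param aperture Aperture side length in mm (default 1).
#' @return Object of class `detector_spec`.
#' @export
detector_spec <- function(mode = c("transmission", "reflection"),
                          offset = NULL, aperture = 1) {
  mode <- match.arg(mode)
  if (aperture <= 0) stop("aperture must be positive")
  if (is.null(offset)) offset <- if (mode == "reflection") 0.4 else 0
  structure(list(mode = mode, offset = offset, aperture = aperture),
            class = "detector_spec")
}

#' Run a voxel Monte Carlo simulation
#'
#' Propagates `n_photons` weighted packets from a pencil source through a
#' [build_voxel_model()] grid and tallies exit weights into reflected,
#' transmitted and lateral-escape bins, detector apertures, and a fluence
#' cross-section map (pathlength density, packet-weight x mm per voxel;
#' multiplying a voxel's fluence by its medium's `mu_a` gives the
#' absorbed-weight density).  Results are
#' reproducible for a given `seed`: each packet draws from its own
#' counter-derived random stream.
#'
#' @param grid A `voxel_grid`.
#' @param source A [source_spec()] (default: centered pencil beam).
#' @param detectors A [detector_spec()] or list of them (default: one
#'   transmission and one reflection detector).
#' @param n_photons Number of packets to launch (>= 1).
#' @param seed Integer random seed.
#' @param roulette_threshold Weight below which Russian roulette is
#'   played (default 1e-4).
#' @param roulette_survive Survival probability of the roulette
#'   (default 0.1).
#' @param max_events Per-packet event cap guaranteeing termination
#'   (default 1e6); capped packets are reported and their weight is
#'   tallied as absorbed.
#' @param fluence Tally the fluence cross-section map (default `TRUE`).
#' @param n_outside Refractive index of the external medium (default 1).
#' @return Object of class `simulation_result` with per-photon-normalized
#'   tallies, detector intensities with Monte Carlo standard errors, the
#'   fluence map, and provenance (seed, photon count).  Fails if global
#'   weight conservation is violated beyond 1e-9 relative.
#' @export
run_simulation <- function(grid, source = source_spec(),
                           detectors = NULL, n_photons = 10000, seed = 1,
                           roulette_threshold = 1e-4,
                           roulette_survive = 0.1, max_events = 1e6,
                           fluence = TRUE, n_outside = 1.0) {
  stopifnot(inherits(grid, "voxel_grid"), n_photons >= 1)
  if (is.null(detectors))
    detectors <- list(detector_spec("transmission"),
                      detector_spec("reflection"))
  if (inherits(detectors, "detector_spec")) detectors <- list(detectors)

  nx <- grid$dims[["nx"]]; ny <- grid$ny
  sx <- if (is.null(source$x)) nx * grid$pitch / 2 else source$x
  sy <- if (is.null(source$y)) ny * grid$pitch / 2 else source$y
  if (sx < 0 || sx > nx * grid$pitch || sy < 0 || sy > ny * grid$pitch)
    stop("source entry position lies outside the grid face")

  det_face <- vapply(detectors, function(d)
    if (d$mode == "transmission") 1L else 0L, integer(1))
  det_cx <- vapply(detectors, function(d) sx + d$offset, numeric(1))
  det_cy <- rep(sy, length(detectors))
  det_half <- vapply(detectors, function(d) d$aperture / 2, numeric(1))

  # property matrix ordered by label id
  labs <- sort(grid$props$label)
  pm <- as.matrix(grid$props[match(labs, grid$props$label),
                             c("mu_a", "mu_s", "g", "n")])
  if (!identical(labs, seq_along(labs)))
    stop("voxel labels must be consecutive integers starting at 1")

  res <- .mc_run_cpp(grid$label, ny, grid$pitch, pm, sx, sy,
                     det_face, det_cx, det_cy, det_half,
                     as.integer(n_photons), as.numeric(seed),
                     roulette_threshold, roulette_survive,
                     max_events, fluence, n_outside)

  total <- res$reflected + res$transmitted + res$absorbed + res$lateral
  cons_err <- abs(total - n_photons) / n_photons
  if (cons_err > 1e-9)
    stop(sprintf("weight conservation violated: relative error %.3g",
                 cons_err))

  se_of <- function(sum_w, sum_w2) {
    v <- pmax(0, sum_w2 / n_photons - (sum_w / n_photons)^2)
    sqrt(v / n_photons)
  }
  out <- list(
    n_photons = n_photons, seed = seed,
    reflected = res$reflected / n_photons,
    transmitted = res$transmitted / n_photons,
    absorbed = res$absorbed / n_photons,
    lateral = res$lateral / n_photons,
    reflected_se = se_of(res$reflected, res$reflected_sq),
    transmitted_se = se_of(res$transmitted, res$transmitted_sq),
    detected = res$detected / n_photons,
    detected_se = se_of(res$detected, res$detected_sq),
    detectors = detectors,
    fluence = if (fluence) res$fluence else NULL,
    n_capped = res$n_capped,
    capped_fraction = res$n_capped / n_photons,
    mean_events = res$mean_events,
    conservation_error = cons_err,
    wavelength_nm = grid$wavelength_nm,
    pressure = grid$artery$pressure
  )
  class(out) <- "simulation_result"
  out
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation_result: %g photons, seed %g\n",
              x$n_photons, x$seed))
  cat(sprintf("  R = %.5f  T = %.5f  A = %.5f  lateral = %.5f\n",
              x$reflected, x$transmitted, x$absorbed, x$lateral))
  for (i in seq_along(x$detected))
    cat(sprintf("  detector %d (%s): %.6g +/- %.2g\n", i,
                x$detectors[[i]]$mode, x$detected[i], x$detected_se[i]))
  invisible(x)
}

#' Absorbed-weight cross-section map
#'
#' Converts the fluence (pathlength-density) map of a simulation into the
#' absorbed-weight density map by multiplying each voxel's fluence with
#' the absorption coefficient of its medium.
#'
#' @param result A `simulation_result` run with `fluence = TRUE`.
#' @param grid The `voxel_grid` the simulation was run on.
#' @return Matrix (x by z) of absorbed weight per voxel.
#' @export
absorbed_map <- function(result, grid) {
  stopifnot(inherits(result, "simulation_result"),
            inherits(grid, "voxel_grid"))
  if (is.null(result$fluence)) stop("simulation was run with fluence = FALSE")
  mu_a <- grid$props$mu_a[match(as.vector(grid$label), grid$props$label)]
  result$fluence * matrix(mu_a, nrow = nrow(grid$label))
}

#' Detected intensity of a simulation result
#'
#' Convenience accessor for the per-photon-normalized detected weight of
#' the detector operating in the requested mode.
#'
#' @param result A `simulation_result`.
#' @param mode `"transmission"` or `"reflection"`.
#' @return Named list with `intensity` and `mc_se`.
#' @export
detected_intensity <- function(result,
                               mode = c("transmission", "reflection")) {
  mode <- match.arg(mode)
  i <- which(vapply(result$detectors, function(d) d$mode, "") == mode)
  if (length(i) == 0) stop("no detector in mode ", mode)
  list(intensity = result$detected[i[1]], mc_se = result$detected_se[i[1]])
}
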