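# Test helpers: an independent layered (non-voxel) Monte Carlo oracle,
# closed-form truncated-normal moments, and small fixture builders.

# Straightforward layered-slab Monte Carlo, vectorized over packets.
# Matched refractive indices everywhere (no Fresnel), memoryless step
# resampling at layer boundaries (statistically exact for exponential
# steps).  Written independently of the package's voxel kernel so the two
# can be cross-checked.
layered_mc_oracle <- function(layers, n_photons = 1e4, seed = 1,
                              w_min = 1e-4, p_survive = 0.1,
                              max_iter = 20000) {
  set.seed(seed)
  zb <- c(0, cumsum(layers$thickness))
  nl <- nrow(layers)
  n <- n_photons
  z <- rep(0, n); li <- rep(1L, n)
  ux <- uy <- rep(0, n); uz <- rep(1, n)
  w <- rep(1, n)
  alive <- rep(TRUE, n)
  refl <- trans <- absb <- rep(0, n)
  it <- 0
  while (any(alive) && it < max_iter) {
    it <- it + 1
    idx <- which(alive)
    mu_a <- layers$mu_a[li[idx]]
    mu_s <- layers$mu_s[li[idx]]
    g <- layers$g[li[idx]]
    mu_t <- mu_a + mu_s
    s_geo <- -log(runif(length(idx))) / mu_t
    zt <- ifelse(uz[idx] > 0, zb[li[idx] + 1L], zb[li[idx]])
    db <- ifelse(uz[idx] == 0, Inf, (zt - z[idx]) / uz[idx])
    cross <- s_geo > db

    # boundary crossings
    ci <- idx[cross]
    if (length(ci) > 0) {
      up <- uz[ci] > 0
      z[ci] <- ifelse(up, zb[li[ci] + 1L], zb[li[ci]])
      li[ci] <- li[ci] + ifelse(up, 1L, -1L)
      out_top <- li[ci] < 1L
      out_bot <- li[ci] > nl
      exit <- out_top | out_bot
      if (any(exit)) {
        ei <- ci[exit]
        refl[ei] <- refl[ei] + ifelse(out_top[exit], w[ei], 0)
        trans[ei] <- trans[ei] + ifelse(out_bot[exit], w[ei], 0)
        alive[ei] <- FALSE
      }
    }

    # interactions
    ii <- idx[!cross]
    if (length(ii) > 0) {
      sg <- s_geo[!cross]
      z[ii] <- z[ii] + uz[ii] * sg
      ma <- layers$mu_a[li[ii]]; mt <- ma + layers$mu_s[li[ii]]
      dw <- w[ii] * ma / mt
      absb[ii] <- absb[ii] + dw
      w[ii] <- w[ii] - dw
      # roulette
      low <- w[ii] < w_min
      if (any(low)) {
        lo <- ii[low]
        u <- runif(length(lo))
        surv <- u < p_survive
        absb[lo[surv]] <- absb[lo[surv]] -
          w[lo[surv]] * (1 / p_survive - 1)
        w[lo[surv]] <- w[lo[surv]] / p_survive
        absb[lo[!surv]] <- absb[lo[!surv]] + w[lo[!surv]]
        alive[lo[!surv]] <- FALSE
      }
      live <- ii[alive[ii]]
      if (length(live) > 0) {
        gg <- layers$g[li[live]]
        xi <- runif(length(live))
        ct <- ifelse(gg == 0, 1 - 2 * xi, {
          f <- (1 - gg^2) / (1 - gg + 2 * gg * xi)
          pmin(1, pmax(-1, (1 + gg^2 - f^2) / (2 * gg)))
        })
        st <- sqrt(pmax(0, 1 - ct^2))
        phi <- 2 * pi * runif(length(live))
        cp <- cos(phi); sp <- sin(phi)
        u0 <- ux[live]; v0 <- uy[live]; w0 <- uz[live]
        near_pole <- abs(w0) > 0.999999
        den <- sqrt(pmax(1e-30, 1 - w0^2))
        nux <- ifelse(near_pole, st * cp,
                      st * (u0 * w0 * cp - v0 * sp) / den + u0 * ct)
        nuy <- ifelse(near_pole, st * sp,
                      st * (v0 * w0 * cp + u0 * sp) / den + v0 * ct)
        nuz <- ifelse(near_pole, ct * sign(w0), -den * st * cp + w0 * ct)
        nrm <- sqrt(nux^2 + nuy^2 + nuz^2)
        ux[live] <- nux / nrm; uy[live] <- nuy / nrm; uz[live] <- nuz / nrm
      }
    }
  }
  list(
    R = mean(refl), T = mean(trans), A = mean(absb),
    se_R = sd(refl) / sqrt(n), se_T = sd(trans) / sqrt(n)
  )
}

# closed-form mean of a normal truncated to [a, b]
truncnorm_mean <- function(mean, sd, min, max) {
  a <- (min - mean) / sd
  b <- (max - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# strictly monotone analytic intensity table over the working range
analytic_table <- function(p = 42:200, rate = 0.005) {
  intensity_table(p, 1e-4 * exp(rate * p), mc_se = 1e-9,
                  wavelength_nm = 940, mode = "transmission")
}

# uniform or layered verification slab grid (no artery)
slab_grid <- function(layers, pitch = 0.25, lateral = 60) {
  geom <- finger_geometry(voxel_pitch = pitch, lateral_extent = lateral,
                          layer_stack = layers, symmetric = FALSE,
                          artery = FALSE)
  build_voxel_model(geom, wavelength_nm = 940)
}

# synthetic two-wave beat train with known peak locations/amplitudes
synthetic_beat_train <- function(bpm = 72, duration = 60, fs = 100,
                                 amp = 1, dicrotic = 0.3) {
  period <- 60 / bpm
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  ph <- (t %% period) / period
  x <- amp * exp(-(ph - 0.3)^2 / (2 * 0.05^2)) +
    dicrotic * amp * exp(-(ph - 0.6)^2 / (2 * 0.08^2))
  x
}
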