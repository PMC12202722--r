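#' Spatial ledger of non-renewable hyperpolarized magnetization
#'
#' Hyperpolarized 13C magnetization is a fixed, non-renewable pool: every RF
#' pulse consumes part of it and T1 decay removes the rest. The grid tracks
#' the longitudinal magnetization Mz (normalized to the initial polarization)
#' over an axis-aligned bounding box so that a multi-voxel acquisition can be
#' budgeted shot by shot.
#'
#' @param xlim,ylim,zlim Length-2 extents of the bounding box in mm.
#' @param resolution_mm Isotropic grid step in mm (default 0.5).
#' @param t1_s Intrinsic longitudinal relaxation time in s.
#' @param mz0 Initial Mz (default 1 everywhere).
#' @return list of class `magnetization_grid`: coordinate vectors `x`, `y`,
#'   `z`, array `mz`, `time_s`, `t1_s`.
#' @export
magnetization_grid <- function(xlim, ylim, zlim, resolution_mm = 0.5,
                               t1_s = Inf, mz0 = 1) {
  ax <- function(lim) seq(lim[1] + resolution_mm / 2, lim[2], by = resolution_mm)
  x <- ax(xlim); y <- ax(ylim); z <- ax(zlim)
  structure(list(x = x, y = y, z = z,
                 mz = array(mz0, dim = c(length(x), length(y), length(z))),
                 time_s = 0, t1_s = t1_s),
            class = "magnetization_grid")
}

grid_axis <- function(grid, axis) grid[[axis]]

# index mask of grid cells whose center lies in [min, max] on `axis`
slab_mask <- function(grid, axis, lo, hi) {
  v <- grid_axis(grid, axis)
  v >= lo & v <= hi
}

# per-cell multiplier along one axis expanded to the full array
axis_field <- function(grid, axis, values) {
  d <- dim(grid$mz)
  switch(axis,
         x = array(values, dim = d),
         y = aperm(array(values, dim = d[c(2, 1, 3)]), c(2, 1, 3)),
         z = aperm(array(values, dim = d[c(3, 1, 2)]), c(2, 3, 1)))
}

# normalized flip response p(r) along the slab axis from a Bloch profile:
# local flip alpha(r) = atan2(|Mxy|, Mz), normalized by the nominal flip
profile_flip_fraction <- function(profile, flip_deg) {
  alpha <- atan2(profile$mxy, profile$mz)
  alpha / (flip_deg * pi / 180)
}

#' Apply a slice-selective excitation to the ledger
#'
#' Inside the excitation slab, `Mz <- Mz * cos(theta * p(r))` where `p(r)` is
#' the normalized spatial flip response: 1 inside / 0 outside the slab for an
#' ideal profile, or interpolated from a Bloch [slice_profile()] centered on
#' the slab. The excited transverse component is read out and then destroyed
#' (crushers/decay), so only the cosine-projected longitudinal pool survives.
#'
#' @param grid A [magnetization_grid()].
#' @param axis Slab axis, `"x"`, `"y"` or `"z"`.
#' @param range_mm Length-2 slab extent in mm.
#' @param flip_deg Nominal flip angle in degrees, in (0, 180].
#' @param profile Optional `bloch_profile` (positions relative to the slab
#'   center); `NULL` uses the ideal boxcar response.
#' @return The updated grid.
#' @export
apply_excitation <- function(grid, axis, range_mm, flip_deg, profile = NULL) {
  if (flip_deg <= 0 || flip_deg > 180) stop_invalid("flip_deg must be in (0, 180]")
  theta <- flip_deg * pi / 180
  v <- grid_axis(grid, axis)
  if (range_mm[1] > max(v) || range_mm[2] < min(v)) {
    warning("slab lies outside the grid; no-op")
    return(grid)
  }
  p <- if (is.null(profile)) {
    as.numeric(slab_mask(grid, axis, range_mm[1], range_mm[2]))
  } else {
    ctr <- mean(range_mm)
    frac <- profile_flip_fraction(profile, flip_deg = attr(profile, "flip_deg"))
    stats::approx(profile$position_mm + ctr, frac, xout = v,
                  yleft = 0, yright = 0)$y
  }
  grid$mz <- grid$mz * axis_field(grid, axis, cos(theta * p))
  grid
}

#' Apply a slice-selective refocusing event to the ledger
#'
#' A refocusing event acts on the longitudinal pool as an imperfect
#' inversion: `Mz <- -(2 q(r) - 1) * Mz` inside the slab, with inversion
#' efficiency `q = 1` for a perfect inversion and `q = 0.5` for full
#' saturation. For semi-LASER the per-axis AFP pair is folded into a single
#' event with its net efficiency. Transverse magnetization created outside
#' the voxel is assumed fully crushed and lost.
#'
#' @param grid A [magnetization_grid()].
#' @param axis Slab axis.
#' @param range_mm Length-2 slab extent in mm.
#' @param q Scalar inversion efficiency in `[0, 1]`, or a `bloch_profile`
#'   from which `q(r) = (1 - Mz_profile) / 2` is interpolated (positions
#'   relative to the slab center).
#' @return The updated grid.
#' @export
apply_refocusing <- function(grid, axis, range_mm, q = 0.97) {
  v <- grid_axis(grid, axis)
  if (inherits(q, "bloch_profile")) {
    ctr <- mean(range_mm)
    qv <- stats::approx(q$position_mm + ctr, (1 - q$mz) / 2, xout = v,
                        yleft = 0, yright = 0)$y
    qv <- pmin(pmax(qv, 0), 1)
    mult <- -(2 * qv - 1)
  } else {
    if (q < 0 || q > 1) stop_invalid("q must be in [0, 1]")
    mult <- ifelse(slab_mask(grid, axis, range_mm[1], range_mm[2]),
                   -(2 * q - 1), 1)
  }
  grid$mz <- grid$mz * axis_field(grid, axis, mult)
  grid
}

#' Mono-exponential T1 relaxation of the ledger
#'
#' For a non-renewable hyperpolarized pool there is no recovery toward
#' thermal equilibrium (which is negligible on this scale); Mz simply decays:
#' `Mz <- Mz * exp(-dt / T1)`.
#'
#' @param grid A [magnetization_grid()].
#' @param dt_s Elapsed time in s (>= 0).
#' @return The updated grid with `time_s` advanced.
#' @export
relax <- function(grid, dt_s) {
  if (dt_s < 0) stop_invalid("dt_s must be >= 0")
  if (is.finite(grid$t1_s)) grid$mz <- grid$mz * exp(-dt_s / grid$t1_s)
  grid$time_s <- grid$time_s + dt_s
  grid
}

# mean Mz over the voxel box
voxel_mean_mz <- function(grid, voxel) {
  mx <- slab_mask(grid, "x", voxel$x - voxel$dx / 2, voxel$x + voxel$dx / 2)
  my <- slab_mask(grid, "y", voxel$y - voxel$dy / 2, voxel$y + voxel$dy / 2)
  mz <- slab_mask(grid, "z", voxel$z - voxel$dz / 2, voxel$z + voxel$dz / 2)
  if (!any(mx) || !any(my) || !any(mz)) return(NA_real_)
  mean(grid$mz[mx, my, mz])
}

#' Simulate a multi-voxel acquisition on the magnetization ledger
#'
#' Plays the plan in acquisition order. Per voxel and TR: the available
#' in-voxel magnetization is read (mean Mz over the voxel box), the recorded
#' signal is `available * sin(flip)`, then the excitation slab and the two
#' refocusing slabs are applied to the ledger and the pool relaxes for one TR.
#' An optional final non-selective 90-degree probe reports the remaining
#' magnetization fraction: total |Mz| at the end over total at the start
#' (residually inverted regions still hold usable polarization, so the
#' ledger counts magnitude).
#'
#' @param plan A [voxel_plan()].
#' @param grid A [magnetization_grid()] covering the plan.
#' @param flip_deg Excitation flip angle in degrees.
#' @param tr_ms Repetition time in ms.
#' @param q Inversion efficiency of one refocusing event (scalar in `[0, 1]`
#'   or `bloch_profile`); defaults 0.97 for adiabatic (semi-LASER) and 0.80
#'   for amplitude-modulated (PRESS) refocusing via `refocusing`.
#' @param refocusing `"afp"` or `"slr"`; sets the default `q`.
#' @param roles Role-to-axis assignment, as in [slabs_of()].
#' @param n_repeats Number of passes over the plan (dynamic acquisitions).
#' @param exc_profile Optional excitation `bloch_profile` (else ideal).
#' @param probe_after Include the remaining-magnetization probe (default TRUE).
#' @return list of class `acquisition_record`: `record` (data.frame with
#'   `shot`, `label`, `time_s`, `available`, `signal`), `remaining` fraction,
#'   and the final `grid`.
#' @export
simulate_acquisition <- function(plan, grid, flip_deg = 90, tr_ms = 1000,
                                 q = NULL, refocusing = c("afp", "slr"),
                                 roles = default_roles(), n_repeats = 1,
                                 exc_profile = NULL, probe_after = TRUE) {
  refocusing <- match.arg(refocusing)
  if (is.null(q)) q <- if (refocusing == "afp") 0.97 else 0.80
  total0 <- sum(abs(grid$mz))
  rec <- list()
  shot <- 0L
  if (nrow(plan) > 0) plan <- plan[order(plan$order), ]
  for (rep_i in seq_len(n_repeats)) {
    for (v in seq_len(nrow(plan))) {
      vox <- plan[v, ]
      shot <- shot + 1L
      avail <- voxel_mean_mz(grid, vox)
      rec[[shot]] <- data.frame(shot = shot, label = vox$label,
                                time_s = grid$time_s,
                                available = avail,
                                signal = avail * sin(flip_deg * pi / 180))
      slabs <- slabs_of(vox, roles)
      ex <- slabs[slabs$role == "exc", ]
      grid <- apply_excitation(grid, ex$axis, c(ex$min, ex$max), flip_deg,
                               profile = exc_profile)
      for (rr in c("ref1", "ref2")) {
        sl <- slabs[slabs$role == rr, ]
        grid <- apply_refocusing(grid, sl$axis, c(sl$min, sl$max), q = q)
      }
      grid <- relax(grid, tr_ms / 1000)
    }
  }
  record <- if (length(rec)) do.call(rbind, rec) else
    data.frame(shot = integer(), label = character(), time_s = numeric(),
               available = numeric(), signal = numeric())
  remaining <- if (probe_after) sum(abs(grid$mz)) / total0 else NA_real_
  structure(list(record = record, remaining = remaining, grid = grid),
            class = "acquisition_record")
}

#' Effective T1 of a hyperpolarized signal time series
#'
#' Fits `S(t) = S0 * exp(-t / T1eff)` by nonlinear least squares (seeded by a
#' log-linear fit). Under repeated excitation at flip theta every TR the
#' effective rate is `1/T1eff = 1/T1 - ln(cos theta) / TR`, always faster
#' than the intrinsic decay.
#'
#' @param time_s Time points in s (or an `acquisition_record` / data.frame
#'   with `time_s` and `signal` columns).
#' @param signal Positive signal values.
#' @return Fitted `t1eff_s` (list with `t1eff_s`, `s0`, `fit`).
#' @export
effective_t1 <- function(time_s, signal = NULL) {
  if (inherits(time_s, "acquisition_record")) time_s <- time_s$record
  if (is.data.frame(time_s)) {
    signal <- time_s$signal
    time_s <- time_s$time_s
  }
  if (length(time_s) < 3) stop_invalid("need at least 3 time points")
  if (any(signal <= 0)) stop_invalid("signals must be positive")
  lf <- stats::lm(log(signal) ~ time_s)
  slope <- stats::coef(lf)[[2]]
  if (slope >= 0)
    stop(structure(class = c("hpmrsim_fit_failure", "error", "condition"),
                   list(message = "series is not decaying; cannot fit an effective T1",
                        call = sys.call())))
  s0_0 <- exp(stats::coef(lf)[[1]])
  t1_0 <- -1 / slope
  rss0 <- sum((signal - s0_0 * exp(-time_s / t1_0))^2)
  if (rss0 < 1e-20 * sum(signal^2)) {
    # log-linear seed already exact (noise-free series); nls cannot improve
    return(list(t1eff_s = t1_0, s0 = s0_0, fit = lf))
  }
  fit <- stats::nls(signal ~ s0 * exp(-time_s / t1),
                    start = list(s0 = s0_0, t1 = t1_0),
                    control = stats::nls.control(maxiter = 200, warnOnly = TRUE))
  co <- stats::coef(fit)
  list(t1eff_s = unname(co["t1"]), s0 = unname(co["s0"]), fit = fit)
}
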