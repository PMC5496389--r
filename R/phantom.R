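# Digital LV short-axis phantom with known ground truth.
#
# The phantom is an annular myocardium (epicardial disc minus endocardial
# disc) on every slice, with an anteroseptal (LAD-territory) lesion built from
# up to four nested components: an edema shell (elevated T2), a hemorrhagic
# core (depressed T2*, mildly depressed T2), a hyperenhancing infarct (short
# effective T1 on LGE) and a hypoenhanced MVO core. Which components exist is
# dictated by the experimental arm being emulated:
#
#   +HEM   hemorrhage + edema, no infarct, no MVO
#   I-HEM  infarct + edema, no hemorrhage, no MVO
#   I+HEM  infarct + edema + hemorrhage (+ optional MVO)
#
# Geometry is deterministic (voxel centers tested against the analytic
# annulus/sector); only the signal noise is random.

ARMS <- c("healthy", "+HEM", "I-HEM", "I+HEM")

# Arm geometry defaults: angular width (deg), transmural fraction of the wall,
# slices spanned (of 10), and the core fractions. Chosen so the lesion burden
# ranks +HEM < I-HEM < I+HEM as percent of LV myocardium, mirroring the
# qualitative pattern of the three experimental groups.
arm_defaults <- function(arm, n_slices) {
  mid <- (n_slices + 1) / 2
  span <- function(k) {
    lo <- max(1L, floor(mid - k / 2) + 1L)
    seq.int(lo, min(n_slices, lo + k - 1L))
  }
  switch(arm,
    "healthy" = list(
      sector_width_deg = 0, transmurality = 0, lesion_slices = integer(),
      hemorrhage_fraction = 0, mvo_fraction = 0
    ),
    "+HEM" = list(
      sector_width_deg = 60, transmurality = 0.50, lesion_slices = span(4L),
      hemorrhage_fraction = 0.25, mvo_fraction = 0
    ),
    "I-HEM" = list(
      sector_width_deg = 75, transmurality = 0.65, lesion_slices = span(5L),
      hemorrhage_fraction = 0, mvo_fraction = 0
    ),
    "I+HEM" = list(
      sector_width_deg = 100, transmurality = 0.85, lesion_slices = span(7L),
      hemorrhage_fraction = 0.12, mvo_fraction = 0.2
    )
  )
}

#' Phantom specification
#'
#' Declares the grid, LV geometry, lesion layout, tissue parameters, noise
#' model and cine volumes of one synthetic subject. Defaults describe a 3T
#' porcine study: remote myocardial T2 38 ms and T2* 35 ms; the edema shell T2
#' is elevated by roughly 19% (+HEM), 20% (I-HEM) or 35% (I+HEM) over remote;
#' the hemorrhagic core T2* is 12 ms (about half of remote, and below the
#' 20 ms detection criterion) with T2 depressed to 25 ms so the core reads
#' hypointense on T2 maps as iron products make it in vivo.
#'
#' @param arm `"healthy"`, `"+HEM"`, `"I-HEM"` or `"I+HEM"`.
#' @param matrix in-plane matrix `(nx, ny)`.
#' @param n_slices number of short-axis slices.
#' @param voxel_size `(dx, dy, dz)` mm.
#' @param center LV axis position in voxel units `(row, col)`; defaults to the
#'   grid center.
#' @param r_endo_mm,r_epi_mm endocardial/epicardial radii (mm).
#' @param sector_center_deg lesion sector center; 120 degrees places it
#'   anteroseptally under the package's angle convention (degrees
#'   counter-clockwise from the +column axis).
#' @param sector_width_deg,transmurality,lesion_slices lesion extent; `NULL`
#'   takes the arm default.
#' @param hemorrhage_fraction fraction of edema voxels forming the hemorrhagic
#'   core (hemorrhagic arms only).
#' @param mvo_fraction fraction of infarct voxels forming the MVO core
#'   (I+HEM only; 0 disables MVO).
#' @param tissue named list overriding any of: `remote_t2`, `remote_t2star`,
#'   `edema_t2`, `edema_t2star` (T2* of the injured territory; depressed to
#'   25 ms in hemorrhagic arms to model diffusely scattered iron outside the
#'   frank core), `hemorrhage_t2star`, `hemorrhage_t2`, `amplitude`,
#'   `t1_remote`, `t1_infarct`, `t1_mvo` (ms; amplitude in arbitrary signal
#'   units).
#' @param noise list with `model` (`"rician"`, `"gaussian"`, `"none"`) and
#'   `snr` (remote amplitude / noise sigma).
#' @param seed integer seed for signal noise.
#' @param cine list with `edv_ml`, `esv_ml`, `n_phases`.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(arm = "I+HEM",
                         matrix = c(128L, 128L),
                         n_slices = 10L,
                         voxel_size = c(1.9, 1.9, 5),
                         center = NULL,
                         r_endo_mm = 19,
                         r_epi_mm = 30,
                         sector_center_deg = 120,
                         sector_width_deg = NULL,
                         transmurality = NULL,
                         lesion_slices = NULL,
                         hemorrhage_fraction = NULL,
                         mvo_fraction = NULL,
                         tissue = list(),
                         noise = list(model = "rician", snr = 20),
                         seed = 1L,
                         cine = list(edv_ml = 65, esv_ml = 29, n_phases = 20L)) {
  arm <- match.arg(arm, ARMS)
  ad <- arm_defaults(arm, n_slices)
  sector_width_deg <- sector_width_deg %||% ad$sector_width_deg
  transmurality <- transmurality %||% ad$transmurality
  lesion_slices <- lesion_slices %||% ad$lesion_slices
  hemorrhage_fraction <- hemorrhage_fraction %||% ad$hemorrhage_fraction
  mvo_fraction <- mvo_fraction %||% ad$mvo_fraction

  ts <- utils::modifyList(list(
    remote_t2 = 38, remote_t2star = 35,
    hemorrhage_t2star = 12, hemorrhage_t2 = 25,
    amplitude = 100,
    t1_remote = 280 / log(2), t1_infarct = 150, t1_mvo = 520
  ), tissue)
  if (is.null(ts$edema_t2)) {
    # arm defaults express the observed percent elevation over remote
    ts$edema_t2 <- ts$remote_t2 * switch(arm,
      "healthy" = 1, "+HEM" = 1.19, "I-HEM" = 1.20, "I+HEM" = 1.35
    )
  }
  if (is.null(ts$edema_t2star)) {
    # hemorrhagic arms carry diffusely scattered iron across the injured
    # territory, mildly depressing T2* outside the frank core
    ts$edema_t2star <- if (arm %in% c("+HEM", "I+HEM")) 25 else ts$remote_t2star
  }

  # arm consistency rules
  if (arm %in% c("healthy", "I-HEM") && hemorrhage_fraction > 0) {
    cmrtc_stop(sprintf("arm %s excludes a hemorrhagic core", arm), "cmrtc_config_error")
  }
  if (arm != "I+HEM" && mvo_fraction > 0) {
    cmrtc_stop(sprintf("arm %s excludes MVO (only I+HEM may have it)", arm),
      "cmrtc_config_error")
  }
  if (arm %in% c("+HEM", "I+HEM") && hemorrhage_fraction <= 0) {
    cmrtc_stop(sprintf("arm %s requires a hemorrhagic core", arm), "cmrtc_config_error")
  }
  if (ts$edema_t2 < ts$remote_t2) {
    cmrtc_stop("edema T2 must be >= remote T2", "cmrtc_config_error")
  }
  if (arm %in% c("+HEM", "I+HEM") &&
    !(ts$hemorrhage_t2star < 20 && 20 <= ts$remote_t2star)) {
    cmrtc_stop("need hemorrhage T2* < 20 ms <= remote T2*", "cmrtc_config_error")
  }
  if (sector_center_deg < 0 || sector_center_deg >= 360) {
    cmrtc_stop("sector_center_deg must lie in [0, 360)", "cmrtc_config_error")
  }
  if (r_epi_mm <= r_endo_mm || r_endo_mm <= 0) {
    cmrtc_stop("need 0 < r_endo_mm < r_epi_mm", "cmrtc_config_error")
  }
  noise$model <- match.arg(noise$model, c("rician", "gaussian", "none"))
  if (noise$model != "none" && (is.null(noise$snr) || noise$snr <= 0)) {
    cmrtc_stop("noise model needs a positive snr", "cmrtc_config_error")
  }
  if (!is.null(cine$edv_ml) && !is.null(cine$esv_ml) &&
    !(cine$edv_ml > cine$esv_ml && cine$esv_ml > 0)) {
    cmrtc_stop("cine requires EDV > ESV > 0", "cmrtc_config_error")
  }

  structure(
    list(
      arm = arm, matrix = as.integer(matrix), n_slices = as.integer(n_slices),
      voxel_size = as.numeric(voxel_size),
      center = center %||% ((as.numeric(matrix) + 1) / 2),
      r_endo_mm = r_endo_mm, r_epi_mm = r_epi_mm,
      sector_center_deg = sector_center_deg,
      sector_width_deg = sector_width_deg,
      transmurality = transmurality,
      lesion_slices = as.integer(lesion_slices),
      hemorrhage_fraction = hemorrhage_fraction,
      mvo_fraction = mvo_fraction,
      tissue = ts, noise = noise, seed = as.integer(seed), cine = cine
    ),
    class = "phantom_spec"
  )
}

# Morphological 6-erosion: voxels whose six axial neighbors all lie inside
# the mask (volume-edge voxels drop out).
erode6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift_ok <- function(ax, dd) {
    s <- array(FALSE, d)
    if (ax == 1 && dd == 1) s[1:(d[1] - 1), , ] <- mask[2:d[1], , ]
    if (ax == 1 && dd == -1) s[2:d[1], , ] <- mask[1:(d[1] - 1), , ]
    if (ax == 2 && dd == 1) s[, 1:(d[2] - 1), ] <- mask[, 2:d[2], ]
    if (ax == 2 && dd == -1) s[, 2:d[2], ] <- mask[, 1:(d[2] - 1), ]
    if (ax == 3 && dd == 1) s[, , 1:(d[3] - 1)] <- mask[, , 2:d[3]]
    if (ax == 3 && dd == -1) s[, , 2:d[3]] <- mask[, , 1:(d[3] - 1)]
    s
  }
  for (ax in 1:3) for (dd in c(-1, 1)) out <- out & shift_ok(ax, dd)
  out
}

# In-plane polar coordinates of voxel centers: radius (mm) and angle (deg,
# counter-clockwise from the +column axis, in [0, 360)).
polar_grid <- function(matrix, voxel_size, center) {
  nr <- matrix[1]; nc <- matrix[2]
  y <- (seq_len(nr) - center[1]) * voxel_size[1]
  x <- (seq_len(nc) - center[2]) * voxel_size[2]
  ym <- base::matrix(y, nr, nc)
  xm <- base::matrix(x, nr, nc, byrow = TRUE)
  r <- sqrt(xm^2 + ym^2)
  theta <- (atan2(ym, xm) * 180 / pi) %% 360
  list(r = r, theta = theta)
}

# Half-open angular sector membership [center - w/2, center + w/2) mod 360,
# so adjoining sectors never double-label a voxel.
in_sector <- function(theta, center_deg, width_deg) {
  if (width_deg <= 0) return(array(FALSE, dim = dim(theta)))
  if (width_deg >= 360) return(array(TRUE, dim = dim(theta)))
  lo <- (center_deg - width_deg / 2) %% 360
  d <- (theta - lo) %% 360
  d < width_deg
}

#' Angular sector mask over the myocardium
#'
#' Utility shared by the remote-reference selector and the anteroseptal
#' fallback ROI: all myocardial voxels whose in-plane angle falls in the
#' half-open sector `[center - width/2, center + width/2)`.
#'
#' @param myocardium logical 3-D mask.
#' @param spec the `phantom_spec` (supplies grid geometry), or a list with
#'   `matrix`, `voxel_size`, `center`.
#' @param center_deg,width_deg sector placement in degrees.
#' @param slices optional slice subset.
#' @return logical 3-D mask.
#' @export
sector_mask <- function(myocardium, spec, center_deg, width_deg, slices = NULL) {
  pg <- polar_grid(spec$matrix, spec$voxel_size, spec$center)
  sec2d <- in_sector(pg$theta, center_deg, width_deg)
  out <- myocardium
  ns <- dim(myocardium)[3]
  keep <- slices %||% seq_len(ns)
  for (z in seq_len(ns)) {
    out[, , z] <- if (z %in% keep) myocardium[, , z] & sec2d else FALSE
  }
  out
}

# k voxels of `pool` (logical 3-D) nearest the pool's center under a
# normalized metric in lesion-adapted coordinates (radial offset, arc length
# at the mean radius, slice position); ties broken by array index. Working in
# (r, theta, z) rather than Cartesian keeps the carved core inside the
# curved annular band instead of drifting toward the concave (cavity) side.
core_subset <- function(pool, k, voxel_size, pg, sector_center_deg,
                        slices_allowed = NULL) {
  out <- array(FALSE, dim = dim(pool))
  if (k <= 0 || !any(pool)) return(out)
  # carve from the 6-erosion of the parent so every core voxel keeps all its
  # neighbors inside the parent region: strict enclosure by construction
  eroded <- erode6(pool)
  if (!any(eroded)) return(out)
  idx <- which(eroded)
  ai <- arrayInd(idx, dim(pool))
  if (!is.null(slices_allowed)) {
    ok <- ai[, 3] %in% slices_allowed
    idx <- idx[ok]; ai <- ai[ok, , drop = FALSE]
    if (!length(idx)) return(out)
  }
  inplane <- (ai[, 2] - 1L) * dim(pool)[1] + ai[, 1]
  r <- pg$r[inplane]
  dtheta <- ((pg$theta[inplane] - sector_center_deg + 180) %% 360) - 180
  arc <- mean(r) * dtheta * pi / 180
  z <- ai[, 3] * voxel_size[3]
  u <- cbind(r, arc, z)
  ctr <- colMeans(u)
  sc <- pmax(apply(u, 2, stats::sd), 1e-6)
  # cores run longitudinally through the lesion: stretch the metric along z
  # so the blob spans the interior slices with a near-uniform footprint
  sc[3] <- sc[3] * 4
  d2 <- colSums((t(u) - ctr)^2 / sc^2)
  k <- min(k, length(idx))
  # grow a single 6-connected blob in distance order so the core is one
  # compact component (a no-reflow core is one region, not scattered islands)
  d <- dim(pool)
  ord <- order(d2, idx)
  chosen <- logical(length(idx))
  lookup <- new.env(hash = TRUE, size = length(idx))
  for (j in seq_along(idx)) assign(as.character(idx[j]), j, envir = lookup)
  adjacent <- logical(length(idx))
  chosen[ord[1]] <- TRUE
  mark_nb <- function(j) {
    for (nb in neighbors6(idx[j], d)) {
      jj <- mget(as.character(nb), envir = lookup, ifnotfound = list(NULL))[[1]]
      if (!is.null(jj) && !chosen[jj]) adjacent[jj] <<- TRUE
    }
  }
  mark_nb(ord[1])
  n_chosen <- 1L
  while (n_chosen < k) {
    cand <- which(adjacent & !chosen)
    if (!length(cand)) break # pool exhausted around the blob
    j <- cand[which.min(d2[cand])]
    chosen[j] <- TRUE
    adjacent[j] <- FALSE
    mark_nb(j)
    n_chosen <- n_chosen + 1L
  }
  out[idx[chosen]] <- TRUE
  out
}

#' Build the phantom ground truth
#'
#' Rasterizes the annulus and lesion geometry of a [phantom_spec()] and fills
#' the true parameter maps. Purely deterministic: identical specs give
#' identical ground truth; randomness enters only when series are simulated.
#'
#' Core components (hemorrhage, MVO) are carved out of their parent regions as
#' the exact `fraction`-sized set of voxels nearest the parent's center of
#' mass, restricted to interior slices, which guarantees the containment
#' chain `mvo` in `infarct` in `edema` and strict 3-D enclosure of the cores.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_truth`: true `t2`, `t2star`, `amplitude`,
#'   `t1eff` maps, `myocardium` mask, `masks` (list: hemorrhage, edema,
#'   infarct, mvo), and the originating `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$matrix[1]; nc <- spec$matrix[2]; ns <- spec$n_slices
  pg <- polar_grid(spec$matrix, spec$voxel_size, spec$center)
  wall <- spec$r_epi_mm - spec$r_endo_mm

  myo2d <- pg$r >= spec$r_endo_mm & pg$r < spec$r_epi_mm
  myo <- array(myo2d, dim = c(nr, nc, ns))

  dims <- c(nr, nc, ns)
  edema <- array(FALSE, dims); infarct <- array(FALSE, dims)

  if (spec$arm != "healthy") {
    les2d <- myo2d &
      in_sector(pg$theta, spec$sector_center_deg, spec$sector_width_deg) &
      pg$r < spec$r_endo_mm + spec$transmurality * wall
    for (z in spec$lesion_slices) edema[, , z] <- les2d
    if (spec$arm %in% c("I-HEM", "I+HEM")) {
      inf2d <- myo2d &
        in_sector(pg$theta, spec$sector_center_deg, 0.7 * spec$sector_width_deg) &
        pg$r < spec$r_endo_mm + 0.8 * spec$transmurality * wall
      for (z in spec$lesion_slices) infarct[, , z] <- inf2d
    }
  }

  interior <- function(slices) {
    if (length(slices) >= 3) slices[-c(1, length(slices))] else slices
  }
  hemorrhage <- core_subset(
    edema, round(spec$hemorrhage_fraction * sum(edema)),
    spec$voxel_size, pg, spec$sector_center_deg, interior(spec$lesion_slices)
  )
  mvo <- core_subset(
    infarct, round(spec$mvo_fraction * sum(infarct)),
    spec$voxel_size, pg, spec$sector_center_deg, interior(spec$lesion_slices)
  )
  if (spec$hemorrhage_fraction > 0 && !any(hemorrhage)) {
    cmrtc_stop("lesion too thin to host an enclosed hemorrhagic core",
      "cmrtc_config_error")
  }
  if (spec$mvo_fraction > 0 && !any(mvo)) {
    cmrtc_stop("infarct too thin to host an enclosed MVO core",
      "cmrtc_config_error")
  }

  ts <- spec$tissue
  t2 <- array(0, dims); t2star <- array(0, dims)
  t1eff <- array(0, dims); amp <- array(0, dims)
  t2[myo] <- ts$remote_t2
  t2[edema] <- ts$edema_t2
  t2[hemorrhage] <- ts$hemorrhage_t2
  t2star[myo] <- ts$remote_t2star
  t2star[edema] <- ts$edema_t2star
  t2star[hemorrhage] <- ts$hemorrhage_t2star
  t1eff[myo] <- ts$t1_remote
  t1eff[infarct] <- ts$t1_infarct
  t1eff[mvo] <- ts$t1_mvo
  amp[myo] <- ts$amplitude

  structure(
    list(
      t2 = t2, t2star = t2star, amplitude = amp, t1eff = t1eff,
      myocardium = myo,
      masks = list(
        hemorrhage = hemorrhage, edema = edema, infarct = infarct, mvo = mvo
      ),
      spec = spec
    ),
    class = "phantom_truth"
  )
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "<phantom_truth> arm %s, grid %dx%dx%d, myocardium %d voxels\n",
    x$spec$arm, dim(x$t2)[1], dim(x$t2)[2], dim(x$t2)[3], sum(x$myocardium)
  ))
  for (m in names(x$masks)) cat(sprintf("  %-10s %d voxels\n", m, sum(x$masks[[m]])))
  invisible(x)
}

# Apply the configured noise model to a noiseless magnitude signal array.
# Rician: magnitude of a complex Gaussian perturbation, sigma = remote
# amplitude / SNR -- the physical model for magnitude MR images. Gaussian is
# offered for oracle tests and is floored at zero to preserve the magnitude
# convention (negligible at the SNRs used).
apply_noise <- function(signal, noise, amplitude_remote, seed) {
  model <- noise$model %||% "none"
  if (model == "none") return(signal)
  sigma <- amplitude_remote / noise$snr
  set.seed(seed)
  n <- length(signal)
  if (model == "rician") {
    sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  } else {
    pmax(signal + stats::rnorm(n, 0, sigma), 0)
  }
}

new_series <- function(data, times, contrast_kind, voxel_size) {
  structure(
    list(data = data, times = times, contrast_kind = contrast_kind,
         voxel_size = voxel_size),
    class = "image_series"
  )
}

simulate_decay_series <- function(gt, protocol, map, noise, seed, kind, stream) {
  if (protocol$contrast_kind != kind) {
    cmrtc_stop(sprintf("protocol contrast is %s, expected %s",
      protocol$contrast_kind, kind), "cmrtc_config_error")
  }
  d <- dim(map)
  if (any(d != c(protocol$matrix, protocol$n_slices))) {
    cmrtc_stop("protocol grid does not match phantom grid", "cmrtc_dim_error")
  }
  te <- protocol$echo_times
  ne <- length(te)
  dec <- array(0, dim = c(d, ne))
  rate <- array(0, dim = d)
  pos <- map > 0
  rate[pos] <- 1 / map[pos]
  for (i in seq_len(ne)) {
    s <- gt$amplitude * exp(-te[i] * rate)
    s[!pos] <- 0
    dec[, , , i] <- s
  }
  dec <- array(
    apply_noise(dec, noise, gt$spec$tissue$amplitude, child_seed(seed, stream)),
    dim = c(d, ne)
  )
  new_series(dec, te, kind, protocol$voxel_size)
}

#' Simulate the T2-prepared series
#'
#' Noiseless signal `A * exp(-TE / T2)` per voxel and preparation time;
#' background voxels (amplitude 0) receive noise only.
#'
#' @param gt a [build_phantom()] result.
#' @param protocol a `t2prep` [acquisition_protocol()] on the phantom grid.
#' @param noise noise settings (defaults to the spec's).
#' @param seed noise seed (defaults to the spec's).
#' @return an `image_series` with a 4-D `data` array (row, col, slice, echo).
#' @export
simulate_t2prep_series <- function(gt, protocol = NULL,
                                   noise = gt$spec$noise, seed = gt$spec$seed) {
  protocol <- protocol %||% t2prep_protocol(
    n_slices = gt$spec$n_slices, matrix = gt$spec$matrix,
    voxel_size = gt$spec$voxel_size
  )
  simulate_decay_series(gt, protocol, gt$t2, noise, seed, "t2prep", 1L)
}

#' Simulate the multi-echo gradient-echo series
#'
#' As [simulate_t2prep_series()] with `A * exp(-TE / T2*)`.
#'
#' @inheritParams simulate_t2prep_series
#' @return an `image_series`.
#' @export
simulate_gre_series <- function(gt, protocol = NULL,
                                noise = gt$spec$noise, seed = gt$spec$seed) {
  protocol <- protocol %||% gre_protocol(
    n_slices = gt$spec$n_slices, matrix = gt$spec$matrix,
    voxel_size = gt$spec$voxel_size
  )
  simulate_decay_series(gt, protocol, gt$t2star, noise, seed, "me_gre", 2L)
}

#' Simulate the late gadolinium enhancement image
#'
#' Magnitude inversion-recovery model `S = A * |1 - 2 exp(-TI / T1_eff)|`
#' evaluated on per-compartment effective T1 values. At the default inversion
#' time (280 ms) remote myocardium (T1_eff = TI / ln 2) nulls exactly, the
#' short-T1 infarct is bright and the MVO compartment is hypointense.
#'
#' @param gt a [build_phantom()] result.
#' @param inversion_time TI in ms, > 0.
#' @param noise,seed noise settings (default the spec's).
#' @return an `image_series` with 3-D `data` and `times = inversion_time`.
#' @export
simulate_lge_image <- function(gt, inversion_time = 280,
                               noise = gt$spec$noise, seed = gt$spec$seed) {
  if (inversion_time <= 0) {
    cmrtc_stop("inversion_time must be > 0", "cmrtc_config_error")
  }
  s <- array(0, dim = dim(gt$t1eff))
  m <- gt$t1eff > 0
  s[m] <- gt$amplitude[m] * abs(1 - 2 * exp(-inversion_time / gt$t1eff[m]))
  s <- array(
    apply_noise(s, noise, gt$spec$tissue$amplitude, child_seed(seed, 3L)),
    dim = dim(s)
  )
  new_series(s, inversion_time, "lge", gt$spec$voxel_size)
}

#' Simulate cine cavity and myocardium masks
#'
#' The cavity is a disc per slice whose voxel count tracks a smooth volume
#' curve from EDV (phase 1) to ESV (mid-cycle) and back; the myocardial
#' annulus keeps a phase-constant voxel count (incompressibility convention).
#' Both masks are built by selecting an exact number of voxels in order of
#' radius, so volumes match their targets to the rasterization step.
#'
#' @param spec a [phantom_spec()] with `cine$edv_ml > cine$esv_ml > 0`.
#' @param n_phases number of cardiac phases (default from the spec).
#' @return list with `cavity` and `myocardium` (lists of logical 3-D masks,
#'   one per phase), `volumes_ml` (cavity volume per phase) and `voxel_size`.
#' @export
simulate_cine_masks <- function(spec, n_phases = NULL) {
  n_phases <- as.integer(n_phases %||% spec$cine$n_phases %||% 20L)
  edv <- spec$cine$edv_ml; esv <- spec$cine$esv_ml
  if (is.null(edv) || is.null(esv) || !(edv > esv && esv > 0)) {
    cmrtc_stop("cine simulation requires EDV > ESV > 0", "cmrtc_config_error")
  }
  if (n_phases < 1) cmrtc_stop("n_phases must be >= 1", "cmrtc_config_error")
  nr <- spec$matrix[1]; nc <- spec$matrix[2]; ns <- spec$n_slices
  pg <- polar_grid(spec$matrix, spec$voxel_size, spec$center)
  ord <- order(pg$r, seq_along(pg$r))
  vml <- voxel_ml(spec$voxel_size)

  # phase-constant myocardial voxel count from the spec's annulus area
  myo_per_slice <- round(pi * (spec$r_epi_mm^2 - spec$r_endo_mm^2) /
    (spec$voxel_size[1] * spec$voxel_size[2]))

  phases <- seq_len(n_phases) - 1
  vol_target <- if (n_phases == 1) edv else {
    esv + (edv - esv) * (1 + cos(2 * pi * phases / n_phases)) / 2
  }

  cavity <- vector("list", n_phases)
  myocardium <- vector("list", n_phases)
  vol_out <- numeric(n_phases)
  for (p in seq_len(n_phases)) {
    k_cav <- max(1L, round(vol_target[p] / vml / ns))
    cav2d <- matrix(FALSE, nr, nc)
    cav2d[ord[seq_len(k_cav)]] <- TRUE
    myo2d <- matrix(FALSE, nr, nc)
    myo2d[ord[seq.int(k_cav + 1, k_cav + myo_per_slice)]] <- TRUE
    cavity[[p]] <- array(cav2d, dim = c(nr, nc, ns))
    myocardium[[p]] <- array(myo2d, dim = c(nr, nc, ns))
    vol_out[p] <- k_cav * ns * vml
  }
  list(
    cavity = cavity, myocardium = myocardium,
    volumes_ml = vol_out, voxel_size = spec$voxel_size
  )
}
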