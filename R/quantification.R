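# Volumetrics, ROI statistics and cardiac function.

#' Lesion volumes, masses and percent of LV
#'
#' Voxel counting with exact unit conversion: volume (mL) = voxel count x
#' voxel volume, mass (g) = volume x density, percent = 100 x label voxels /
#' LV myocardial voxels. Labels are clipped to the myocardium so every
#' percent is <= 100.
#'
#' @param masks named list of `lesion_mask` objects or logical arrays.
#' @param myocardium logical 3-D LV myocardial mask (the percent denominator).
#' @param voxel_size `(dx, dy, dz)` mm.
#' @param density_g_per_ml myocardial density (default 1.05 g/mL).
#' @return object of class `volume_report`: a data.frame `table` (label,
#'   n_voxels, volume_ml, mass_g, percent_lv) plus `lv_volume_ml`,
#'   `lv_mass_g`, `voxel_size`, `density`.
#' @export
compute_volumes <- function(masks, myocardium, voxel_size,
                            density_g_per_ml = 1.05) {
  n_lv <- sum(myocardium)
  if (n_lv == 0) {
    cmrtc_stop("empty myocardium: percent of LV undefined", "cmrtc_data_error")
  }
  vml <- voxel_ml(voxel_size)
  rows <- lapply(names(masks), function(lb) {
    m <- masks[[lb]]
    if (inherits(m, "lesion_mask")) m <- m$mask
    check_same_dim(m, myocardium, paste0(lb, " vs myocardium"))
    n <- sum(m & myocardium)
    data.frame(
      label = lb, n_voxels = n, volume_ml = n * vml,
      mass_g = n * vml * density_g_per_ml,
      percent_lv = 100 * n / n_lv, stringsAsFactors = FALSE
    )
  })
  structure(
    list(
      table = do.call(rbind, rows),
      lv_volume_ml = n_lv * vml,
      lv_mass_g = n_lv * vml * density_g_per_ml,
      voxel_size = voxel_size, density = density_g_per_ml
    ),
    class = "volume_report"
  )
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf("<volume_report> LV %0.1f mL / %0.1f g\n", x$lv_volume_ml, x$lv_mass_g))
  print(x$table, row.names = FALSE)
  invisible(x)
}

# Mid-ventricular slice: median index of slices containing myocardium; even
# counts take the lower index.
mid_ventricular_slice <- function(myocardium) {
  zs <- which(apply(myocardium, 3, any))
  if (!length(zs)) cmrtc_stop("empty myocardium mask", "cmrtc_data_error")
  zs[ceiling(length(zs) / 2)]
}

#' Infarct-zone and remote relaxation values on the mid-ventricular slice
#'
#' Copies the LGE-segmented infarct region onto the relaxation maps and
#' reports its mean/SD T2 and T2*, beside the remote values. When the infarct
#' mask is empty (no enhancement, the hemorrhage-only pathway) the supplied
#' anteroseptal fallback ROI is used instead.
#'
#' @param t2_map,t2star_map `parameter_map`s on a common grid.
#' @param infarct_mask `lesion_mask` or logical array.
#' @param remote_mask logical remote-reference mask.
#' @param myocardium logical mask (used to pick the mid-ventricular slice).
#' @param fallback_roi logical mask used when the infarct is empty (build one
#'   with [sector_mask()] over the anteroseptal sector).
#' @return object of class `region_stats`: infarct-zone and remote mean/sd T2
#'   and T2*, the slice used, and which ROI was used.
#' @export
extract_region_stats <- function(t2_map, t2star_map, infarct_mask, remote_mask,
                                 myocardium, fallback_roi = NULL) {
  inf <- if (inherits(infarct_mask, "lesion_mask")) infarct_mask$mask else infarct_mask
  z <- mid_ventricular_slice(myocardium)
  slice_only <- function(m) {
    out <- array(FALSE, dim = dim(m)); out[, , z] <- m[, , z]; out
  }
  roi_name <- "infarct"
  roi <- slice_only(inf)
  # no enhancement at all, or none on the chosen slice: use the LAD-territory
  # fallback sector
  if (!any(roi)) {
    roi_name <- "anteroseptal_fallback"
    roi <- if (!is.null(fallback_roi)) slice_only(fallback_roi) else roi
  }
  if (!any(roi)) {
    cmrtc_stop(
      sprintf("no infarct and no fallback ROI on mid-ventricular slice %d", z),
      "cmrtc_data_error"
    )
  }
  rem <- slice_only(remote_mask)
  s_t2 <- map_summary(t2_map, roi)
  s_t2s <- map_summary(t2star_map, roi)
  r_t2 <- map_summary(t2_map, rem)
  r_t2s <- map_summary(t2star_map, rem)
  structure(
    list(
      slice = z, roi = roi_name,
      infarct_t2_mean = s_t2$mean, infarct_t2_sd = s_t2$sd,
      infarct_t2star_mean = s_t2s$mean, infarct_t2star_sd = s_t2s$sd,
      remote_t2_mean = r_t2$mean, remote_t2_sd = r_t2$sd,
      remote_t2star_mean = r_t2s$mean, remote_t2star_sd = r_t2s$sd
    ),
    class = "region_stats"
  )
}

#' Cardiac function from per-phase masks
#'
#' EDV is the largest per-phase cavity volume, ESV the smallest,
#' EF = 100 (EDV - ESV) / EDV, and LV mass is the myocardial volume at the
#' EDV phase times density.
#'
#' @param cavity_masks,myocardium_masks lists of logical 3-D masks, one per
#'   phase (a single phase gives EF 0).
#' @param voxel_size `(dx, dy, dz)` mm.
#' @param density_g_per_ml myocardial density.
#' @return object of class `function_report`: `ef`, `edv_ml`, `esv_ml`,
#'   `lv_mass_g`.
#' @export
cardiac_function <- function(cavity_masks, myocardium_masks, voxel_size,
                             density_g_per_ml = 1.05) {
  if (!length(cavity_masks)) {
    cmrtc_stop("need at least one cine phase", "cmrtc_config_error")
  }
  vml <- voxel_ml(voxel_size)
  vols <- vapply(cavity_masks, function(m) sum(m) * vml, numeric(1))
  edv <- max(vols); esv <- min(vols)
  if (edv == 0) cmrtc_stop("EDV is zero: EF undefined", "cmrtc_data_error")
  p_edv <- which.max(vols)
  mass <- sum(myocardium_masks[[p_edv]]) * vml * density_g_per_ml
  structure(
    list(
      ef = 100 * (edv - esv) / edv, edv_ml = edv, esv_ml = esv,
      lv_mass_g = mass
    ),
    class = "function_report"
  )
}

#' @export
print.function_report <- function(x, ...) {
  cat(sprintf(
    "<function_report> EF %0.1f%%, EDV %0.1f mL, ESV %0.1f mL, LV mass %0.1f g\n",
    x$ef, x$edv_ml, x$esv_ml, x$lv_mass_g
  ))
  invisible(x)
}
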