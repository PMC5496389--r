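# Lesion segmentation from parameter maps and LGE images.
#
# Criteria:
#   hemorrhage  valid T2* strictly below 20 ms, within the myocardium
#   edema       T2 strictly above remote mean + 2 SD, plus enclosed
#               hypointense cores (hemorrhage/MVO read dark on T2)
#   infarct     full-width-half-maximum on LGE: intensity >= half the
#               reference maximum over the myocardium
#   MVO         hypoenhanced region enclosed by the infarct, recovered by
#               seeded front propagation
#
# All connected-component and growing operations use 6-neighborhood
# connectivity in 3-D. Every mask records the exact thresholds applied in its
# provenance.

# ---- connectivity helpers -------------------------------------------------

# Valid 6-neighbors of linear indices `idx` in a grid of dim `d`.
neighbors6 <- function(idx, d) {
  ai <- arrayInd(idx, d)
  out <- vector("list", 6L)
  k <- 0L
  for (ax in 1:3) {
    for (dd in c(-1L, 1L)) {
      nb <- ai
      nb[, ax] <- nb[, ax] + dd
      ok <- nb[, ax] >= 1L & nb[, ax] <= d[ax]
      k <- k + 1L
      out[[k]] <- (nb[ok, 1] - 1L) + (nb[ok, 2] - 1L) * d[1] +
        (nb[ok, 3] - 1L) * d[1] * d[2] + 1L
    }
  }
  unlist(out, use.names = FALSE)
}

#' Label 6-connected components of a 3-D mask
#'
#' @param mask logical 3-D array.
#' @return integer array: 0 outside the mask, 1..k component labels.
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  todo <- which(mask)
  if (!length(todo)) return(lab)
  inmask <- array(FALSE, d)
  inmask[todo] <- TRUE
  nxt <- 0L
  for (s in todo) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    lab[s] <- nxt
    frontier <- s
    while (length(frontier)) {
      nb <- unique(neighbors6(frontier, d))
      nb <- nb[inmask[nb] & lab[nb] == 0L]
      lab[nb] <- nxt
      frontier <- nb
    }
  }
  lab
}

# Drop connected components smaller than min_size voxels.
drop_small_components <- function(mask, min_size) {
  if (min_size <= 1 || !any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  array(lab %in% keep, dim = dim(mask))
}

# Connected components of `candidates` that are fully enclosed by `wall`:
# every 6-neighbor outside the component is a wall voxel and the component
# touches no volume boundary. The search is restricted to the bounding box of
# the wall; a component reaching the box boundary has escaped the wall and is
# therefore open.
enclosed_components <- function(candidates, wall) {
  d <- dim(candidates)
  if (!any(wall)) return(list())
  ai <- arrayInd(which(wall), d)
  lo <- pmax(apply(ai, 2, min) - 1L, 1L)
  hi <- pmin(apply(ai, 2, max) + 1L, d)
  box <- array(FALSE, d)
  box[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  cand <- candidates & box & !wall
  if (!any(cand)) return(list())
  lab <- label_components(cand)
  out <- list()
  for (k in seq_len(max(lab))) {
    comp <- which(lab == k)
    ci <- arrayInd(comp, d)
    nb <- setdiff(unique(neighbors6(comp, d)), comp)
    # a component on the volume edge has missing neighbors and cannot be
    # enclosed; one clipped at the box face has non-wall neighbors outside it
    full_interior <- all(ci[, 1] > 1L & ci[, 1] < d[1] &
      ci[, 2] > 1L & ci[, 2] < d[2] &
      ci[, 3] > 1L & ci[, 3] < d[3])
    if (full_interior && all(wall[nb])) out[[length(out) + 1L]] <- comp
  }
  out
}

new_lesion_mask <- function(label, mask, myocardium = NULL, provenance = list()) {
  if (!is.null(myocardium)) mask <- mask & myocardium
  structure(
    list(label = label, mask = mask, provenance = provenance),
    class = "lesion_mask"
  )
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s: %d voxels\n", x$label, sum(x$mask)))
  invisible(x)
}

# ---- remote reference -----------------------------------------------------

#' Select the remote-myocardium reference sector
#'
#' The uninjured reference region is the myocardial sector centered
#' diametrically opposite (180 degrees from) the lesion sector, spanning all
#' slices.
#'
#' @param myocardium logical 3-D myocardial mask.
#' @param spec geometry provider (a [phantom_spec()] or list with `matrix`,
#'   `voxel_size`, `center`).
#' @param lesion_center_deg lesion sector center.
#' @param width_deg angular width of the remote sector (default 60), must be
#'   < 360 so it cannot overlap the lesion.
#' @return logical 3-D mask.
#' @export
select_remote <- function(myocardium, spec, lesion_center_deg, width_deg = 60) {
  if (!any(myocardium)) cmrtc_stop("empty myocardium mask", "cmrtc_data_error")
  if (width_deg >= 360) {
    cmrtc_stop("remote sector width must be < 360 degrees (would overlap the lesion)",
      "cmrtc_config_error")
  }
  sector_mask(myocardium, spec, (lesion_center_deg + 180) %% 360, width_deg)
}

#' Remote reference statistics
#'
#' @param t2_map `parameter_map` of T2.
#' @param remote_mask logical mask from [select_remote()].
#' @param t2star_map optional `parameter_map` of T2*.
#' @return object of class `remote_reference`: `mask`, `t2_mean`, `t2_sd`,
#'   `t2star_mean`, `n_valid`.
#' @export
remote_reference <- function(t2_map, remote_mask, t2star_map = NULL) {
  s <- map_summary(t2_map, remote_mask)
  t2s <- if (!is.null(t2star_map)) map_summary(t2star_map, remote_mask)$mean else NA_real_
  structure(
    list(
      mask = remote_mask, t2_mean = s$mean, t2_sd = s$sd,
      t2star_mean = t2s, n_valid = s$n_valid
    ),
    class = "remote_reference"
  )
}

# ---- lesion criteria ------------------------------------------------------

#' Segment intramyocardial hemorrhage on a T2* map
#'
#' Labels myocardial voxels whose valid fitted T2* is strictly below the
#' threshold (default 20 ms).
#'
#' @param t2star_map a `parameter_map`.
#' @param myocardium logical 3-D mask.
#' @param threshold_ms detection threshold, strict `<`.
#' @param min_size smallest kept 6-connected component (voxels); suppresses
#'   single-voxel noise islands.
#' @return a `lesion_mask` labelled `"hemorrhage"`.
#' @export
segment_hemorrhage <- function(t2star_map, myocardium, threshold_ms = 20,
                               min_size = 3L) {
  check_same_dim(t2star_map$valid, myocardium, "map vs myocardium")
  raw <- t2star_map$valid & myocardium &
    !is.na(t2star_map$relaxation_time) &
    t2star_map$relaxation_time < threshold_ms
  m <- drop_small_components(raw, min_size)
  new_lesion_mask("hemorrhage", m,
    provenance = list(
      criterion = "t2star_below_threshold", threshold_ms = threshold_ms,
      strict = TRUE, min_component_size = min_size,
      n_raw = sum(raw), n_kept = sum(m)
    )
  )
}

#' Segment myocardial edema on a T2 map
#'
#' Two components are unioned: (1) the threshold component — myocardial
#' voxels with valid T2 strictly above `remote mean + 2 SD`; (2) the
#' core-fill component — hypointense regions (T2 below the remote mean) that
#' are fully enclosed by the threshold component, plus any voxels of the
#' supplied companion core masks (hemorrhage from T2*, MVO from LGE). The
#' core fill uses the same enclosed-region growing routine as [segment_mvo()]
#' and accounts for hemorrhage/MVO reading dark on T2 despite sitting inside
#' edematous tissue.
#'
#' @param t2_map a `parameter_map`.
#' @param myocardium logical 3-D mask.
#' @param remote a [remote_reference()] (its `t2_sd` must be finite).
#' @param companion_cores optional list of `lesion_mask` objects or logical
#'   arrays (hemorrhage / MVO) to include as hypointense cores.
#' @param n_sd multiplier on the remote SD (default 2).
#' @param min_size smallest kept component of the final mask.
#' @return a `lesion_mask` labelled `"edema"`; provenance records both
#'   components' voxel counts and the cut-off applied.
#' @export
segment_edema <- function(t2_map, myocardium, remote, companion_cores = NULL,
                          n_sd = 2, min_size = 3L) {
  if (!inherits(remote, "remote_reference") ||
    !is.finite(remote$t2_sd) || !is.finite(remote$t2_mean)) {
    cmrtc_stop(
      "remote T2 statistics undefined; build them with select_remote()/remote_reference()",
      "cmrtc_undefined_stats"
    )
  }
  check_same_dim(t2_map$valid, myocardium, "map vs myocardium")
  cutoff <- remote$t2_mean + n_sd * remote$t2_sd
  t2 <- t2_map$relaxation_time
  thr <- t2_map$valid & myocardium & !is.na(t2) & t2 > cutoff

  hypo <- t2_map$valid & myocardium & !is.na(t2) & t2 < remote$t2_mean & !thr
  comps <- enclosed_components(hypo, thr)
  fill <- array(FALSE, dim = dim(thr))
  for (comp in comps) fill[comp] <- TRUE
  for (cm in companion_cores %||% list()) {
    m <- if (inherits(cm, "lesion_mask")) cm$mask else cm
    fill <- fill | (m & myocardium)
  }
  m <- drop_small_components(thr | fill, min_size)
  new_lesion_mask("edema", m,
    provenance = list(
      criterion = "t2_above_remote_plus_sd", cutoff_ms = cutoff,
      n_sd = n_sd, remote_mean_ms = remote$t2_mean, remote_sd_ms = remote$t2_sd,
      n_threshold = sum(thr), n_core_fill = sum(fill & !thr),
      min_component_size = min_size, n_kept = sum(m)
    )
  )
}

#' Segment infarct on an LGE image by full-width-half-maximum
#'
#' The reference maximum is the largest myocardial LGE intensity over the 3-D
#' volume (restricted to `seed_region` when supplied, mimicking the
#' semi-automatic operator seed); voxels at or above half that reference are
#' labelled. Hypoenhanced voxels enclosed by the mask are left to
#' [segment_mvo()]. When remote LGE statistics are supplied and the reference
#' maximum does not exceed `remote mean + floor_mult * SD`, the myocardium is
#' deemed unenhanced and an empty mask is returned (the hemorrhage-only arm).
#'
#' @param lge an `image_series` (3-D data) or a 3-D array.
#' @param myocardium logical 3-D mask.
#' @param seed_region optional logical mask restricting the reference-maximum
#'   search.
#' @param remote_lge optional list with `mean` and `sd` of remote LGE
#'   intensity, enabling the no-enhancement floor guard.
#' @param floor_mult guard multiple (default 5).
#' @param min_size smallest kept component.
#' @return a `lesion_mask` labelled `"infarct"`.
#' @export
segment_infarct_fwhm <- function(lge, myocardium, seed_region = NULL,
                                 remote_lge = NULL, floor_mult = 5,
                                 min_size = 3L) {
  img <- if (inherits(lge, "image_series")) lge$data else lge
  if (!any(myocardium)) cmrtc_stop("empty myocardium mask", "cmrtc_data_error")
  check_same_dim(img, myocardium, "lge vs myocardium")
  search <- if (is.null(seed_region)) myocardium else (seed_region & myocardium)
  if (!any(search)) cmrtc_stop("empty reference search region", "cmrtc_data_error")
  ref <- max(img[search])
  floor_val <- if (!is.null(remote_lge)) {
    remote_lge$mean + floor_mult * remote_lge$sd
  } else {
    -Inf
  }
  if (ref <= floor_val) {
    return(new_lesion_mask("infarct", array(FALSE, dim = dim(img)),
      provenance = list(
        criterion = "fwhm", reference_max = ref, below_floor = TRUE,
        floor = floor_val, floor_mult = floor_mult, min_component_size = min_size
      )
    ))
  }
  m <- drop_small_components(myocardium & img >= ref / 2, min_size)
  new_lesion_mask("infarct", m,
    provenance = list(
      criterion = "fwhm", reference_max = ref, half_max = ref / 2,
      below_floor = FALSE, floor = floor_val, floor_mult = floor_mult,
      min_component_size = min_size, n_kept = sum(m)
    )
  )
}

#' Segment microvascular obstruction within an infarct
#'
#' Candidate voxels are those below the half-maximum reference (taken over
#' the infarct) and fully enclosed by the infarct mask under 6-connectivity;
#' the region is grown by front propagation from `seed_point` when given,
#' otherwise from the darkest enclosed candidate, and stops at the infarct
#' boundary. Hypointense regions touching unenclosed tissue (e.g. the LV
#' cavity) are excluded.
#'
#' @param lge an `image_series` or 3-D array.
#' @param infarct_mask a `lesion_mask` or logical array; must be non-empty.
#' @param seed_point optional `(row, col, slice)` index inside the infarct
#'   bounding region.
#' @param min_size smallest kept component.
#' @return a `lesion_mask` labelled `"mvo"` (possibly empty).
#' @export
segment_mvo <- function(lge, infarct_mask, seed_point = NULL, min_size = 3L) {
  img <- if (inherits(lge, "image_series")) lge$data else lge
  inf <- if (inherits(infarct_mask, "lesion_mask")) infarct_mask$mask else infarct_mask
  if (!any(inf)) cmrtc_stop("segment_mvo() needs a non-empty infarct mask",
    "cmrtc_config_error")
  check_same_dim(img, inf, "lge vs infarct")
  d <- dim(img)
  ref <- max(img[inf])
  cand <- img < ref / 2 & !inf
  comps <- enclosed_components(cand, inf)

  pick <- NULL
  if (!is.null(seed_point)) {
    ai <- arrayInd(which(inf), d)
    lo <- apply(ai, 2, min); hi <- apply(ai, 2, max)
    if (any(seed_point < lo) || any(seed_point > hi)) {
      cmrtc_stop("seed_point lies outside the infarct bounding region",
        "cmrtc_config_error")
    }
    sidx <- (seed_point[1] - 1L) + (seed_point[2] - 1L) * d[1] +
      (seed_point[3] - 1L) * d[1] * d[2] + 1L
    for (comp in comps) if (sidx %in% comp) pick <- comp
  } else if (length(comps)) {
    darkest <- which.min(vapply(comps, function(c) min(img[c]), numeric(1)))
    pick <- comps[[darkest]]
  }

  m <- array(FALSE, dim = d)
  if (!is.null(pick)) m[pick] <- TRUE
  m <- drop_small_components(m, min_size)
  new_lesion_mask("mvo", m,
    provenance = list(
      criterion = "enclosed_hypoenhancement", reference_max = ref,
      half_max = ref / 2, seeded = !is.null(seed_point),
      min_component_size = min_size, n_kept = sum(m)
    )
  )
}
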