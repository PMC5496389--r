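# Pixel-wise mono-exponential relaxometry.
#
# Model: S(TE) = A * exp(-TE / T). The fit minimizes the ordinary
# least-squares criterion in signal space, initialized from a log-linear
# regression on the strictly positive samples and refined by a
# Levenberg-Marquardt iteration run simultaneously over all voxels
# (closed-form 2x2 normal equations per voxel). No Rician-likelihood
# correction is applied: the reference analysis used plain least squares, and
# the signal-space objective already down-weights the noise-floor echoes
# relative to a log-domain fit.

REASON_OK <- 0L
REASON_NON_DECAYING <- 1L
REASON_UNDERFLOW <- 2L
REASON_OUTSIDE_MASK <- 3L

#' Fit a relaxation-time map
#'
#' @param series an `image_series` (from the simulator or [read_study()])
#'   with at least 2 echoes.
#' @param mask logical array of voxels to fit (e.g. the myocardium); `NULL`
#'   fits every voxel.
#' @param method `"nonlinear"` (log-linear init + Levenberg-Marquardt
#'   refinement, the default) or `"loglin"` (log-linear only; exact on
#'   noiseless data, biased in noise).
#' @param cap largest reportable relaxation time (ms). Voxels whose signal
#'   does not decay (log-linear slope >= 0 or fitted T >= cap) are flagged
#'   invalid with `relaxation_time = cap` rather than reported as infinite.
#' @param tol relative parameter-change convergence tolerance.
#' @param max_iter iteration cap per voxel.
#' @return object of class `parameter_map`: arrays `relaxation_time`,
#'   `amplitude`, `residual_norm`, `valid`, `reason` (0 ok, 1 non-decaying,
#'   2 underflow, 3 outside mask) plus `contrast_kind` and the fit options.
#' @export
fit_exponential_map <- function(series, mask = NULL, method = c("nonlinear", "loglin"),
                                cap = 500, tol = 1e-8, max_iter = 100L) {
  method <- match.arg(method)
  te <- series$times
  if (length(te) < 2) {
    cmrtc_stop("relaxometry needs at least 2 echo times", "cmrtc_config_error")
  }
  d <- dim(series$data)
  stopifnot(length(d) == 4, d[4] == length(te))
  grid <- d[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim = grid)
  check_same_dim(mask, array(0, dim = grid), "mask vs series grid")

  nvox_all <- prod(grid)
  S_all <- matrix(series$data, nrow = nvox_all, ncol = length(te))
  idx <- which(mask)
  S <- S_all[idx, , drop = FALSE]
  nv <- length(idx)

  T_hat <- rep(NA_real_, nv)
  A_hat <- rep(NA_real_, nv)
  reason <- rep(REASON_OK, nv)

  # --- log-linear initialization on strictly positive samples ------------
  pos <- S > 0
  Y <- log(pmax(S, .Machine$double.xmin))
  Y[!pos] <- 0
  n_i <- rowSums(pos)
  TE <- matrix(te, nv, length(te), byrow = TRUE)
  st <- rowSums(TE * pos)
  st2 <- rowSums(TE^2 * pos)
  sy <- rowSums(Y * pos)
  sty <- rowSums(TE * Y * pos)
  denom <- n_i * st2 - st^2
  usable <- n_i >= 2 & denom > 0
  slope <- rep(NA_real_, nv)
  slope[usable] <- (n_i * sty - st * sy)[usable] / denom[usable]
  icept <- rep(NA_real_, nv)
  icept[usable] <- (sy - slope * st)[usable] / n_i[usable]

  reason[!usable] <- REASON_UNDERFLOW
  nondec <- usable & slope >= -1 / cap
  reason[nondec] <- REASON_NON_DECAYING
  T_hat[nondec] <- cap
  A_hat[nondec] <- exp(icept[nondec])

  fit <- usable & !nondec
  T0 <- -1 / slope[fit]
  A0 <- exp(icept[fit])

  if (method == "loglin" || !any(fit)) {
    T_hat[fit] <- T0
    A_hat[fit] <- A0
  } else {
    res <- lm_refine(S[fit, , drop = FALSE], te, A0, pmin(T0, cap), cap, tol, max_iter)
    T_hat[fit] <- res$T
    A_hat[fit] <- res$A
    hit_cap <- fit
    hit_cap[fit] <- res$T >= cap - 1e-9
    reason[hit_cap & fit] <- REASON_NON_DECAYING
  }

  # residual norm under the reported parameters
  pred <- A_hat * exp(-TE / T_hat)
  pred[is.na(pred)] <- 0
  rn <- sqrt(rowSums((S - pred)^2))

  mk <- function(vals, fill = NA_real_) {
    a <- array(fill, dim = grid); a[idx] <- vals; a
  }
  reason_arr <- array(REASON_OUTSIDE_MASK, dim = grid)
  reason_arr[idx] <- reason
  valid <- array(FALSE, dim = grid)
  valid[idx] <- reason == REASON_OK

  structure(
    list(
      relaxation_time = mk(T_hat),
      amplitude = mk(A_hat),
      residual_norm = mk(rn),
      valid = valid,
      reason = reason_arr,
      contrast_kind = series$contrast_kind,
      options = list(method = method, cap = cap, tol = tol, max_iter = max_iter)
    ),
    class = "parameter_map"
  )
}

# Levenberg-Marquardt over all voxels at once, parameters (A, R = 1/T).
lm_refine <- function(S, te, A, T0, cap, tol, max_iter) {
  nv <- nrow(S)
  ne <- length(te)
  TE <- matrix(te, nv, ne, byrow = TRUE)
  R <- 1 / T0
  Rmin <- 1 / cap
  Rmax <- 1 / 1e-3 # T floor of 1e-3 ms keeps exp() finite
  lambda <- rep(1e-3, nv)
  sse <- function(A, R) rowSums((S - A * exp(-TE * R))^2)
  cur <- sse(A, R)
  active <- rep(TRUE, nv)

  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    E <- exp(-TE * R)
    res <- S - A * E
    JA <- E
    JR <- -A * TE * E
    g1 <- rowSums(JA * res)
    g2 <- rowSums(JR * res)
    h11 <- rowSums(JA * JA)
    h22 <- rowSums(JR * JR)
    h12 <- rowSums(JA * JR)

    a11 <- h11 * (1 + lambda)
    a22 <- h22 * (1 + lambda)
    det <- a11 * a22 - h12^2
    det[det == 0 | !is.finite(det)] <- NA
    dA <- (g1 * a22 - g2 * h12) / det
    dR <- (g2 * a11 - g1 * h12) / det
    dA[is.na(dA)] <- 0
    dR[is.na(dR)] <- 0

    A_new <- A + ifelse(active, dA, 0)
    R_new <- pmin(pmax(R + ifelse(active, dR, 0), Rmin), Rmax)
    new <- sse(A_new, R_new)
    better <- active & is.finite(new) & new <= cur

    relchg <- pmax(
      abs(A_new - A) / pmax(abs(A), 1e-12),
      abs(R_new - R) / pmax(abs(R), 1e-12)
    )
    A[better] <- A_new[better]
    R[better] <- R_new[better]
    cur[better] <- new[better]
    lambda[better] <- pmax(lambda[better] / 3, 1e-12)
    lambda[active & !better] <- pmin(lambda[active & !better] * 3, 1e12)
    active[better & relchg < tol] <- FALSE
    # voxels whose damping exploded cannot improve further
    active[active & lambda >= 1e12] <- FALSE
  }
  list(A = A, T = 1 / R)
}

#' Summary statistics of a parameter map over an ROI
#'
#' Statistics are computed over the *valid* voxels of the ROI only; `n_valid`
#' is reported so callers can detect unusable ROIs. The spread estimator is
#' the sample standard deviation.
#'
#' @param map a `parameter_map`.
#' @param roi_mask logical array on the map grid.
#' @return list with `mean`, `sd`, `n_valid`.
#' @export
map_summary <- function(map, roi_mask) {
  stopifnot(inherits(map, "parameter_map"))
  check_same_dim(roi_mask, map$valid, "roi vs map grid")
  sel <- roi_mask & map$valid
  n <- sum(sel)
  if (n == 0) {
    cmrtc_stop("no valid voxels in ROI: statistics undefined", "cmrtc_undefined_stats")
  }
  v <- map$relaxation_time[sel]
  list(mean = mean(v), sd = sd0(v), n_valid = n)
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf(
    "<parameter_map> %s, grid %s, %d valid voxels (method %s, cap %g ms)\n",
    x$contrast_kind, paste(dim(x$valid), collapse = "x"),
    sum(x$valid), x$options$method, x$options$cap
  ))
  invisible(x)
}
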