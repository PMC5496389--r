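# Acquisition protocols: echo / preparation-time schedules and slice geometry.

#' Acquisition protocol
#'
#' Describes one imaging contrast: the echo (or T2-preparation) time schedule,
#' the voxel geometry and the matrix size. The stock schedules follow a 3T
#' porcine ischemia-reperfusion protocol: a T2-prepared spiral sequence with
#' preparation times 2.9/24.3/45.6/88.2/184.2 ms, an 8-echo gradient-echo
#' sequence spanning 1.4-15.8 ms for T2*, and a single inversion-recovery LGE
#' image per slice; slice thickness 5 mm throughout.
#'
#' @param contrast_kind one of `"t2prep"`, `"me_gre"`, `"lge"`, `"cine"`.
#' @param echo_times strictly increasing positive times in ms. Required
#'   (length >= 2) for `t2prep`/`me_gre`; length <= 1 for `lge`; ignored for
#'   `cine`.
#' @param voxel_size numeric length-3 `(dx, dy, dz)` in mm, all > 0.
#' @param n_slices number of short-axis slices, >= 1.
#' @param matrix in-plane matrix `(nx, ny)`.
#' @return an object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(contrast_kind,
                                 echo_times = numeric(),
                                 voxel_size = c(1.9, 1.9, 5),
                                 n_slices = 10L,
                                 matrix = c(128L, 128L)) {
  contrast_kind <- match.arg(contrast_kind, c("t2prep", "me_gre", "lge", "cine"))
  echo_times <- as.numeric(echo_times)
  if (contrast_kind %in% c("t2prep", "me_gre")) {
    if (length(echo_times) < 2) {
      cmrtc_stop(paste0(contrast_kind, " protocol needs at least 2 echo times"),
        "cmrtc_config_error")
    }
  }
  if (contrast_kind == "lge" && length(echo_times) > 1) {
    cmrtc_stop("lge protocol takes at most one echo time", "cmrtc_config_error")
  }
  if (length(echo_times) > 0) {
    if (any(echo_times <= 0) || any(diff(echo_times) <= 0)) {
      cmrtc_stop("echo_times must be strictly increasing and positive",
        "cmrtc_config_error")
    }
  }
  if (length(voxel_size) != 3 || any(voxel_size <= 0)) {
    cmrtc_stop("voxel_size must be 3 positive lengths (mm)", "cmrtc_config_error")
  }
  if (n_slices < 1) cmrtc_stop("n_slices must be >= 1", "cmrtc_config_error")
  structure(
    list(
      contrast_kind = contrast_kind,
      echo_times = echo_times,
      voxel_size = as.numeric(voxel_size),
      n_slices = as.integer(n_slices),
      matrix = as.integer(matrix)
    ),
    class = "acquisition_protocol"
  )
}

#' Stock protocols
#'
#' @param n_slices,matrix,voxel_size override the defaults (all contrasts are
#'   simulated on a common grid so masks transfer between them without
#'   registration).
#' @return an `acquisition_protocol`.
#' @rdname stock_protocols
#' @export
t2prep_protocol <- function(n_slices = 10L, matrix = c(128L, 128L),
                            voxel_size = c(1.9, 1.9, 5)) {
  acquisition_protocol("t2prep",
    echo_times = c(2.9, 24.3, 45.6, 88.2, 184.2),
    voxel_size = voxel_size, n_slices = n_slices, matrix = matrix
  )
}

#' @rdname stock_protocols
#' @export
gre_protocol <- function(n_slices = 10L, matrix = c(128L, 128L),
                         voxel_size = c(1.9, 1.9, 5)) {
  acquisition_protocol("me_gre",
    echo_times = seq(1.4, 15.8, length.out = 8),
    voxel_size = voxel_size, n_slices = n_slices, matrix = matrix
  )
}

#' @rdname stock_protocols
#' @export
lge_protocol <- function(n_slices = 10L, matrix = c(128L, 128L),
                         voxel_size = c(1.9, 1.9, 5)) {
  acquisition_protocol("lge",
    echo_times = numeric(),
    voxel_size = voxel_size, n_slices = n_slices, matrix = matrix
  )
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat(sprintf(
    "<acquisition_protocol> %s: %dx%d x %d slices, voxels %s mm",
    x$contrast_kind, x$matrix[1], x$matrix[2], x$n_slices,
    paste(x$voxel_size, collapse = "x")
  ), "\n")
  if (length(x$echo_times)) {
    cat("  echo times (ms):", paste(round(x$echo_times, 2), collapse = ", "), "\n")
  }
  invisible(x)
}
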