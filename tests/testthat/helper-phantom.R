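# Shared fixtures: a small fast phantom grid and builders for synthetic
# series / maps used across the suite. Everything is generated in code.

small_spec <- function(arm = "I+HEM", noise = list(model = "none"), seed = 1L, ...) {
  phantom_spec(arm,
    matrix = c(48L, 48L), n_slices = 6L,
    r_endo_mm = 11, r_epi_mm = 20,
    noise = noise, seed = seed, ...
  )
}

# image_series with exact mono-exponential decay from given T and A arrays
decay_series <- function(T, A, te, contrast = "t2prep", voxel_size = c(1, 1, 1)) {
  d <- dim(T)
  dat <- array(0, dim = c(d, length(te)))
  for (i in seq_along(te)) {
    s <- ifelse(T > 0, A * exp(-te[i] / T), 0)
    dat[, , , i] <- s
  }
  cmrtc:::new_series(dat, te, contrast, voxel_size)
}

# hand-built parameter_map for boundary-value segmentation tests
fake_map <- function(values, valid = NULL, contrast = "me_gre") {
  valid <- valid %||% array(TRUE, dim = dim(values))
  structure(
    list(
      relaxation_time = values, amplitude = NULL, residual_norm = NULL,
      valid = valid,
      reason = array(ifelse(valid, 0L, 3L), dim = dim(values)),
      contrast_kind = contrast, options = list()
    ),
    class = "parameter_map"
  )
}

fake_remote <- function(mean, sd, t2star_mean = NA_real_) {
  structure(
    list(mask = NULL, t2_mean = mean, t2_sd = sd, t2star_mean = t2star_mean,
      n_valid = 100L),
    class = "remote_reference"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
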