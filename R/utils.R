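# Internal helpers shared across modules.

#' Signal a classed error
#'
#' All package errors carry a class so callers (and the CLI exit-code mapping)
#' can distinguish configuration problems from data problems.
#'
#' @param msg message string.
#' @param class one of "cmrtc_config_error", "cmrtc_data_error",
#'   "cmrtc_dim_error", "cmrtc_undefined_stats", "cmrtc_insufficient_data",
#'   "cmrtc_undefined_slope".
#' @noRd
cmrtc_stop <- function(msg, class = "cmrtc_data_error") {
  stop(structure(
    class = c(class, "cmrtc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' @noRd
check_same_dim <- function(a, b, what = "arrays") {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (length(da) != length(db) || any(da != db)) {
    cmrtc_stop(
      sprintf(
        "grid mismatch for %s: %s vs %s", what,
        paste(da, collapse = "x"), paste(db, collapse = "x")
      ),
      "cmrtc_dim_error"
    )
  }
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Voxel volume in mL
#' @noRd
voxel_ml <- function(voxel_size) prod(voxel_size) / 1000

#' Dice overlap between two logical masks
#'
#' @param a,b logical arrays of identical dimension.
#' @return `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  check_same_dim(a, b, "masks")
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

#' Sample standard deviation that returns 0 (not NA) for n = 1
#' @noRd
sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)

#' Derive a child seed below 2^31 from a base seed and stream index
#' @noRd
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729 + 17) %% 2147483629)
}
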