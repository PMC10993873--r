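# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trapezoidal integral of y sampled at uniform spacing dt
#' @param y numeric vector
#' @param dt sample spacing
#' @return scalar integral
#' @keywords internal
trapz <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  dt * (sum(y) - (y[1L] + y[n]) / 2)
}

# Row-wise trapezoid over a voxels x frames matrix.
trapz_rows <- function(m, dt) {
  n <- ncol(m)
  if (n < 2L) return(numeric(nrow(m)))
  dt * (rowSums(m) - (m[, 1L] + m[, n]) / 2)
}

#' Reflect a 3D array across the midline plane of one axis
#'
#' The midline is the central plane of the grid: index i maps to n + 1 - i.
#' For an even-dimension axis this is an exact voxel permutation with no
#' voxel on the plane itself.
#'
#' @param vol 3D array
#' @param axis axis index (1, 2 or 3) perpendicular to the midline plane
#' @return array of the same shape
#' @export
mirror_volume <- function(vol, axis = 1L) {
  stopifnot(length(dim(vol)) == 3L, axis %in% 1:3)
  idx <- rep(list(quote(expr = )), 3L)
  idx[[axis]] <- rev(seq_len(dim(vol)[axis]))
  do.call(`[`, c(list(vol), idx, list(drop = FALSE)))
}

#' Dice overlap coefficient between two masks
#' @param a,b logical arrays of equal shape
#' @return scalar in [0, 1]; 1 when both masks are empty
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

# Logical ellipsoid mask on a grid, in voxel coordinates.
ellipsoid_mask <- function(shape, center, radii) {
  stopifnot(length(shape) == 3L, length(center) == 3L, length(radii) == 3L,
            all(radii > 0))
  x <- (seq_len(shape[1L]) - center[1L]) / radii[1L]
  y <- (seq_len(shape[2L]) - center[2L]) / radii[2L]
  z <- (seq_len(shape[3L]) - center[3L]) / radii[3L]
  q <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  q <= 1
}

# Set the RNG seed when one is supplied; NULL leaves the stream untouched.
maybe_set_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Consistent grid check.
check_same_grid <- function(...) {
  dims <- lapply(list(...), dim)
  ok <- all(vapply(dims[-1L], identical, logical(1L), y = dims[[1L]]))
  if (!ok) stop("input volumes are not on the same grid", call. = FALSE)
  invisible(TRUE)
}
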