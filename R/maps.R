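#' Fit an ADC map from two-point diffusion-weighted volumes
#'
#' With only two b-values the monoexponential fit is exact per direction:
#' ADC_d = ln(S0 / S_b) / b. The returned map is the arithmetic mean of the
#' per-direction maps. Voxels with a non-positive signal in any used image
#' are excluded from `fit_mask` (dropped, not clipped, to avoid silent
#' bias); negative ADC values arising from noise (S_b > S0) are retained in
#' `values` but flagged in `negative`.
#'
#' @param b0 unweighted (b = 0) volume, 3D array
#' @param b_high a 3D array or list of 3D arrays, one per gradient direction
#' @param b the high b-value in s/mm^2
#' @return list of class `adc_map`: `values` (mm^2/s), `fit_mask`,
#'   `negative`, and `direction_maps`
#' @export
fit_adc <- function(b0, b_high, b) {
  if (!is.list(b_high)) b_high <- list(b_high)
  stopifnot(b > 0)
  do.call(check_same_grid, c(list(b0), b_high))
  dir_maps <- vector("list", length(b_high))
  ok <- b0 > 0
  for (d in seq_along(b_high)) {
    sb <- b_high[[d]]
    ok <- ok & sb > 0
    m <- array(NA_real_, dim = dim(b0))
    w <- b0 > 0 & sb > 0
    m[w] <- log(b0[w] / sb[w]) / b
    dir_maps[[d]] <- m
  }
  values <- Reduce(`+`, dir_maps) / length(dir_maps)
  structure(list(values = values, fit_mask = ok,
                 negative = ok & !is.na(values) & values < 0,
                 direction_maps = dir_maps, b = b),
            class = "adc_map")
}

#' Fit a T2 map from multi-echo volumes by log-linear least squares
#'
#' Per voxel, ordinary (optionally S^2-weighted) least squares of
#' ln S against TE estimates the decay rate 1/T2 from the slope. Echoes
#' with non-positive signal are dropped from that voxel's fit; voxels with
#' fewer than two usable echoes, or with a non-positive estimated decay
#' rate (apparent infinite or negative T2), are excluded from `fit_mask`
#' and flagged. S^2 weighting stabilizes the log-domain variance and
#' approximates the nonlinear least-squares solution; it is off by default.
#'
#' @param echo_volumes list of 3D arrays, one per echo time
#' @param echo_times echo times in ms (>= 2 distinct values)
#' @param weighted use w = S^2 variance-stabilizing weights
#' @return list of class `t2_map`: `values` (ms), `fit_mask`,
#'   `flat` (non-decaying voxels), `sigma` (residual SD of ln S)
#' @export
fit_t2 <- function(echo_volumes, echo_times, weighted = FALSE) {
  stopifnot(is.list(echo_volumes), length(echo_volumes) == length(echo_times),
            length(echo_times) >= 2L)
  if (length(unique(echo_times)) < 2L)
    stop("echo times must contain at least two distinct values")
  do.call(check_same_grid, echo_volumes)
  shape <- dim(echo_volumes[[1L]])
  ne <- length(echo_times)
  S <- vapply(echo_volumes, as.numeric, numeric(prod(shape)))  # nvox x ne

  W <- (S > 0) * 1
  if (weighted) W <- W * S^2
  Y <- log(pmax(S, .Machine$double.xmin))
  Y[S <= 0] <- 0  # weight is zero there

  te <- matrix(echo_times, nrow = nrow(S), ncol = ne, byrow = TRUE)
  sw <- rowSums(W)
  n_used <- rowSums(S > 0)
  usable <- n_used >= 2L & sw > 0
  mx <- rowSums(W * te) / sw
  my <- rowSums(W * Y) / sw
  sxx <- rowSums(W * (te - mx)^2)
  sxy <- rowSums(W * (te - mx) * (Y - my))
  slope <- sxy / sxx
  rate <- -slope  # 1/T2 in 1/ms

  values <- rep(NA_real_, nrow(S))
  good <- usable & is.finite(rate) & rate > 0
  values[good] <- 1 / rate[good]
  flat <- usable & is.finite(rate) & rate <= 0

  # residual SD of the weighted log-linear fit (per voxel)
  fit <- my + slope * (te - mx)
  rss <- rowSums(W * (Y - fit)^2)
  dof <- pmax(n_used - 2, 1)
  sigma <- sqrt(rss / (sw * dof / pmax(n_used, 1)))
  sigma[!usable] <- NA_real_

  structure(list(values = array(values, dim = shape),
                 fit_mask = array(good, dim = shape),
                 flat = array(flat, dim = shape),
                 sigma = array(sigma, dim = shape),
                 echo_times = echo_times, weighted = weighted),
            class = "t2_map")
}
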