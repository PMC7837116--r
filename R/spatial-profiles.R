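#' Mediolateral density profile with a sliding window
#'
#' Counts points (treenodes or synapse positions) in a sliding window of
#' fixed physical width along the mediolateral axis, reports positions
#' normalized to the neuropil width and centered at the midline (midline =
#' 0, domain about \[-0.5, 0.5\]), and optionally normalizes the counts to
#' the maximum density. The window is a closed interval of
#' `window_um / 2` on either side of each grid center.
#'
#' @param x mediolateral point coordinates, nm.
#' @param volume a [volume_spec()] with `midline_x` and `neuropil_width`.
#' @param window_um sliding-window width in um (default 2.5).
#' @param grid_step grid spacing as a fraction of the neuropil width
#'   (default 0.01).
#' @param max_normalize divide by the maximum count (default TRUE; an
#'   empty point set stays all-zero).
#' @return data.frame of class `density_profile` with `position`
#'   (normalized) and `density`; attributes `window_um`, `normalized`,
#'   `max_count`.
#' @export
density_profile <- function(x, volume, window_um = 2.5, grid_step = 0.01,
                            max_normalize = TRUE) {
  stopifnot(window_um > 0, grid_step > 0)
  width <- volume$neuropil_width
  centers_norm <- seq(-0.5, 0.5, by = grid_step)
  centers_nm <- volume$midline_x + centers_norm * width
  half_nm <- window_um * 1000 / 2
  counts <- vapply(centers_nm,
                   function(c0) sum(x >= c0 - half_nm & x <= c0 + half_nm),
                   numeric(1))
  max_count <- max(counts)
  dens <- if (max_normalize && max_count > 0) counts / max_count else counts
  structure(data.frame(position = centers_norm, density = dens),
            class = c("density_profile", "data.frame"),
            window_um = window_um,
            normalized = max_normalize && max_count > 0,
            max_count = max_count)
}

#' Loess-smooth a density profile
#'
#' Locally weighted quadratic regression (tricube weights over the
#' span-nearest neighbors, no robustness iterations), evaluated at the
#' profile's own grid. A constant profile is reproduced exactly and an
#' exact quadratic is reproduced when the span covers all points.
#'
#' @param profile a [density_profile()] (or any data.frame with `position`
#'   and `density`).
#' @param span fraction of points in each local neighborhood (default
#'   0.1).
#' @param degree local polynomial degree (default 2).
#' @return the profile with an added `smoothed` column.
#' @export
loess_smooth <- function(profile, span = 0.1, degree = 2) {
  n <- nrow(profile)
  if (n < max(degree + 2, ceiling(span * n)))
    stop("too few points for loess smoothing")
  fit <- stats::loess(density ~ position, data = profile, span = span,
                      degree = degree, family = "gaussian",
                      surface = "direct")
  profile$smoothed <- stats::predict(fit, newdata = profile)
  profile
}

as_mask_stack <- function(stack) {
  if (is.list(stack)) stack <- simplify2array(stack)
  if (length(dim(stack)) != 3) stop("mask stack must be rows x cols x time")
  stack > 0
}

#' Cumulative exploration area relative to the mature arbor
#'
#' Given an ordered stack of binary arbor masks over developmental time
#' (the last frame being the mature arbor), returns the cumulative area
#' covered at any time as a percentage of the mature area. 100% means no
#' transient coverage beyond the final morphology; values are >= 100 when
#' the mature arbor is contained in the union.
#'
#' @param stack list of binary matrices, or a rows x cols x time array;
#'   the final frame is the mature mask.
#' @return percent (scalar).
#' @export
exploration_ratio <- function(stack) {
  a <- as_mask_stack(stack)
  mature <- a[, , dim(a)[3]]
  if (!any(mature)) stop("mature mask is empty")
  cumulative <- apply(a, c(1, 2), any)
  100 * sum(cumulative) / sum(mature)
}

#' Thresholded mediolateral membrane-distribution profile
#'
#' Binarizes a 3-D intensity volume at a threshold (voxels >= threshold
#' count; the threshold is an explicit parameter, mirroring a manually
#' chosen mask), sums over the Z axis, and averages over the remaining row
#' axis, yielding one value per mediolateral column.
#'
#' @param volume_image 3-D array, rows x columns x Z; columns index the
#'   mediolateral axis.
#' @param threshold intensity threshold.
#' @return numeric vector, one value per column.
#' @export
membrane_profile <- function(volume_image, threshold) {
  if (length(dim(volume_image)) != 3)
    stop("volume_image must be a 3-D array")
  bin <- volume_image >= threshold
  zsum <- apply(bin, c(1, 2), sum)
  colMeans(zsum)
}
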