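#' Radial index of a colony
#'
#' Deviation of the radial occupancy profile from complete spatial
#' randomness (CSR). The disc of maximum radius R about the centroid is
#' partitioned into `bins` equal-width annuli; the per-annulus occupancy
#' probability (occupied count / annulus area in pixels) is compared with
#' the CSR reference density N / (pi R^2). R_CSR is the outer edge of the
#' outermost annulus whose occupancy probability still meets the CSR
#' reference — colonies are dense centrally and rarefy outward — and the
#' radial index is I_r = 1 - R_CSR / R, clamped to \[0, 1\]. A filled disc
#' gives I_r near 0; long radial filaments push R beyond R_CSR and I_r up.
#'
#' @param image a [binary_image].
#' @param bins number of annuli (default 178).
#' @return List with `I_r` and `R_csr` (pixels).
#' @export
radial_index <- function(image, bins = 178) {
  stopifnot(inherits(image, "binary_image"))
  cen <- occupied_centres(image$pixels)
  centroid <- colMeans(cen)
  r <- sqrt(rowSums(sweep(cen, 2, centroid)^2))
  R <- max(r)
  if (R <= 0) return(list(I_r = 0, R_csr = 0))
  breaks <- seq(0, R, length.out = bins + 1L)
  k <- pmin(pmax(findInterval(r, breaks, rightmost.closed = TRUE), 1L), bins)
  counts <- tabulate(k, nbins = bins)
  area <- pi * diff(breaks^2)
  ref <- nrow(cen) / (pi * R^2)
  meets <- which(counts / area >= ref)
  R_csr <- if (length(meets)) breaks[max(meets) + 1L] else 0
  list(I_r = min(max(1 - R_csr / R, 0), 1), R_csr = R_csr)
}

#' Angular index of a colony
#'
#' Variance of the CSR-normalized angular occupancy. The angles of all
#' occupied pixel centres about the centroid (from the x-axis) are binned
#' into `bins` equal bins over \[0, 2*pi); each count is divided by its CSR
#' expectation N / bins and I_theta is the population variance of the
#' normalized counts. Zero for angularly uniform colonies; large when mass
#' concentrates in a few directions.
#'
#' @param image a [binary_image].
#' @param bins number of angular bins (default 200).
#' @return Scalar `I_theta` >= 0.
#' @export
angular_index <- function(image, bins = 200) {
  stopifnot(inherits(image, "binary_image"))
  cen <- occupied_centres(image$pixels)
  if (nrow(cen) < 2L) {
    warning("degenerate colony (single pixel): angular index is 0", call. = FALSE)
    return(0)
  }
  centroid <- colMeans(cen)
  theta <- atan2(cen[, "y"] - centroid["y"], cen[, "x"] - centroid["x"]) %% (2 * pi)
  k <- pmin(floor(theta / (2 * pi / bins)) + 1L, bins)
  norm <- tabulate(k, nbins = bins) / (nrow(cen) / bins)
  mean((norm - mean(norm))^2)
}

#' Angular pair-correlation index of a colony
#'
#' Local angular aggregation measured through the angular pair-correlation
#' function F_Theta. Up to `sample` occupied pixels are drawn without
#' replacement (all pixels when fewer exist); every pairwise absolute
#' angular separation about the centroid, folded onto \[0, pi\], is binned
#' into `bins` equal bins and normalized by the expected pair count under
#' independent uniform angles (the folded separation of two independent
#' uniform angles is itself uniform on \[0, pi\], so the expectation is
#' n_pairs / bins per bin). The index is the first-bin excess
#' I_Theta = F_Theta(1) - 1: zero under CSR, positive when nearby angular
#' separations are over-represented (pixels aggregate in narrow sectors).
#'
#' @param image a [binary_image].
#' @param bins number of separation bins (default 200).
#' @param sample number of pixels to sample (default 1000).
#' @param seed integer seed for the pixel sample (required for
#'   reproducibility).
#' @return List with `I_Theta` and the length-`bins` profile `F_Theta`.
#' @export
pair_correlation_index <- function(image, bins = 200, sample = 1000, seed = 1L) {
  stopifnot(inherits(image, "binary_image"))
  cen <- occupied_centres(image$pixels)
  if (nrow(cen) < 2L) stop("pair-correlation index needs at least 2 occupied pixels")
  centroid <- colMeans(cen)
  n <- min(sample, nrow(cen))
  idx <- if (n < nrow(cen)) {
    withr::with_seed(seed, sample.int(nrow(cen), n))
  } else seq_len(nrow(cen))
  theta <- atan2(cen[idx, "y"] - centroid["y"], cen[idx, "x"] - centroid["x"])
  dmat <- abs(outer(theta, theta, "-"))
  d <- dmat[upper.tri(dmat)]
  d <- pmin(d, 2 * pi - d)  # fold onto [0, pi]
  k <- pmin(floor(d / (pi / bins)) + 1L, bins)
  F_Theta <- tabulate(k, nbins = bins) / (length(d) / bins)
  list(I_Theta = F_Theta[1L] - 1, F_Theta = F_Theta)
}

#' All three spatial indices of a colony
#'
#' Convenience wrapper returning the radial, angular and pair-correlation
#' indices with the default binning (178 / 200 / 200 bins, 1000 sampled
#' pixels for the pair-correlation index).
#'
#' @inheritParams pair_correlation_index
#' @param radial_bins,angular_bins,pc_bins bin counts for the three indices.
#' @return List with `I_r`, `R_csr`, `I_theta`, `I_Theta`, `F_Theta`.
#' @export
spatial_indices <- function(image, seed = 1L, radial_bins = 178,
                            angular_bins = 200, pc_bins = 200, sample = 1000) {
  rad <- radial_index(image, bins = radial_bins)
  pc <- pair_correlation_index(image, bins = pc_bins, sample = sample, seed = seed)
  list(I_r = rad$I_r, R_csr = rad$R_csr,
       I_theta = angular_index(image, bins = angular_bins),
       I_Theta = pc$I_Theta, F_Theta = pc$F_Theta)
}
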