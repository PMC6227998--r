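#' Equally spaced chord angles
#'
#' The angles phi_d = (d - 1) * pi / D for d = 1..D, measured from the
#' horizontal axis. D = 4 gives (0, pi/4, pi/2, 3*pi/4).
#'
#' @param D positive integer number of angles.
#' @return Numeric vector of length `D`, strictly increasing in \[0, pi).
#' @export
angle_set <- function(D) {
  if (!is.numeric(D) || length(D) != 1L || D < 1 || D != round(D))
    stop("`D` must be a positive integer")
  (seq_len(D) - 1) * pi / D
}

#' Longest chord through a pixel centre at a given angle
#'
#' Length of the maximal connected segment of the line through the pixel's
#' centre at angle `phi` that contains the centre and lies entirely inside
#' the occupied region, modelled as the union of closed unit pixel squares.
#' The segment is measured continuously (not as a pixel count): for a 3 x 3
#' filled square the long diagonal through a corner pixel is 3*sqrt(2).
#' Chords are truncated at the raster edge. For concave shapes the line may
#' re-enter the region elsewhere; only the run containing the centre counts.
#'
#' @param image a [binary_image].
#' @param p integer vector `c(row, col)` of an occupied pixel (an error is
#'   raised for unoccupied pixels).
#' @param phi angle in radians in \[0, pi).
#' @return Chord length in pixels (>= 1 for any occupied pixel).
#' @export
chord_length <- function(image, p, phi) {
  stopifnot(inherits(image, "binary_image"), length(p) == 2L)
  drop(chord_lengths_cpp(image$pixels, as.integer(p[1]), as.integer(p[2]),
                         as.numeric(phi)))
}

#' Shape primitives for a set of boundary pixels
#'
#' For each boundary pixel the D chord lengths at the angles of
#' [angle_set()] are measured in pixels and converted to micrometres with
#' the linear factor `sqrt(resolution)` (the resolution is an area per
#' pixel, so its square root is the pixel side length in micrometres).
#'
#' @param image a [binary_image].
#' @param D number of chord angles (4 by default; 12 also supported).
#' @param pixels optional integer matrix of (row, col) pixels; defaults to
#'   [boundary_pixels()] of the image.
#' @return Object of class `shape_primitives`: a list with `image_id`,
#'   `group_label`, `resolution`, `D`, `angles`, `pixels` (n x 2),
#'   `lengths_px` and `lengths_um` (n x D matrices).
#' @export
shape_primitives <- function(image, D = 4, pixels = NULL) {
  stopifnot(inherits(image, "binary_image"))
  angles <- angle_set(D)
  if (is.null(pixels)) pixels <- boundary_pixels(image)
  if (nrow(pixels) == 0L) stop("no boundary pixels")
  lp <- chord_lengths_cpp(image$pixels, as.integer(pixels[, 1]),
                          as.integer(pixels[, 2]), angles)
  structure(
    list(image_id = image$image_id, group_label = image$group_label,
         resolution = image$resolution, D = D, angles = angles,
         pixels = pixels, lengths_px = lp,
         lengths_um = lp * sqrt(image$resolution)),
    class = "shape_primitives")
}

#' Shape primitive for a single boundary pixel
#'
#' @inheritParams shape_primitives
#' @param p integer `c(row, col)` boundary pixel.
#' @return List with `pixel`, `lengths_px`, `lengths_um`.
#' @export
shape_primitive <- function(image, p, D = 4) {
  sp <- shape_primitives(image, D = D, pixels = matrix(as.integer(p), 1))
  list(pixel = p, lengths_px = drop(sp$lengths_px),
       lengths_um = drop(sp$lengths_um))
}

#' @export
print.shape_primitives <- function(x, ...) {
  cat(sprintf("<shape_primitives> %s: %d boundary pixels, D = %d\n",
              x$image_id, nrow(x$pixels), x$D))
  invisible(x)
}

#' @export
as.data.frame.shape_primitives <- function(x, ...) {
  lens <- as.data.frame(x$lengths_um)
  names(lens) <- paste0("phi_", seq_len(x$D))
  cbind(data.frame(image_id = x$image_id, row = x$pixels[, 1],
                   col = x$pixels[, 2]), lens)
}

#' Representation space of a group of images
#'
#' Concatenates the physical-unit shape primitives over all boundary pixels
#' of all images in a group, retaining image provenance. k-means clustering
#' of this multiset yields the group's clustered shape primitives.
#'
#' @param images list of [binary_image] objects (one group).
#' @param D number of chord angles.
#' @return List with `lengths_um` (N x D matrix), `image_id` (length-N
#'   character) and `D`.
#' @export
representation_space <- function(images, D = 4) {
  if (length(images) == 0L) stop("empty group: no images")
  sps <- lapply(images, shape_primitives, D = D)
  list(lengths_um = do.call(rbind, lapply(sps, `[[`, "lengths_um")),
       image_id = unlist(lapply(sps, function(s) rep(s$image_id, nrow(s$pixels)))),
       D = D)
}
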