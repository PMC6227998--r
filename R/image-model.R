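#' Construct a binary colony image
#'
#' The unit every descriptor in this package is computed from: an occupancy
#' grid together with the physical resolution of the raster and a group
#' label. Pixel (row r, col c) is taken to cover the closed unit square
#' \[c-1, c\] x \[r-1, r\] in a continuous plane with x rightward and y
#' downward, so its centre sits at (c - 0.5, r - 0.5). All chord and
#' centroid geometry uses this convention.
#'
#' @param pixels logical (or coercible numeric) matrix; `TRUE`/nonzero =
#'   occupied.
#' @param resolution positive scalar, image resolution in square micrometres
#'   per pixel. Linear distances convert as `sqrt(resolution)` micrometres
#'   per pixel side.
#' @param group_label character group/class label.
#' @param image_id character identifier; defaults to `"image"`.
#' @return An object of class `binary_image`.
#' @export
binary_image <- function(pixels, resolution = 1, group_label = "",
                         image_id = "image") {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (is.numeric(pixels)) pixels <- pixels != 0
  if (!is.logical(pixels)) stop("`pixels` must be logical or numeric")
  pixels[is.na(pixels)] <- FALSE
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("image must be at least 1 x 1")
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("`resolution` must be a positive scalar (μm² per pixel)")
  if (!any(pixels)) stop("empty colony: mask has no occupied pixels")
  img <- structure(
    list(pixels = pixels, resolution = as.numeric(resolution),
         group_label = as.character(group_label),
         image_id = as.character(image_id)),
    class = "binary_image")
  if (touches_border(pixels))
    warning("colony touches the raster border; chords are truncated at the edge",
            call. = FALSE)
  img
}

touches_border <- function(px) {
  any(px[1, ]) || any(px[nrow(px), ]) || any(px[, 1]) || any(px[, ncol(px)])
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image> %s [%s]: %d x %d px, %d occupied, %.3g um^2/px\n",
              x$image_id, x$group_label, nrow(x$pixels), ncol(x$pixels),
              sum(x$pixels), x$resolution))
  invisible(x)
}

#' Load a binary mask from a PNG or TIFF file
#'
#' Nonzero raster values map to occupied; for multi-channel rasters a pixel
#' is occupied if any channel is nonzero (equivalent to thresholding the
#' grayscale reduction at zero). The image id is derived from the filename.
#'
#' @param path path to a PNG or TIFF file.
#' @inheritParams binary_image
#' @return A [binary_image].
#' @export
load_mask <- function(path, resolution, group_label = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raster <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format '", ext, "' (use PNG or TIFF)"))
  if (length(dim(raster)) == 3L) {
    raster <- apply(raster != 0, c(1, 2), any)
  } else if (length(dim(raster)) != 2L) {
    stop("mask raster must be 2-D (grayscale) or 2-D multi-channel")
  }
  binary_image(raster != 0, resolution = resolution, group_label = group_label,
               image_id = tools::file_path_sans_ext(basename(path)))
}

#' Load a directory of masks described by a sidecar configuration
#'
#' The sidecar (JSON or YAML) maps mask filenames to their resolution and
#' group, e.g. `{"colony1.png": {"resolution": 1.52, "group": "A7-50"}}`.
#'
#' @param dir directory containing the mask files and the sidecar.
#' @param config filename of the sidecar within `dir`.
#' @return List of [binary_image] objects.
#' @export
load_dataset <- function(dir, config = "dataset.json") {
  cfg_path <- file.path(dir, config)
  if (!file.exists(cfg_path)) stop("sidecar config not found: ", cfg_path)
  ext <- tolower(tools::file_ext(cfg_path))
  cfg <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(cfg_path)
         else jsonlite::read_json(cfg_path)
  lapply(names(cfg), function(fn) {
    entry <- cfg[[fn]]
    if (is.null(entry$resolution) || is.null(entry$group))
      stop("sidecar entry for '", fn, "' needs `resolution` and `group`")
    load_mask(file.path(dir, fn), resolution = entry$resolution,
              group_label = entry$group)
  })
}

#' Boundary pixels of a binary image
#'
#' A pixel belongs to the boundary when it is occupied and at least one of
#' its 4-neighbours (up/down/left/right) is unoccupied or off the grid. The
#' 4-neighbour exterior test is the convention under which a 3 x 3 filled
#' square has exactly 8 boundary pixels (the centre, all of whose
#' 4-neighbours are occupied, is interior).
#'
#' @param image a [binary_image].
#' @return Integer matrix with columns `row`, `col`, rows in row-major order
#'   (by row, then column).
#' @export
boundary_pixels <- function(image) {
  stopifnot(inherits(image, "binary_image"))
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  pad <- function(drow, dcol) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + drow; cs <- seq_len(nc) + dcol
    ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
    out[ok_r, ok_c] <- px[rs[ok_r], cs[ok_c], drop = FALSE]
    out
  }
  interior <- pad(-1L, 0L) & pad(1L, 0L) & pad(0L, -1L) & pad(0L, 1L)
  boundary <- px & !interior
  idx <- which(t(boundary))  # t() so that which() runs row-major
  cbind(row = (idx - 1L) %/% nc + 1L, col = (idx - 1L) %% nc + 1L)
}

#' Centroid and maximum radius of a colony
#'
#' The centroid is the unweighted mean of the occupied pixel centres; the
#' maximum radius R is the largest Euclidean distance from the centroid to
#' an occupied pixel centre.
#'
#' @param image a [binary_image].
#' @return List with `centroid` (x, y in pixel units), `radius_px` and
#'   `radius_um`.
#' @export
colony_geometry <- function(image) {
  stopifnot(inherits(image, "binary_image"))
  cen <- occupied_centres(image$pixels)
  centroid <- colMeans(cen)
  R <- sqrt(max(rowSums(sweep(cen, 2, centroid)^2)))
  list(centroid = centroid, radius_px = R,
       radius_um = R * sqrt(image$resolution))
}

# occupied pixel centres as an n x 2 matrix of (x, y) continuous coordinates
occupied_centres <- function(px) {
  idx <- which(px, arr.ind = TRUE)
  cbind(x = idx[, "col"] - 0.5, y = idx[, "row"] - 0.5)
}

#' Number of 4-connected occupied components
#'
#' Iterative label propagation on the occupancy grid. Used to warn when a
#' mask holds more than one component (all components are retained).
#'
#' @param image a [binary_image] or logical matrix.
#' @return Integer component count.
#' @export
count_components <- function(image) {
  px <- if (inherits(image, "binary_image")) image$pixels else image
  nr <- nrow(px); nc <- ncol(px)
  lab <- matrix(0L, nr, nc)
  lab[px] <- seq_len(sum(px))  # unique seeds; propagate the minimum label
  shift <- function(m, drow, dcol) {
    out <- matrix(Inf, nr, nc)
    rs <- seq_len(nr) + drow; cs <- seq_len(nc) + dcol
    ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c], drop = FALSE]
    out
  }
  cur <- matrix(Inf, nr, nc); cur[px] <- lab[px]
  repeat {
    nxt <- pmin(cur, shift(cur, -1L, 0L), shift(cur, 1L, 0L),
                shift(cur, 0L, -1L), shift(cur, 0L, 1L))
    nxt[!px] <- Inf
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  length(unique(cur[px]))
}
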