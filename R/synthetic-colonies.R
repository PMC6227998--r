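#' Parameters for a synthetic filamentous colony
#'
#' Describes a roughly circular dense core with radial filamentous
#' protrusions, the morphology of pseudohyphal yeast colonies viewed
#' top-down: a disc core plus `n_filaments` thick radial segments whose
#' lengths follow a truncated normal. Filament directions are evenly
#' spaced around the circle (with a random global rotation); angular
#' anisotropy is controlled by `angular_jitter`, the dispersion of a
#' per-direction log-normal growth multiplier on filament length
#' (`exp(angular_jitter * z)` with `z` standard normal truncated to
#' \[-2, 1\]): 0 develops every direction equally, larger values
#' concentrate boundary mass in a few well-developed directions, raising
#' the angular non-uniformity the angular index measures. Validation
#' requires the core plus the longest admissible filament,
#' `(mean + 4 sd) * exp(angular_jitter)`, to fit in the image with at
#' least a 2-pixel margin.
#'
#' @param core_radius core disc radius in pixels.
#' @param n_filaments number of filaments (>= 0).
#' @param filament_length mean filament length in pixels.
#' @param filament_sd standard deviation of filament length (pixels).
#' @param filament_width filament thickness in pixels (>= 2 so rasterized
#'   filaments stay connected).
#' @param angular_jitter angular anisotropy (dimensionless, >= 0): sd of
#'   the per-direction log-normal growth multiplier on filament length.
#' @param branching_prob probability that a filament carries one side
#'   branch of half its length.
#' @param image_size side of the square raster in pixels.
#' @param resolution image resolution in square micrometres per pixel.
#' @return Validated list of class `colony_params`.
#' @export
colony_params <- function(core_radius = 40, n_filaments = 10,
                          filament_length = 60, filament_sd = 8,
                          filament_width = 3, angular_jitter = 0.2,
                          branching_prob = 0, image_size = 512,
                          resolution = 1) {
  p <- list(core_radius = core_radius, n_filaments = n_filaments,
            filament_length = filament_length, filament_sd = filament_sd,
            filament_width = filament_width, angular_jitter = angular_jitter,
            branching_prob = branching_prob, image_size = image_size,
            resolution = resolution)
  if (core_radius <= 0 || filament_width < 2 || image_size < 8 ||
      resolution <= 0 || filament_length <= 0 || filament_sd <= 0)
    stop("invalid colony parameters: scales must be positive, width >= 2")
  if (n_filaments < 0 || n_filaments != round(n_filaments))
    stop("`n_filaments` must be a non-negative integer")
  if (branching_prob < 0 || branching_prob > 1)
    stop("`branching_prob` must lie in [0, 1]")
  if (angular_jitter < 0) stop("`angular_jitter` must be >= 0")
  lmax <- (filament_length + 4 * filament_sd) * exp(angular_jitter)
  if (n_filaments > 0 && core_radius + lmax > image_size / 2 - 2)
    stop("filaments exceed the image bounds: core + longest filament ",
         "must fit with a 2-pixel margin")
  if (n_filaments == 0 && core_radius > image_size / 2 - 2)
    stop("core exceeds the image bounds")
  structure(p, class = "colony_params")
}

#' Generate one synthetic colony mask
#'
#' Rasterizes the core disc and filaments of a [colony_params()]
#' specification. Filament lengths are drawn from a normal truncated to
#' \[0, mean + 4 sd\]; each filament is a thick segment starting just
#' inside the core (so the mask is one 4-connected component) and may,
#' with `branching_prob`, carry one half-length side branch. Deterministic
#' given `seed`.
#'
#' @param params a [colony_params()].
#' @param seed integer seed.
#' @param group_label,image_id labels for the resulting image.
#' @return A [binary_image].
#' @export
generate_colony <- function(params, seed = 1L, group_label = "synthetic",
                            image_id = "synthetic") {
  stopifnot(inherits(params, "colony_params"))
  n <- params$image_size
  cx <- n / 2; cy <- n / 2
  xs <- matrix(rep(seq_len(n) - 0.5, each = n), n)   # centre x per pixel
  ys <- matrix(rep(seq_len(n) - 0.5, times = n), n)  # centre y per pixel
  px <- (xs - cx)^2 + (ys - cy)^2 <= params$core_radius^2
  if (params$n_filaments > 0) {
    px <- withr::with_seed(seed, {
      nf <- params$n_filaments
      base <- (seq_len(nf) - 1) * 2 * pi / nf
      angles <- (base + runif(1, 0, 2 * pi)) %% (2 * pi)
      lmax <- params$filament_length + 4 * params$filament_sd
      lens <- pmin(pmax(rnorm(nf, params$filament_length,
                              params$filament_sd), 1), lmax)
      # per-direction growth variability (angular anisotropy)
      z <- pmin(pmax(rnorm(nf), -2), 1)
      lens <- lens * exp(params$angular_jitter * z)
      branch <- runif(params$n_filaments) < params$branching_prob
      for (i in seq_len(params$n_filaments)) {
        r0 <- max(params$core_radius - 2, 0)
        x1 <- cx + r0 * cos(angles[i]); y1 <- cy + r0 * sin(angles[i])
        x2 <- cx + (r0 + lens[i]) * cos(angles[i])
        y2 <- cy + (r0 + lens[i]) * sin(angles[i])
        px <- px | stamp_segment(n, x1, y1, x2, y2, params$filament_width / 2)
        if (branch[i]) {
          bt <- runif(1, 0.3, 0.7)  # branch point along the filament
          ba <- angles[i] + sample(c(-1, 1), 1) * (pi / 6 + rnorm(1, 0, 0.1))
          bx <- x1 + bt * (x2 - x1); by <- y1 + bt * (y2 - y1)
          bl <- lens[i] / 2
          px <- px | stamp_segment(n, bx, by, bx + bl * cos(ba),
                                   by + bl * sin(ba), params$filament_width / 2)
        }
      }
      px
    })
  }
  binary_image(px, resolution = params$resolution, group_label = group_label,
               image_id = image_id)
}

# pixels whose centre lies within `hw` of the segment (x1,y1)-(x2,y2)
stamp_segment <- function(n, x1, y1, x2, y2, hw) {
  r0 <- max(1L, floor(min(y1, y2) - hw)); r1 <- min(n, ceiling(max(y1, y2) + hw))
  c0 <- max(1L, floor(min(x1, x2) - hw)); c1 <- min(n, ceiling(max(x1, x2) + hw))
  out <- matrix(FALSE, n, n)
  if (r0 > r1 || c0 > c1) return(out)
  rows <- r0:r1; cols <- c0:c1
  X <- matrix(rep(cols - 0.5, each = length(rows)), length(rows))
  Y <- matrix(rep(rows - 0.5, times = length(cols)), length(rows))
  vx <- x2 - x1; vy <- y2 - y1
  L2 <- vx^2 + vy^2
  t <- if (L2 > 0) pmin(pmax(((X - x1) * vx + (Y - y1) * vy) / L2, 0), 1) else 0
  d2 <- (X - (x1 + t * vx))^2 + (Y - (y1 + t * vy))^2
  out[rows, cols] <- d2 <= hw^2
  out
}

#' Group specification for a synthetic dataset
#'
#' @param name group label.
#' @param params a [colony_params()] shared by all images of the group.
#' @param n_images number of images (>= 1).
#' @return List of class `group_spec`.
#' @export
group_spec <- function(name, params, n_images) {
  stopifnot(inherits(params, "colony_params"))
  if (n_images < 1) stop("`n_images` must be >= 1")
  structure(list(name = name, params = params, n_images = n_images),
            class = "group_spec")
}

#' Built-in group presets
#'
#' Three presets mimicking the morphological regimes of pseudohyphal
#' yeast colonies grown as two strains at two nutrient concentrations:
#' `a7_50` (10 images, long sparse filaments, 1.52 μm²/px), `a7_500`
#' (9 images, a short dense fringe from ample nutrient, 1.55 μm²/px) and
#' `ar_50` (10 images, intermediate filaments, 1.53 μm²/px). The filament
#' length regimes are disjoint (mean differences exceed 5 sd), so the
#' presets are separable by the full pipeline and serve as the package's
#' reference experiment.
#'
#' @return Named list of [group_spec()] objects.
#' @export
colony_presets <- function() {
  list(
    a7_50 = group_spec("a7_50", colony_params(
      core_radius = 40, n_filaments = 24, filament_length = 125,
      filament_sd = 10, filament_width = 3, angular_jitter = 0.2,
      image_size = 512, resolution = 1.52), 10),
    a7_500 = group_spec("a7_500", colony_params(
      core_radius = 40, n_filaments = 48, filament_length = 15,
      filament_sd = 3, filament_width = 4, angular_jitter = 0.35,
      image_size = 512, resolution = 1.55), 9),
    ar_50 = group_spec("ar_50", colony_params(
      core_radius = 40, n_filaments = 24, filament_length = 60,
      filament_sd = 8, filament_width = 3, angular_jitter = 0.2,
      image_size = 512, resolution = 1.53), 10))
}

#' Generate a labelled multi-group dataset
#'
#' @param specs list of [group_spec()] objects (or names of
#'   [colony_presets()]).
#' @param seed master seed; per-image seeds are derived from it.
#' @return List of [binary_image] objects with group labels set.
#' @export
generate_grouped_dataset <- function(specs, seed = 1L) {
  if (length(specs) == 0L) stop("at least one group spec is required")
  if (is.character(specs)) {
    presets <- colony_presets()
    missing <- setdiff(specs, names(presets))
    if (length(missing)) stop("unknown preset(s): ", paste(missing, collapse = ", "))
    specs <- presets[specs]
  }
  total <- sum(vapply(specs, `[[`, numeric(1), "n_images"))
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, total))
  out <- list(); s <- 0L
  for (sp in specs) {
    stopifnot(inherits(sp, "group_spec"))
    for (i in seq_len(sp$n_images)) {
      s <- s + 1L
      out[[s]] <- generate_colony(sp$params, seed = seeds[s],
                                  group_label = sp$name,
                                  image_id = sprintf("%s_%02d", sp$name, i))
    }
  }
  out
}

#' Write a synthetic dataset as PNG masks plus a sidecar config
#'
#' Produces the on-disk layout consumed by [load_dataset()]: one PNG per
#' image and a JSON sidecar mapping filenames to resolution and group.
#'
#' @param images list of [binary_image] objects.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(images, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list()
  for (img in images) {
    fn <- paste0(img$image_id, ".png")
    png::writePNG(img$pixels * 1, file.path(dir, fn))
    cfg[[fn]] <- list(resolution = img$resolution, group = img$group_label)
  }
  jsonlite::write_json(cfg, file.path(dir, "dataset.json"), auto_unbox = TRUE)
  invisible(dir)
}
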