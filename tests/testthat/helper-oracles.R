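# Independent oracles and fixture builders used across the suite.

# Point membership in the closed union of occupied unit squares: a point on
# a shared edge/corner belongs to every adjacent square, so all candidate
# cells within an epsilon are checked.
inside_closed <- function(px, x, y) {
  nr <- nrow(px); nc <- ncol(px)
  ok <- rep(FALSE, length(x))
  for (dy in c(-1e-9, 1e-9)) {
    for (dx in c(-1e-9, 1e-9)) {
      r <- floor(y + dy) + 1L
      cc <- floor(x + dx) + 1L
      good <- which(r >= 1L & r <= nr & cc >= 1L & cc <= nc)
      if (length(good))
        ok[good] <- ok[good] | px[cbind(r[good], cc[good])]
    }
  }
  ok
}

# Dense-sampling chord oracle: walk outward from the pixel centre in steps
# of `step` px in both directions and stop at the first sample outside the
# closed union (or the grid). Accurate to ~2 * step.
oracle_chord <- function(px, p, phi, step = 0.01) {
  x0 <- p[2] - 0.5; y0 <- p[1] - 0.5
  dmax <- sqrt(nrow(px)^2 + ncol(px)^2) + 1
  ts <- seq(step, dmax, by = step)
  half <- function(sgn) {
    ins <- inside_closed(px, x0 + sgn * ts * cos(phi), y0 + sgn * ts * sin(phi))
    first_out <- which(!ins)[1L]
    if (is.na(first_out)) dmax else ts[first_out] - step
  }
  half(1) + half(-1)
}

# Brute-force boundary oracle: occupied pixels with a 4-neighbour that is
# unoccupied or off the grid, scanned pixel by pixel.
oracle_boundary <- function(px) {
  out <- NULL
  for (r in seq_len(nrow(px))) for (cc in seq_len(ncol(px))) {
    if (!px[r, cc]) next
    nb <- rbind(c(r - 1, cc), c(r + 1, cc), c(r, cc - 1), c(r, cc + 1))
    ext <- apply(nb, 1, function(q)
      q[1] < 1 || q[1] > nrow(px) || q[2] < 1 || q[2] > ncol(px) ||
        !px[q[1], q[2]])
    if (any(ext)) out <- rbind(out, c(r, cc))
  }
  out
}

# Random blob mask: union of a few random discs, guaranteed non-empty and
# away from the raster border.
random_blob <- function(n = 32, n_discs = 3, seed = 1) {
  withr::with_seed(seed, {
    px <- matrix(FALSE, n, n)
    xs <- matrix(rep(seq_len(n) - 0.5, each = n), n)
    ys <- matrix(rep(seq_len(n) - 0.5, times = n), n)
    for (i in seq_len(n_discs)) {
      cx <- runif(1, n * 0.3, n * 0.7)
      cy <- runif(1, n * 0.3, n * 0.7)
      rad <- runif(1, 2, n * 0.2)
      px <- px | ((xs - cx)^2 + (ys - cy)^2 <= rad^2)
    }
    px
  })
}

# 90-degree anticlockwise-in-display rotation of a mask (row/col transpose
# convention is irrelevant to the multiset property being tested).
rotate90 <- function(px) t(px)[ncol(px):1, , drop = FALSE]

# Lexicographic row sort, for comparing primitive multisets.
sort_rows <- function(m) m[do.call(order, as.data.frame(m)), , drop = FALSE]

# Small, fast synthetic groups for classification tests: same structure as
# the full presets but 128 px images so that k-means runs in milliseconds.
small_groups <- function(n_per_group = 6, seed = 1,
                         lengths = c(a = 30, b = 10),
                         n_filaments = c(a = 8, b = 20)) {
  specs <- lapply(names(lengths), function(g)
    group_spec(g, colony_params(core_radius = 12,
                                n_filaments = n_filaments[[g]],
                                filament_length = lengths[[g]],
                                filament_sd = lengths[[g]] / 8,
                                filament_width = 2, image_size = 144),
               n_per_group))
  generate_grouped_dataset(specs, seed = seed)
}

# Uniform-random CSR disc: N occupied pixels sampled uniformly inside a
# disc of the given radius (the null model all three indices compare to).
csr_disc <- function(N = 5000, radius = 90, size = 200, seed = 1) {
  withr::with_seed(seed, {
    px <- matrix(FALSE, size, size)
    got <- 0L
    while (got < N) {
      x <- runif(2 * N, -radius, radius)
      y <- runif(2 * N, -radius, radius)
      keep <- x^2 + y^2 <= radius^2
      r <- pmin(pmax(floor(y[keep] + size / 2) + 1L, 1L), size)
      cc <- pmin(pmax(floor(x[keep] + size / 2) + 1L, 1L), size)
      px[cbind(r, cc)] <- TRUE
      got <- sum(px)
    }
    # trim to exactly N occupied pixels for a fair CSR reference
    occ <- which(px)
    if (length(occ) > N) px[sample(occ, length(occ) - N)] <- FALSE
    px
  })
}
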