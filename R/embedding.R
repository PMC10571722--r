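# The embedded-WSI-map encoding: per-window counts of the three merged cell
# classes, fixed-resolution model inputs, normalization and augmentation.

#' Build the 3-channel embedded WSI map
#'
#' Counts, for every half-open `window_size` x `window_size` pixel window,
#' the nuclei of each merged class whose centroid falls inside it. With the
#' default 64-px window this is the 64-fold lateral reduction of the slide.
#' Channel order is (neoplastic, inflammatory, miscellaneous).
#'
#' @param table a class-mapped `nuclei_table`.
#' @param window_size window edge in pixels (default 64).
#' @return An `embedded_map`: list with `counts` (array `3 x H_w x W_w`),
#'   `window_size`, `channel_order`, `slide_width`, `slide_height`.
#' @export
build_embedded_map <- function(table, window_size = 64) {
  stopifnot(inherits(table, "nuclei_table"))
  if (!isTRUE(table$mapped))
    stop("table must be class-mapped first (see map_classes)")
  if (window_size <= 0) stop("window_size must be positive")
  wn <- as.integer(ceiling(table$slide_width / window_size))
  hn <- as.integer(ceiling(table$slide_height / window_size))
  counts <- array(0L, dim = c(3L, hn, wn))
  rec <- table$records
  if (nrow(rec) > 0) {
    ci <- as.integer(rec$merged_class)                 # 1..3
    wi <- floor(rec$centroid_y / window_size)          # 0-based window row
    wj <- floor(rec$centroid_x / window_size)          # 0-based window col
    idx <- ci + 3 * (wi + as.numeric(hn) * wj)         # 1-based linear index
    tab <- tabulate(idx, nbins = 3L * hn * wn)
    counts <- array(as.integer(tab), dim = c(3L, hn, wn))
  }
  structure(list(counts = counts, window_size = window_size,
                 channel_order = MERGED_CLASSES,
                 slide_width = table$slide_width,
                 slide_height = table$slide_height),
            class = "embedded_map")
}

#' @export
print.embedded_map <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("embedded_map: 3 x %d x %d windows of %d px; channel sums: %s\n",
              d[2], d[3], x$window_size,
              paste(sprintf("%s=%g", x$channel_order,
                            apply(x$counts, 1, sum)), collapse = ", ")))
  invisible(x)
}

# internal: 1-D area-overlap weight matrix mapping `n_in` unit cells onto
# `n_out` output cells. Column sums are 1, so count mass is conserved
# exactly for any resize factor.
area_weights <- function(n_out, n_in) {
  s <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * s
    hi <- i * s
    k0 <- floor(lo)
    k1 <- min(ceiling(hi), n_in)
    for (k in (k0 + 1):k1) {
      ov <- min(hi, k) - max(lo, k - 1)
      if (ov > 0) W[i, k] <- ov
    }
  }
  W
}

#' Resize an embedded map to the model input resolution
#'
#' Default mode `"area"` uses area-overlap pooling/interpolation: each input
#' window's count is distributed over the output cells it geometrically
#' overlaps, so the total count is preserved exactly at any scale factor
#' (an exact 2x reduction sums 2x2 blocks). Mode `"bilinear"` interpolates
#' values instead and does not preserve mass.
#'
#' @param map an `embedded_map` (or a bare `3 x h x w` array).
#' @param resolution output edge length (default 256).
#' @param mode `"area"` (default) or `"bilinear"`.
#' @return Numeric array `3 x resolution x resolution`.
#' @export
resize_to_input <- function(map, resolution = 256, mode = c("area", "bilinear")) {
  mode <- match.arg(mode)
  grid <- if (inherits(map, "embedded_map")) map$counts else map
  stopifnot(length(dim(grid)) == 3, dim(grid)[1] == 3)
  if (resolution <= 0) stop("resolution must be a positive integer")
  h <- dim(grid)[2]; w <- dim(grid)[3]
  if (h == 0 || w == 0) stop("map is empty")
  out <- array(0, dim = c(3, resolution, resolution))
  if (mode == "area") {
    Wr <- area_weights(resolution, h)
    Wc <- area_weights(resolution, w)
    for (c in 1:3) out[c, , ] <- Wr %*% grid[c, , ] %*% t(Wc)
  } else {
    # bilinear on cell centers, clamped at borders
    src <- function(n_out, n_in) {
      x <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
      pmin(pmax(x, 0), n_in - 1)
    }
    ry <- src(resolution, h); rx <- src(resolution, w)
    y0 <- pmin(floor(ry), h - 1); x0 <- pmin(floor(rx), w - 1)
    y1 <- pmin(y0 + 1, h - 1);    x1 <- pmin(x0 + 1, w - 1)
    fy <- ry - y0; fx <- rx - x0
    for (c in 1:3) {
      G <- grid[c, , ]
      A <- G[y0 + 1, x0 + 1] * outer(1 - fy, 1 - fx) +
           G[y1 + 1, x0 + 1] * outer(fy, 1 - fx) +
           G[y0 + 1, x1 + 1] * outer(1 - fy, fx) +
           G[y1 + 1, x1 + 1] * outer(fy, fx)
      out[c, , ] <- A
    }
  }
  out
}

#' Normalize an embedded map's counts
#'
#' Monotone per-entry transforms applied before the network: `"none"`
#' (identity), `"log1p"` (`log(1 + x)`, the default upstream of training
#' since window counts are heavy-tailed), or `"max_scale"` (divide by the
#' global maximum; the all-zero map stays all-zero).
#'
#' @param map an `embedded_map` or bare 3-channel array.
#' @param scheme normalization scheme.
#' @return Numeric array of the same shape.
#' @export
normalize_counts <- function(map, scheme = c("none", "log1p", "max_scale")) {
  scheme <- match.arg(scheme)
  grid <- if (inherits(map, "embedded_map")) map$counts else map
  grid <- grid * 1.0
  switch(scheme,
         none = grid,
         log1p = log1p(grid),
         max_scale = {
           m <- max(grid)
           if (m > 0) grid / m else grid
         })
}

#' Augmentation settings
#'
#' Geometric augmentations are right-angle rotations, horizontal/vertical
#' flips and a random resized crop ("scaling"); photometric jitter acts
#' multiplicatively per channel on the count grid (there is no RGB image at
#' this stage), with "saturation" interpreted as mixing each channel toward
#' the per-pixel channel mean.
#'
#' @param enable_rotation,enable_flip logical switches.
#' @param scale_range crop-scale interval within (0, 1].
#' @param brightness,contrast,saturation max jitter half-ranges; a value `v`
#'   draws factors in `[1 - v, 1 + v]` (saturation mixes with weight in
#'   `[0, v]`).
#' @param seed integer seed making the augmentation stream reproducible.
#' @return An `augmentation_spec` list.
#' @export
augmentation_spec <- function(enable_rotation = TRUE, enable_flip = TRUE,
                              scale_range = c(0.9, 1.0), brightness = 0.1,
                              contrast = 0.1, saturation = 0.1, seed = 1L) {
  stopifnot(length(scale_range) == 2, scale_range[1] <= scale_range[2],
            scale_range[1] > 0, scale_range[2] <= 1,
            brightness >= 0, contrast >= 0, saturation >= 0)
  structure(list(enable_rotation = enable_rotation, enable_flip = enable_flip,
                 scale_range = scale_range, brightness = brightness,
                 contrast = contrast, saturation = saturation,
                 seed = as.integer(seed)),
            class = "augmentation_spec")
}

# internal: rotate a h x w matrix by k * 90 degrees counter-clockwise
rot90_mat <- function(m, k) {
  k <- k %% 4
  if (k == 0) return(m)
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

#' Apply seeded augmentation to a model input grid
#'
#' Deterministic given `(input, spec, draw)`: the same spec and draw index
#' always produce the same output. Rotations and flips permute entries (the
#' total count is invariant); the crop-and-resize and photometric jitters
#' rescale values within the spec's ranges.
#'
#' @param input numeric array `3 x R x R`.
#' @param spec an [augmentation_spec()].
#' @param draw integer index of the augmentation draw (e.g. epoch * n + i);
#'   combined with `spec$seed` to seed the jitter.
#' @return Augmented array `3 x R x R`.
#' @export
augment <- function(input, spec, draw = 1L) {
  stopifnot(inherits(spec, "augmentation_spec"),
            length(dim(input)) == 3, dim(input)[1] == 3)
  R <- dim(input)[2]
  stopifnot(dim(input)[3] == R)
  with_seed(child_seed(spec$seed, draw), {
    out <- input
    if (spec$enable_rotation) {
      k <- sample(0:3, 1)
      if (k > 0) for (c in 1:3) out[c, , ] <- rot90_mat(input[c, , ], k)
    }
    if (spec$enable_flip && runif(1) < 0.5)
      out <- out[, , rev(seq_len(R)), drop = FALSE]
    if (spec$scale_range[1] < 1) {
      s <- runif(1, spec$scale_range[1], spec$scale_range[2])
      cs <- max(1L, round(R * s))
      if (cs < R) {
        oy <- sample.int(R - cs + 1L, 1L) - 1L
        ox <- sample.int(R - cs + 1L, 1L) - 1L
        crop <- out[, (oy + 1):(oy + cs), (ox + 1):(ox + cs), drop = FALSE]
        out <- resize_to_input(crop, R)
      }
    }
    if (spec$brightness > 0) {
      f <- runif(3, 1 - spec$brightness, 1 + spec$brightness)
      for (c in 1:3) out[c, , ] <- out[c, , ] * f[c]
    }
    if (spec$contrast > 0) {
      f <- runif(1, 1 - spec$contrast, 1 + spec$contrast)
      mu <- mean(out)
      out <- (out - mu) * f + mu
    }
    if (spec$saturation > 0) {
      w <- runif(1, 0, spec$saturation)
      chan_mean <- (out[1, , ] + out[2, , ] + out[3, , ]) / 3
      for (c in 1:3) out[c, , ] <- (1 - w) * out[c, , ] + w * chan_mean
    }
    out
  })
}

#' Persist / load an embedded map as multi-page TIFF + JSON sidecar
#'
#' One 32-bit float TIFF page per channel; values are stored scaled into
#' `[0, 1]` by the global maximum, which is recorded (with window size,
#' channel order and slide dimensions) in a `.json` sidecar next to the
#' TIFF. Integer count maps round-trip exactly.
#'
#' @param map an `embedded_map`.
#' @param path output TIFF path; the sidecar is `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_embedded_tiff <- function(map, path) {
  stopifnot(inherits(map, "embedded_map"))
  scale <- max(map$counts, 1)
  pages <- lapply(1:3, function(c) map$counts[c, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(window_size = map$window_size,
               channel_order = as.list(map$channel_order),
               slide_width = map$slide_width,
               slide_height = map$slide_height,
               scale = scale, integer_counts = is.integer(map$counts))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_embedded_tiff
#' @export
read_embedded_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  counts <- array(0, dim = c(3, h, w))
  for (c in 1:3) counts[c, , ] <- pages[[c]] * meta$scale
  if (isTRUE(meta$integer_counts)) {
    counts <- round(counts)
    storage.mode(counts) <- "integer"
  }
  structure(list(counts = counts, window_size = meta$window_size,
                 channel_order = unlist(meta$channel_order),
                 slide_width = meta$slide_width,
                 slide_height = meta$slide_height),
            class = "embedded_map")
}
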