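#' Histogram equalization
#'
#' Classical global contrast enhancement: pixels are quantized to `n_bins`
#' gray levels and remapped through the empirical CDF, flattening the
#' intensity distribution.  The mapping is non-decreasing, so pixel
#' ordering is preserved.
#'
#' @param image matrix in `[0,1]` or a `bmode_image`.
#' @param n_bins quantization levels (default 256).
#' @return matrix in `[0,1]`.
#' @export
hist_eq <- function(image, n_bins = 256L) {
  x <- as_pixels(image)
  if (min(x) < 0 || max(x) > 1) stop("image must lie in [0,1]")
  if (max(x) == min(x)) {
    warning("constant image: histogram equalization is the identity")
    return(x)
  }
  q <- pmin(floor(x * n_bins), n_bins - 1L)        # levels 0..n_bins-1
  counts <- tabulate(q + 1L, nbins = n_bins)
  cdf <- cumsum(counts) / length(x)
  matrix(cdf[q + 1L], nrow(x), ncol(x))
}

#' CLAHE configuration
#'
#' @param tile_grid `c(rows, cols)` of non-overlapping tiles.
#' @param clip_limit histogram clip threshold as a fraction of the per-tile
#'   pixel count (default 0.01); `Inf` disables clipping.
#' @param n_bins histogram bins.
#' @return object of class `clahe_config`.
#' @export
clahe_config <- function(tile_grid = c(8L, 8L), clip_limit = 0.01,
                         n_bins = 256L) {
  if (any(tile_grid < 1)) stop("tile_grid must be >= (1,1)")
  if (clip_limit <= 0) stop("clip_limit must be positive")
  structure(list(tile_grid = as.integer(tile_grid), clip_limit = clip_limit,
                 n_bins = as.integer(n_bins)),
            class = "clahe_config")
}

## clip a histogram at `limit` counts and redistribute the excess uniformly
## over all bins (single pass; the small residual excess is tolerated).
clip_redistribute <- function(counts, limit) {
  if (!is.finite(limit)) return(counts)
  excess <- sum(pmax(counts - limit, 0))
  counts <- pmin(counts, limit)
  counts + excess / length(counts)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Four steps: (1) partition the image into non-overlapping contiguous
#' tiles, (2) clip each tile's histogram above the threshold and
#' redistribute the clipped mass over all gray values, (3) equalize each
#' tile through its clipped CDF, (4) bilinearly interpolate the tile
#' mappings across the image, removing tile-boundary artifacts.
#'
#' With a single tile and no clipping this degenerates exactly to global
#' [hist_eq()].
#'
#' @param image matrix in `[0,1]` or a `bmode_image`.
#' @param config a `clahe_config`.
#' @return matrix in `[0,1]`.
#' @export
clahe <- function(image, config = clahe_config()) {
  x <- as_pixels(image)
  if (min(x) < 0 || max(x) > 1) stop("image must lie in [0,1]")
  H <- nrow(x); W <- ncol(x)
  gr <- config$tile_grid[1]; gc <- config$tile_grid[2]
  nb <- config$n_bins
  if (H < 2 * gr || W < 2 * gc) stop("tiles smaller than 2x2 pixels")
  q <- pmin(floor(x * nb), nb - 1L)
  # tile boundaries (as equal as possible)
  rb <- floor(seq(0, H, length.out = gr + 1))
  cb <- floor(seq(0, W, length.out = gc + 1))
  # per-tile CDF mappings (nb values each) and tile centres
  maps <- array(0, c(gr, gc, nb))
  ctr_r <- numeric(gr); ctr_c <- numeric(gc)
  for (i in seq_len(gr)) {
    for (j in seq_len(gc)) {
      rows <- (rb[i] + 1):rb[i + 1]; cols <- (cb[j] + 1):cb[j + 1]
      tq <- q[rows, cols]
      counts <- tabulate(tq + 1L, nbins = nb)
      limit <- config$clip_limit * length(tq)
      counts <- clip_redistribute(counts, limit)
      maps[i, j, ] <- cumsum(counts) / sum(counts)
      ctr_r[i] <- mean(range(rows)); ctr_c[j] <- mean(range(cols))
    }
  }
  # step 4: bilinear interpolation between the four surrounding tile maps
  ri <- findInterval(seq_len(H), ctr_r, all.inside = TRUE)  # lower tile row
  ci <- findInterval(seq_len(W), ctr_c, all.inside = TRUE)
  if (gr == 1) { wr <- rep(0, H); ri <- rep(1L, H) } else {
    wr <- (seq_len(H) - ctr_r[ri]) / (ctr_r[ri + 1] - ctr_r[ri])
    wr <- pmin(pmax(wr, 0), 1)
  }
  if (gc == 1) { wc <- rep(0, W); ci <- rep(1L, W) } else {
    wc <- (seq_len(W) - ctr_c[ci]) / (ctr_c[ci + 1] - ctr_c[ci])
    wc <- pmin(pmax(wc, 0), 1)
  }
  out <- matrix(0, H, W)
  lev <- q + 1L
  ri2 <- if (gr == 1) ri else pmin(ri + 1L, gr)
  ci2 <- if (gc == 1) ci else pmin(ci + 1L, gc)
  for (r in seq_len(H)) {
    m00 <- matrix(maps[ri[r], , ], gc, nb)   # (gc x nb) slice, dims kept
    m10 <- matrix(maps[ri2[r], , ], gc, nb)
    l <- lev[r, ]
    v00 <- m00[cbind(ci, l)];  v01 <- m00[cbind(ci2, l)]
    v10 <- m10[cbind(ci, l)];  v11 <- m10[cbind(ci2, l)]
    a <- wr[r]
    out[r, ] <- (1 - a) * ((1 - wc) * v00 + wc * v01) +
                a * ((1 - wc) * v10 + wc * v11)
  }
  out
}
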