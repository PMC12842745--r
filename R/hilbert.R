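#' Generate a Hilbert space-filling curve
#'
#' Enumerates the Hilbert curve on the \eqn{N \times N} grid, \eqn{N = 2^{order}},
#' as an ordered sequence of `(x, y)` cells. The curve visits every cell exactly
#' once and consecutive cells are always 4-neighbours (Manhattan distance 1),
#' which is the locality property exploited by the sonification time mapping:
#' pixels that are close in the image stay close along the 1-D traversal.
#'
#' Coordinates are 0-based with `x` the column and `y` the row. Generation is
#' iterative (vectorised index-to-coordinate bit manipulation), not recursive.
#'
#' @param order Curve order, an integer in `1..15`. The grid side is `2^order`.
#' @return An object of class `hilbert_path`: a list with `order`, grid side
#'   `n`, and `coords`, an integer matrix with columns `x`, `y` holding the
#'   `4^order` cells in traversal order.
#' @examples
#' p <- hilbert_curve(3)
#' nrow(p$coords)  # 64 cells on the 8x8 grid
#' @seealso [restrict_path()], [raster_path()], [locality_score()]
#' @export
hilbert_curve <- function(order) {
  if (!is.numeric(order) || length(order) != 1L || is.na(order) ||
      order != round(order) || order < 1 || order > 15) {
    stop("`order` must be a single integer in 1..15", call. = FALSE)
  }
  order <- as.integer(order)
  n <- bitwShiftL(1L, order)
  d <- seq_len(n * n) - 1L   # 4^15 < 2^31 so integer arithmetic is safe
  x <- integer(length(d))
  y <- integer(length(d))
  t <- d
  s <- 1L
  while (s < n) {
    rx <- bitwAnd(1L, t %/% 2L)
    ry <- bitwAnd(1L, bitwXor(t, rx))
    # rotate the quadrant where ry == 0
    rot <- ry == 0L
    flip <- rot & rx == 1L
    x[flip] <- s - 1L - x[flip]
    y[flip] <- s - 1L - y[flip]
    tmp <- x[rot]; x[rot] <- y[rot]; y[rot] <- tmp
    x <- x + s * rx
    y <- y + s * ry
    t <- t %/% 4L
    s <- bitwShiftL(s, 1L)
  }
  structure(list(order = order, n = n, coords = cbind(x = x, y = y)),
            class = "hilbert_path")
}

#' Restrict a Hilbert curve to an H x W image
#'
#' Keeps, in traversal order, only the curve cells that fall inside the image
#' bounds (`x < W` and `y < H`). The enclosing grid must be the power-of-two
#' grid at least as large as the image, so every pixel is visited: the
#' restricted path has exactly `H * W` coordinates.
#'
#' @param path A `hilbert_path` from [hilbert_curve()].
#' @param H,W Image height and width in pixels.
#' @return A `hilbert_path` with an additional element `valid_coords`
#'   (integer matrix, `H*W` rows) and `H`, `W` recorded.
#' @export
restrict_path <- function(path, H, W) {
  stopifnot(inherits(path, "hilbert_path"))
  if (H < 1 || W < 1) stop("H and W must be positive", call. = FALSE)
  if (path$n < max(H, W)) {
    stop(sprintf("grid side %d is smaller than max(H, W) = %d; use order >= %d",
                 path$n, max(H, W), ceiling(log2(max(H, W)))), call. = FALSE)
  }
  keep <- path$coords[, "x"] < W & path$coords[, "y"] < H
  path$valid_coords <- path$coords[keep, , drop = FALSE]
  path$H <- as.integer(H)
  path$W <- as.integer(W)
  path
}

.hilbert_path_cache <- new.env(parent = emptyenv())

#' Smallest-order Hilbert path covering an image
#'
#' Convenience wrapper: builds the Hilbert curve on the smallest power-of-two
#' grid enclosing `H x W` and restricts it to the image. Results are
#' memoized per image size (the curve is deterministic).
#'
#' @inheritParams restrict_path
#' @return A restricted `hilbert_path`.
#' @export
hilbert_path_for_image <- function(H, W) {
  key <- paste0(H, "x", W)
  cached <- .hilbert_path_cache[[key]]
  if (!is.null(cached)) return(cached)
  order <- max(1L, as.integer(ceiling(log2(max(H, W)))))
  out <- restrict_path(hilbert_curve(order), H, W)
  .hilbert_path_cache[[key]] <- out
  out
}

#' Sonification timing parameters
#'
#' @param duration_sec Audio duration in seconds (default 2).
#' @param sample_rate Sampling rate in Hz (default 16000, the pipeline's
#'   native rate).
#' @param hop Analysis/synthesis hop size in samples (default 500, i.e. 32
#'   frames per second at 16 kHz).
#' @return An object of class `sonification_timing`.
#' @export
sonification_timing <- function(duration_sec = 2, sample_rate = 16000, hop = 500) {
  if (duration_sec <= 0) stop("duration_sec must be > 0", call. = FALSE)
  if (sample_rate <= 0) stop("sample_rate must be > 0", call. = FALSE)
  if (hop <= 0 || hop != round(hop)) stop("hop must be a positive integer", call. = FALSE)
  structure(list(duration_sec = duration_sec, sample_rate = sample_rate,
                 hop = as.integer(hop)),
            class = "sonification_timing")
}

#' Number of time frames implied by a timing specification
#' @param timing A [sonification_timing()].
#' @return Integer frame count `ceil(duration_sec * sample_rate / hop)`.
#' @export
n_time_frames <- function(timing) {
  as.integer(ceiling(timing$duration_sec * timing$sample_rate / timing$hop))
}

#' Partition a restricted path into contiguous time frames
#'
#' Splits the `H*W` valid coordinates of a restricted traversal into
#' `T = ceil(duration_sec * sample_rate / hop)` contiguous, near-equal
#' segments (sizes differ by at most one; the remainder is spread over the
#' leading segments). Each segment becomes one time frame of the composite
#' spectrogram.
#'
#' @param path A restricted `hilbert_path` (or any path object with
#'   `valid_coords`), e.g. from [restrict_path()] or [raster_path()].
#' @param timing A [sonification_timing()].
#' @return An object of class `segmented_path`: list with `coords`,
#'   `segment_id` (integer per coordinate, 1..T), `sizes`, `n_frames`,
#'   `H`, `W`.
#' @export
segment_path <- function(path, timing) {
  coords <- path$valid_coords
  if (is.null(coords)) stop("path has no valid_coords; call restrict_path() first",
                            call. = FALSE)
  n_p <- nrow(coords)
  n_frames <- n_time_frames(timing)
  if (n_p < n_frames) {
    stop(sprintf(paste0("path has %d coordinates but %d time frames are needed; ",
                        "use a larger image or a shorter duration"),
                 n_p, n_frames), call. = FALSE)
  }
  base <- n_p %/% n_frames
  rem <- n_p %% n_frames
  sizes <- rep.int(base, n_frames)
  if (rem > 0) sizes[seq_len(rem)] <- base + 1L
  structure(list(coords = coords,
                 segment_id = rep.int(seq_len(n_frames), sizes),
                 sizes = sizes,
                 n_frames = n_frames,
                 timing = timing,
                 H = path$H, W = path$W),
            class = "segmented_path")
}

#' Average energy maps along a segmented path into channel time series
#'
#' For every Gabor channel `c` and time frame `t`, computes the mean energy
#' over the pixels of segment `t`, turning each 2-D energy map into a 1-D
#' time series that tracks texture energy along the traversal.
#'
#' @param maps An `energy_map_set` from [compute_energy_maps()], or a plain
#'   numeric array with dim `(H, W, C)`.
#' @param seg A `segmented_path` from [segment_path()] built on the same
#'   `H x W` grid.
#' @return An object of class `channel_timeseries`: list with `values`
#'   (`C x T` matrix, nonnegative), `n_channels`, `n_frames`, `timing`.
#' @export
path_to_timeseries <- function(maps, seg) {
  arr <- if (inherits(maps, "energy_map_set")) maps$maps else maps
  stopifnot(inherits(seg, "segmented_path"), length(dim(arr)) == 3L)
  H <- dim(arr)[1]; W <- dim(arr)[2]; C <- dim(arr)[3]
  if (H != seg$H || W != seg$W) {
    stop(sprintf("energy maps are %dx%d but the path was built for %dx%d",
                 H, W, seg$H, seg$W), call. = FALSE)
  }
  # column-major linear index of each path coordinate (x = column, y = row)
  lin <- seg$coords[, "y"] + 1L + H * seg$coords[, "x"]
  flat <- matrix(arr, nrow = H * W, ncol = C)
  sums <- rowsum(flat[lin, , drop = FALSE], group = seg$segment_id, reorder = TRUE)
  values <- t(sums / seg$sizes)
  structure(list(values = values, n_channels = C, n_frames = seg$n_frames,
                 timing = seg$timing),
            class = "channel_timeseries")
}

#' Row-major raster traversal of an image
#'
#' The locality-poor baseline traversal: pixels are visited row by row,
#' left to right. Returned in the same shape as a restricted Hilbert path so
#' it can be segmented and averaged identically (used by the traversal
#' ablation).
#'
#' @param H,W Image height and width in pixels.
#' @return A list of class `raster_path` with `valid_coords` (`H*W` rows,
#'   columns `x`, `y`), `H`, `W`.
#' @export
raster_path <- function(H, W) {
  if (H < 1 || W < 1) stop("H and W must be positive", call. = FALSE)
  H <- as.integer(H); W <- as.integer(W)
  x <- rep.int(seq_len(W) - 1L, H)
  y <- rep(seq_len(H) - 1L, each = W)
  structure(list(valid_coords = cbind(x = x, y = y), H = H, W = W),
            class = "raster_path")
}

#' Neighbour-index locality score of a traversal
#'
#' Summarizes the absolute difference of 1-D traversal indices over all
#' 4-neighbour pixel pairs of the `H x W` grid. Lower is better: spatial
#' neighbours stay close in the 1-D sequence.
#'
#' The default summary is the median, the typical neighbour-pair separation:
#' for a Hilbert traversal over half of all neighbour pairs are consecutive
#' on the curve, so the median is exactly 1, far below the raster traversal's
#' `(1 + W) / 2`. The mean is also available but is a poor proxy for
#' locality here: it is dominated by the few pairs that straddle quadrant
#' seams of the recursive construction, and under it the raster scan can
#' score lower even though its segments are spatially far more dispersed
#' (see [segment_compactness()] for the property that segment averaging
#' actually relies on).
#'
#' @param path A restricted `hilbert_path` or a `raster_path`.
#' @param summary `"median"` (default) or `"mean"`.
#' @return A single numeric score.
#' @export
locality_score <- function(path, summary = c("median", "mean")) {
  summary <- match.arg(summary)
  coords <- path$valid_coords
  if (is.null(coords)) stop("path has no valid_coords", call. = FALSE)
  H <- path$H; W <- path$W
  pos <- matrix(NA_integer_, H, W)
  pos[cbind(coords[, "y"] + 1L, coords[, "x"] + 1L)] <- seq_len(nrow(coords))
  dh <- abs(pos[, -1, drop = FALSE] - pos[, -W, drop = FALSE])   # horizontal pairs
  dv <- abs(pos[-1, , drop = FALSE] - pos[-H, , drop = FALSE])   # vertical pairs
  if (summary == "median") stats::median(c(dh, dv)) else mean(c(dh, dv))
}

#' Spatial compactness of the time-frame segments
#'
#' Mean root-mean-square distance of segment pixels from their segment
#' centroid, averaged over the `T` time frames a traversal is split into.
#' This is the property the per-segment energy averaging exploits: compact
#' segments mean each time frame summarizes one local neighbourhood of the
#' image. Hilbert segments are compact blobs; raster segments are long thin
#' stripes, so the Hilbert score is far lower.
#'
#' @param path A restricted `hilbert_path` or a `raster_path`.
#' @param timing A [sonification_timing()] defining the number of frames.
#' @return Mean within-segment RMS radius in pixels.
#' @export
segment_compactness <- function(path, timing = sonification_timing()) {
  seg <- segment_path(path, timing)
  xs <- seg$coords[, "x"]; ys <- seg$coords[, "y"]
  id <- seg$segment_id
  n <- seg$sizes
  mx <- rowsum(xs, id) / n; my <- rowsum(ys, id) / n
  ssq <- rowsum((xs - mx[id])^2 + (ys - my[id])^2, id)
  mean(sqrt(ssq / n))
}
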