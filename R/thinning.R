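#' Assign leaflet tags by the per-frame median z
#'
#' Points above each frame's median z become `upper`, points below `lower`;
#' a point exactly at the median is assigned `lower` with a warning.
#' Pre-existing (`upper`/`lower`) tags are preserved.
#'
#' @param frames Frame tibble (`frame`, `lipid_id`, `leaflet`, `x`, `y`, `z`).
#' @return The tibble with `leaflet` filled in.
#' @export
assign_leaflets <- function(frames) {
  out <- frames
  warned_tie <- FALSE
  for (f in unique(out$frame)) {
    i <- which(out$frame == f)
    if (length(i) < 4L) abort(sprintf("Frame %s has < 4 points.", f))
    todo <- i[out$leaflet[i] == "unassigned"]
    if (!length(todo)) next
    med <- median(out$z[i])
    at_med <- out$z[todo] == med
    if (any(at_med) && !warned_tie) {
      warn("Point(s) exactly at the median z assigned to the lower leaflet.")
      warned_tie <- TRUE
    }
    out$leaflet[todo] <- ifelse(out$z[todo] > med, "upper", "lower")
    if (length(unique(out$leaflet[i])) < 2L) {
      abort(sprintf("Frame %s is one-sided: all points fell into one leaflet.", f))
    }
  }
  out
}

#' Time-averaged bilayer thickness map
#'
#' Bins the x-y plane at `bin_size`, and for every bin and frame in the
#' averaging window computes the inter-leaflet distance as (mean z of
#' upper-leaflet points in the bin) minus (mean z of lower-leaflet points in
#' the bin). The map value is the average over frames in which both
#' leaflets were represented in that bin; bins never populated are `NA`
#' (empty), never zero. The window defaults to the final 40% of frames —
#' the converged tail of the trajectory.
#'
#' @param frames Frame tibble with assigned leaflets.
#' @param bin_size Bin edge length in angstrom (default 2).
#' @param window Length-2 fractions of the frame sequence to average over
#'   (default `c(0.6, 1)`, i.e. the final 40%).
#' @param box Optional x/y extents; defaults to the `box` attribute of
#'   `frames`, else the data range.
#' @return A `thickness_map` object: `x_edges`, `y_edges`, `x_centers`,
#'   `y_centers`, `thickness` (matrix, NA = empty), `n_frames` and
#'   `n_points` count matrices, `frames_used`, `window`.
#' @export
thickness_map <- function(frames, bin_size = 2, window = c(0.6, 1), box = NULL) {
  if (bin_size <= 0) abort("`bin_size` must be > 0.")
  stopifnot(length(window) == 2L, window[1] >= 0, window[2] <= 1,
            window[1] < window[2])
  if (any(frames$leaflet == "unassigned")) {
    abort("Frames contain unassigned points; run assign_leaflets() first.")
  }
  if (any(!is.finite(frames$x) | !is.finite(frames$y) | !is.finite(frames$z))) {
    abort("Non-finite coordinates in frames.")
  }
  all_frames <- sort(unique(frames$frame))
  nf <- length(all_frames)
  keep <- all_frames[seq_len(nf) > floor(window[1] * nf) &
                     seq_len(nf) <= ceiling(window[2] * nf)]
  if (!length(keep)) abort("Averaging window selects zero frames.")
  fr <- filter(frames, .data$frame %in% keep)

  box <- box %||% attr(frames, "box")
  if (is.null(box)) {
    box_lo <- c(min(fr$x), min(fr$y))
    box_hi <- c(max(fr$x), max(fr$y))
  } else {
    box_lo <- c(0, 0); box_hi <- box
  }
  n_bins <- function(lo, hi) max(1L, as.integer(ceiling((hi - lo) / bin_size - 1e-9)))
  nx <- n_bins(box_lo[1], box_hi[1])
  ny <- n_bins(box_lo[2], box_hi[2])
  x_edges <- box_lo[1] + bin_size * (0:nx)
  y_edges <- box_lo[2] + bin_size * (0:ny)

  ix <- pmin(pmax(findInterval(fr$x, x_edges, rightmost.closed = TRUE), 1L), nx)
  iy <- pmin(pmax(findInterval(fr$y, y_edges, rightmost.closed = TRUE), 1L), ny)
  per <- summarise(group_by(tibble(frame = fr$frame, ix = ix, iy = iy,
                                   leaflet = fr$leaflet, z = fr$z),
                            .data$frame, .data$ix, .data$iy, .data$leaflet),
                   mz = mean(.data$z), np = n(), .groups = "drop")
  wide <- tidyr::pivot_wider(per, names_from = "leaflet",
                             values_from = c("mz", "np"))
  if (!all(c("mz_upper", "mz_lower") %in% names(wide))) {
    abort("A leaflet is entirely absent from the windowed frames.")
  }
  wide <- filter(wide, !is.na(.data$mz_upper) & !is.na(.data$mz_lower))
  wide <- mutate(wide, dist = .data$mz_upper - .data$mz_lower,
                 np = .data$np_upper + .data$np_lower)
  agg <- summarise(group_by(wide, .data$ix, .data$iy),
                   thickness = mean(.data$dist), n_frames = n(),
                   n_points = sum(.data$np), .groups = "drop")

  thick <- matrix(NA_real_, nx, ny)
  cnt_f <- matrix(0L, nx, ny)
  cnt_p <- matrix(0L, nx, ny)
  idx <- cbind(agg$ix, agg$iy)
  thick[idx] <- agg$thickness
  cnt_f[idx] <- agg$n_frames
  cnt_p[idx] <- agg$n_points
  structure(list(x_edges = x_edges, y_edges = y_edges,
                 x_centers = (x_edges[-1] + x_edges[-length(x_edges)]) / 2,
                 y_centers = (y_edges[-1] + y_edges[-length(y_edges)]) / 2,
                 thickness = thick, n_frames = cnt_f, n_points = cnt_p,
                 frames_used = keep, window = window, bin_size = bin_size),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  pop <- sum(!is.na(x$thickness))
  cat(sprintf("Thickness map: %d x %d bins (%.1f A), %d populated; %d frames averaged\n",
              length(x$x_centers), length(x$y_centers), x$bin_size, pop,
              length(x$frames_used)))
  cat(sprintf("  thickness range: %.2f - %.2f A\n",
              min(x$thickness, na.rm = TRUE), max(x$thickness, na.rm = TRUE)))
  invisible(x)
}

#' Summarize local thinning of a thickness map
#'
#' The map minimum marks the thinning site; the bulk thickness is the mean
#' over bins farther than `bulk_radius` from that site; the maximal
#' thinning is bulk minus minimum.
#'
#' @param map A [thickness_map()].
#' @param bulk_radius Distance (angstrom) beyond which bins count as bulk
#'   (default 25).
#' @return List: `bulk` (A), `min` (A), `min_xy` (bin-center coordinates),
#'   `max_thinning` (A), `bulk_radius`, `n_bulk_bins`.
#' @export
thinning_summary <- function(map, bulk_radius = 25) {
  stopifnot(inherits(map, "thickness_map"))
  pop <- which(!is.na(map$thickness), arr.ind = TRUE)
  if (!nrow(pop)) abort("Map has no populated bins.")
  vals <- map$thickness[pop]
  imin <- which.min(vals)
  min_xy <- c(map$x_centers[pop[imin, 1]], map$y_centers[pop[imin, 2]])
  d <- sqrt((map$x_centers[pop[, 1]] - min_xy[1])^2 +
            (map$y_centers[pop[, 2]] - min_xy[2])^2)
  bulk_bins <- d > bulk_radius
  if (!any(bulk_bins)) {
    abort("No bins beyond `bulk_radius` of the minimum; map too small for a bulk estimate.")
  }
  bulk <- mean(vals[bulk_bins])
  list(bulk = bulk, min = vals[imin], min_xy = min_xy,
       max_thinning = bulk - vals[imin], bulk_radius = bulk_radius,
       n_bulk_bins = sum(bulk_bins))
}

#' Difference of two thickness maps
#'
#' Computes A minus B per bin populated in both maps, plus the difference of
#' their maximal thinning values. Grids must match; if not, B is resampled
#' onto A's grid by nearest bin center.
#'
#' @param map_a,map_b [thickness_map()] objects.
#' @param bulk_radius Passed to [thinning_summary()] for the thinning delta.
#' @return List: `diff` (matrix on A's grid, NA where either input is
#'   empty), `delta_max_thinning`, `x_centers`, `y_centers`.
#' @export
difference_map <- function(map_a, map_b, bulk_radius = 25) {
  stopifnot(inherits(map_a, "thickness_map"), inherits(map_b, "thickness_map"))
  same_grid <- isTRUE(all.equal(map_a$x_edges, map_b$x_edges)) &&
    isTRUE(all.equal(map_a$y_edges, map_b$y_edges))
  b_thick <- if (same_grid) {
    map_b$thickness
  } else {
    # nearest-bin resampling of B onto A's grid
    bi <- vapply(map_a$x_centers, function(x) which.min(abs(map_b$x_centers - x)), 1L)
    bj <- vapply(map_a$y_centers, function(y) which.min(abs(map_b$y_centers - y)), 1L)
    map_b$thickness[bi, bj, drop = FALSE]
  }
  both <- !is.na(map_a$thickness) & !is.na(b_thick)
  if (!any(both)) abort("The two maps share no populated bins.")
  d <- matrix(NA_real_, nrow(map_a$thickness), ncol(map_a$thickness))
  d[both] <- map_a$thickness[both] - b_thick[both]
  list(diff = d,
       delta_max_thinning = thinning_summary(map_a, bulk_radius)$max_thinning -
         thinning_summary(map_b, bulk_radius)$max_thinning,
       x_centers = map_a$x_centers, y_centers = map_a$y_centers)
}
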