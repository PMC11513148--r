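#' Specification for a synthetic bilayer trajectory
#'
#' Generates a geometry-only stand-in for a membrane patch: two flat sheets
#' of per-lipid reference points separated by `bulk_separation`, with an
#' optional localized Gaussian "dimple" that thins the bilayer by
#' `dimple_depth * exp(-r^2 / (2 * dimple_sigma^2))`, split symmetrically
#' across the two leaflets, plus independent Gaussian thermal noise on z.
#' Lateral positions are redrawn uniformly each frame (a fluid in-plane
#' rearrangement), so time-averaged maps accumulate coverage everywhere.
#'
#' @param box_xy Length-2 numeric: box extents in angstrom; points occupy
#'   `[0, box_xy[1]] x [0, box_xy[2]]`.
#' @param n_lipids_per_leaflet Reference points per leaflet per frame.
#' @param bulk_separation Inter-leaflet distance far from the dimple (A).
#' @param dimple_center Length-2 numeric (x, y) of the thinning center (A).
#' @param dimple_depth Maximal reduction of the separation (A); must be
#'   smaller than `bulk_separation`.
#' @param dimple_sigma Gaussian width of the dimple (A); must be > 0.
#' @param thermal_sd Per-point z noise SD (A).
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @return A `bilayer_spec` list.
#' @export
bilayer_spec <- function(box_xy = c(64, 64),
                         n_lipids_per_leaflet = 250L,
                         bulk_separation = 40,
                         dimple_center = c(30, 30),
                         dimple_depth = 0,
                         dimple_sigma = 8,
                         thermal_sd = 1,
                         n_frames = 100L,
                         seed = 1L) {
  stopifnot(length(box_xy) == 2L, all(box_xy > 0))
  stopifnot_scalar_number(bulk_separation, "bulk_separation", lower = 0)
  stopifnot_scalar_number(dimple_depth, "dimple_depth", lower = 0)
  if (dimple_depth >= bulk_separation) {
    abort("`dimple_depth` must be smaller than `bulk_separation`.")
  }
  if (dimple_sigma <= 0) abort("`dimple_sigma` must be > 0.")
  stopifnot_scalar_number(thermal_sd, "thermal_sd", lower = 0)
  structure(list(box_xy = box_xy,
                 n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
                 bulk_separation = bulk_separation,
                 dimple_center = dimple_center,
                 dimple_depth = dimple_depth,
                 dimple_sigma = dimple_sigma,
                 thermal_sd = thermal_sd,
                 n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "bilayer_spec")
}

#' Generate synthetic bilayer trajectory frames
#'
#' @param spec A [bilayer_spec()].
#' @param withhold_tags If `TRUE`, leaflet tags are set to `"unassigned"`
#'   (the ground truth is kept in a `truth` attribute) so that
#'   [assign_leaflets()] can be exercised.
#' @return Tibble: `frame`, `lipid_id`, `leaflet`, `x`, `y`, `z`, with a
#'   `box` attribute (the x/y extents).
#' @export
generate_bilayer_trajectory <- function(spec, withhold_tags = FALSE) {
  stopifnot(inherits(spec, "bilayer_spec"))
  n <- spec$n_lipids_per_leaflet
  with_seed(spec$seed, {
    frames <- vector("list", spec$n_frames)
    for (f in seq_len(spec$n_frames)) {
      x <- runif(2L * n, 0, spec$box_xy[1])
      y <- runif(2L * n, 0, spec$box_xy[2])
      leaflet <- rep(c("upper", "lower"), each = n)
      r2 <- (x - spec$dimple_center[1])^2 + (y - spec$dimple_center[2])^2
      deform <- spec$dimple_depth * exp(-r2 / (2 * spec$dimple_sigma^2)) / 2
      z0 <- ifelse(leaflet == "upper",
                   spec$bulk_separation / 2 - deform,
                   -spec$bulk_separation / 2 + deform)
      z <- z0 + if (spec$thermal_sd > 0) rnorm(2L * n, 0, spec$thermal_sd) else 0
      frames[[f]] <- tibble(frame = f, lipid_id = seq_len(2L * n),
                            leaflet = leaflet, x = x, y = y, z = z)
    }
    out <- bind_rows(frames)
    attr(out, "box") <- spec$box_xy
    if (withhold_tags) {
      attr(out, "truth") <- out$leaflet
      out$leaflet <- "unassigned"
    }
    out
  })
}
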