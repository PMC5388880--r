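#' Configuration for a synthetic morphometry mask scene
#'
#' Declares the ground truth of a constructed immunofluorescence-like
#' scene: a vessel (lectin) mask, a mural-cell (desmin) instance mask with
#' prescribed coverage and detachment fractions, and a plaque mask with
#' components of prescribed areas.
#'
#' @param image_shape c(rows, cols) in pixels.
#' @param pixel_size micrometers per pixel.
#' @param plaque_areas plaque areas in square micrometers.
#' @param coverage_fraction_true desmin/lectin pixel ratio in [0, 1].
#' @param detached_fraction_true detached-pixel fraction in [0, 1].
#' @param cell_pixels nominal mural-cell size in pixels.
#' @param seed integer seed (placement jitter).
#' @return object of class `mask_scene_config`.
#' @export
mask_scene_config <- function(image_shape = c(256, 256), pixel_size = 1,
                              plaque_areas = c(100, 200, 400),
                              coverage_fraction_true = 0.6,
                              detached_fraction_true = 0.3,
                              cell_pixels = 25, seed = 1L) {
  if (any(image_shape < 64)) stop("image_shape too small")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (coverage_fraction_true < 0 || coverage_fraction_true > 1 ||
      detached_fraction_true < 0 || detached_fraction_true > 1)
    stop("fractions must lie in [0, 1]")
  if (any(plaque_areas < pixel_size^2))
    stop("plaque areas unachievable at this pixel size")
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, plaque_areas = plaque_areas,
                 coverage_fraction_true = coverage_fraction_true,
                 detached_fraction_true = detached_fraction_true,
                 cell_pixels = as.integer(cell_pixels),
                 seed = as.integer(seed)),
            class = "mask_scene_config")
}

# fill `npx` pixels column-major inside a band of rows, starting at col0;
# returns the linear indices used
.fill_band <- function(nr, rows, col0, npx) {
  cols_needed <- ceiling(npx / length(rows))
  idx <- integer(0)
  left <- npx
  cc <- col0
  while (left > 0L) {
    take <- min(left, length(rows))
    idx <- c(idx, (cc - 1L) * nr + rows[seq_len(take)])
    left <- left - take
    cc <- cc + 1L
  }
  idx
}

#' Generate a synthetic mask scene with known ground truth
#'
#' Constructs (deterministically up to seeded jitter):
#' a lectin mask of vertical vessel stripes; a desmin instance mask whose
#' total pixel count is `round(coverage * lectin pixels)` (exact up to 1
#' pixel), split into isolated cells (the detached subset, pixel share
#' `detached_fraction_true` up to 1 pixel) and a chain of edge-touching
#' cells; and a plaque mask whose 8-connected components have exactly the
#' requested pixel areas. With `coverage_fraction_true = 1` the desmin
#' mask equals the lectin mask.
#'
#' @param cfg a [mask_scene_config()].
#' @return list of class `mask_scene`: binary `lectin`, `desmin`, `plaques`,
#'   `roi` matrices, integer `desmin_instances`, and a `truth` record with
#'   all realized counts (`coverage_realized`, `detached_realized`,
#'   `detached_labels`, `plaque_areas_px`, ...).
#' @export
generate_mask_scene <- function(cfg) {
  stopifnot(inherits(cfg, "mask_scene_config"))
  set.seed(cfg$seed)
  nr <- cfg$image_shape[1]; nc <- cfg$image_shape[2]
  zero <- matrix(0L, nr, nc)

  # --- lectin: vertical stripes of width 4 in the left half -------------
  lectin <- zero
  stripe_w <- 4L
  xs <- seq(4L, floor(nc / 2) - stripe_w, by = 14L)
  target_l <- length(xs) * stripe_w * (nr - 8L)
  for (x in xs) lectin[5L:(nr - 4L), x:(x + stripe_w - 1L)] <- 1L
  n_lectin <- sum(lectin)

  # --- desmin instances --------------------------------------------------
  desmin_lab <- zero
  if (cfg$coverage_fraction_true == 1) {
    desmin <- lectin
    desmin_lab <- label_components(lectin)
    d_det <- NA_integer_
    detached_labels <- sort(unique(desmin_lab[desmin_lab > 0]))
  } else {
    n_desmin <- round(cfg$coverage_fraction_true * n_lectin)
    d_det <- round(cfg$detached_fraction_true * n_desmin)
    d_att <- n_desmin - d_det
    if (d_att == 1L) {          # a 1-px "chain" cannot touch anything
      d_det <- d_det + 1L
      d_att <- 0L
    }
    cell <- cfg$cell_pixels
    lab <- 0L
    # detached cells: 5-row bands in the upper right region, >= 4 px apart
    band_rows <- seq(5L, floor(0.72 * nr) - 5L, by = 9L)
    col_starts <- seq(floor(nc / 2) + 4L, nc - 10L, by = 10L)
    slots <- expand.grid(r = band_rows, x = col_starts)
    si <- 1L
    left <- d_det
    while (left > 0L) {
      if (si > nrow(slots))
        stop("scene too small for the requested detached pixel count")
      take <- min(left, cell)
      rows <- slots$r[si] + 0:4
      idx <- .fill_band(nr, rows, slots$x[si], take)
      lab <- lab + 1L
      desmin_lab[idx] <- lab
      left <- left - take
      si <- si + 1L
    }
    detached_labels <- seq_len(lab)
    # attached chain(s): contiguous column-major fills of 5-row bands in
    # the left half, each sliced into consecutive (hence edge-touching)
    # instances; every band holds at least two instances
    if (d_att > 0L) {
      chain_rows <- seq(5L, nr - 9L, by = 9L)
      band_cap <- 5L * (floor(nc / 2) - 8L)
      left2 <- d_att
      bi <- 1L
      while (left2 > 0L) {
        if (bi > length(chain_rows))
          stop("scene too small for the requested attached pixel count")
        take <- min(left2, band_cap)
        # avoid leaving a lone untouchable instance in the next band
        if (left2 - take == 1L) take <- take - 1L
        rows <- chain_rows[bi] + 0:4
        idx <- .fill_band(nr, rows, 4L, take)
        n_cells <- max(2L, ceiling(take / cell))
        cuts <- ceiling(seq_along(idx) / (length(idx) / n_cells))
        desmin_lab[idx] <- lab + cuts
        lab <- lab + max(cuts)
        left2 <- left2 - take
        bi <- bi + 1L
      }
    }
    storage.mode(desmin_lab) <- "integer"
    desmin <- matrix(as.integer(desmin_lab > 0L), nr, nc)
  }
  n_desmin_real <- sum(desmin)

  # --- plaques: exact-area blobs in the lower right quadrant ------------
  plaques <- zero
  areas_px <- round(cfg$plaque_areas / cfg$pixel_size^2)
  px0 <- floor(nc / 2) + 4L
  pr <- floor(0.75 * nr) + 2L
  pc <- px0
  for (a in areas_px) {
    side <- ceiling(sqrt(a))
    if (pc + side + 3L > nc || pr + side - 1L > nr - 2L)
      stop("plaque placement failed: scene too small")
    rows <- pr:(pr + side - 1L)
    idx <- .fill_band(nr, rows, pc, a)
    if (any(plaques[idx] != 0L) || any(desmin_lab[idx] != 0L))
      stop("plaque placement failed: overlap")
    plaques[idx] <- 1L
    pc <- pc + side + 3L
  }

  truth <- list(
    lectin_pixels = n_lectin,
    desmin_pixels = n_desmin_real,
    coverage_requested = cfg$coverage_fraction_true,
    coverage_realized = n_desmin_real / n_lectin,
    detached_requested = cfg$detached_fraction_true,
    detached_pixels = if (is.na(d_det[1])) n_desmin_real else
      sum(desmin_lab %in% detached_labels),
    detached_realized = if (is.na(d_det[1])) 1 else
      sum(desmin_lab %in% detached_labels) / max(1L, n_desmin_real),
    detached_labels = detached_labels,
    plaque_areas_um2 = cfg$plaque_areas,
    plaque_areas_px = areas_px,
    target_lectin = target_l)

  structure(list(lectin = lectin, desmin = desmin,
                 desmin_instances = desmin_lab, plaques = plaques,
                 roi = matrix(1L, nr, nc), truth = truth, config = cfg),
            class = "mask_scene")
}
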