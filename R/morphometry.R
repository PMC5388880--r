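#' Connected-component labeling of a binary mask
#'
#' Raster-scan two-pass labeling with union-find. 8-connectivity (edge or
#' corner contact) by default, matching the contact rule used for
#' mural-cell detachment.
#'
#' @param mask logical or 0/1 integer matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of the same shape: 0 background, components
#'   labeled 1..k in raster order of first occurrence.
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nxt <- 0L
  for (c in seq_len(nc)) {
    for (r in seq_len(nr)) {
      if (m[r, c] == 0L) next
      nb <- integer(0)
      if (r > 1L && lab[r - 1L, c] > 0L) nb <- c(nb, lab[r - 1L, c])
      if (c > 1L && lab[r, c - 1L] > 0L) nb <- c(nb, lab[r, c - 1L])
      if (connectivity == 8 && c > 1L) {
        if (r > 1L && lab[r - 1L, c - 1L] > 0L) nb <- c(nb, lab[r - 1L, c - 1L])
        if (r < nr && lab[r + 1L, c - 1L] > 0L) nb <- c(nb, lab[r + 1L, c - 1L])
      }
      if (!length(nb)) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[r, c] <- nxt
      } else {
        roots <- vapply(unique(nb), find, integer(1))
        keep <- min(roots)
        lab[r, c] <- keep
        for (q in roots) parent[q] <- keep
      }
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, integer(1))
  # relabel compactly in raster order of first occurrence
  fg <- lab > 0L
  lab[fg] <- roots[lab[fg]]
  ids <- unique(lab[fg])
  lab[fg] <- match(lab[fg], ids)
  lab
}

.morph_result <- function(measure, value, num, den, parameters = list()) {
  structure(list(measure = measure, value = value,
                 numerator_pixels = num, denominator_pixels = den,
                 parameters = parameters),
            class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf("%s: %.4g (%d / %d pixels)\n", x$measure, x$value,
              x$numerator_pixels, x$denominator_pixels))
  invisible(x)
}

#' Pixel-ratio coverage of a signal mask over a reference mask
#'
#' Mural-cell coverage: total signal-positive (e.g. desmin) pixels over
#' total reference-positive (e.g. lectin) pixels.
#'
#' @param signal_mask,reference_mask binary masks of identical shape.
#' @return `morphometry_result` with the coverage fraction.
#' @export
coverage_fraction <- function(signal_mask, reference_mask) {
  if (!identical(dim(signal_mask), dim(reference_mask)))
    stop("masks must share shape")
  den <- sum(reference_mask != 0)
  if (den == 0) stop("empty reference mask")
  num <- sum(signal_mask != 0)
  .morph_result("coverage_fraction", num / den, num, den)
}

#' Detached-cell pixel fraction of an instance-labeled mask
#'
#' An instance is detached iff no pixel of any other instance lies within
#' `contact_distance` in the Chebyshev metric (default 1: 8-connected
#' touch). Returns detached-instance pixels over all instance pixels.
#'
#' @param instance_mask integer matrix, 0 background, k >= 1 instance labels.
#' @param contact_distance Chebyshev contact radius in pixels.
#' @return `morphometry_result`; also carries the detached label ids in
#'   `parameters$detached_labels`. A single-instance mask returns 1 with a
#'   warning (no contact is possible).
#' @export
detachment_fraction <- function(instance_mask, contact_distance = 1) {
  lab <- instance_mask
  labels <- sort(unique(lab[lab > 0]))
  if (!length(labels)) stop("mask has no instances")
  total <- sum(lab > 0)
  if (length(labels) == 1L) {
    warning("single instance: no contact possible, detachment = 1")
    return(.morph_result("detachment_fraction", 1, total, total,
                         list(contact_distance = contact_distance,
                              detached_labels = labels)))
  }
  d <- as.integer(contact_distance)
  nr <- nrow(lab); nc <- ncol(lab)
  in_contact <- logical(max(labels))
  for (dx in -d:d) {
    for (dy in -d:d) {
      if (dx == 0 && dy == 0) next
      r1 <- max(1, 1 + dy):min(nr, nr + dy)
      r0 <- r1 - dy
      c1 <- max(1, 1 + dx):min(nc, nc + dx)
      c0 <- c1 - dx
      a <- lab[r0, c0, drop = FALSE]
      b <- lab[r1, c1, drop = FALSE]
      hit <- a > 0 & b > 0 & a != b
      if (any(hit)) {
        in_contact[unique(a[hit])] <- TRUE
        in_contact[unique(b[hit])] <- TRUE
      }
    }
  }
  detached <- labels[!in_contact[labels]]
  num <- sum(lab %in% detached)
  .morph_result("detachment_fraction", num / total, num, total,
                list(contact_distance = contact_distance,
                     detached_labels = detached))
}

#' Pixel fraction of flagged instances
#'
#' E.g. mural-cell dedifferentiation: pixels belonging to instances flagged
#' by an external (observer-supplied) classification, over all instance
#' pixels.
#'
#' @param instance_mask integer label matrix.
#' @param class_flags logical vector named by instance label (or indexed by
#'   label id); every instance present must have a flag.
#' @return `morphometry_result` with the flagged-pixel fraction.
#' @export
class_pixel_fraction <- function(instance_mask, class_flags) {
  lab <- instance_mask
  labels <- sort(unique(lab[lab > 0]))
  if (!length(labels)) stop("mask has no instances")
  if (!is.null(names(class_flags))) {
    flg <- class_flags[as.character(labels)]
  } else {
    flg <- class_flags[labels]
  }
  if (anyNA(flg) || length(flg) < length(labels))
    stop("missing class flag for some instance")
  total <- sum(lab > 0)
  flagged <- labels[as.logical(flg)]
  num <- sum(lab %in% flagged)
  .morph_result("class_pixel_fraction", num / total, num, total)
}

#' Plaque load within a region of interest
#'
#' Connected components (8-connectivity) of the plaque mask inside the ROI;
#' components smaller than `min_plaque_area` are removed (thresholding was
#' tuned so plaques of ~100 square micrometers survive). Returns the
#' percent of ROI area covered by surviving plaques and their count.
#'
#' @param plaque_mask binary plaque mask.
#' @param roi_mask binary region-of-interest mask, same shape.
#' @param min_plaque_area smallest retained plaque area, square
#'   micrometers (default 100).
#' @param pixel_size micrometers per pixel (default 1).
#' @return `morphometry_result`: `value` is the load in percent;
#'   `parameters$n_plaques` the surviving component count.
#' @export
plaque_load <- function(plaque_mask, roi_mask, min_plaque_area = 100,
                        pixel_size = 1) {
  if (!identical(dim(plaque_mask), dim(roi_mask)))
    stop("masks must share shape")
  if (min_plaque_area < 0) stop("min_plaque_area must be >= 0")
  roi_px <- sum(roi_mask != 0)
  if (roi_px == 0) stop("empty ROI")
  m <- (plaque_mask != 0) & (roi_mask != 0)
  lab <- label_components(m, connectivity = 8)
  if (max(lab) == 0)
    return(.morph_result("plaque_load_percent", 0, 0L, roi_px,
                         list(n_plaques = 0L,
                              min_plaque_area = min_plaque_area)))
  areas_px <- tabulate(lab[lab > 0])
  keep <- which(areas_px * pixel_size^2 >= min_plaque_area)
  num <- sum(areas_px[keep])
  .morph_result("plaque_load_percent", 100 * num / roi_px, num, roi_px,
                list(n_plaques = length(keep),
                     min_plaque_area = min_plaque_area,
                     pixel_size = pixel_size))
}

#' Vascular amyloid load
#'
#' Percent of a vessel's surface area covered by amyloid: 100 * amyloid
#' surface / vessel surface. Surface areas are scalar inputs (e.g. from 3D
#' segmentation).
#'
#' @param amyloid_surface,vessel_surface surface areas, same units.
#' @return load in percent. Vectorized.
#' @export
vascular_amyloid_load <- function(amyloid_surface, vessel_surface) {
  if (any(vessel_surface <= 0)) stop("vessel surface must be positive")
  if (any(amyloid_surface < 0)) stop("amyloid surface must be >= 0")
  if (any(amyloid_surface > vessel_surface))
    stop("amyloid surface exceeds vessel surface: inconsistent segmentation")
  100 * amyloid_surface / vessel_surface
}

#' Threshold an intensity image against a background-density ceiling
#'
#' Finds the smallest intensity threshold at which the background region's
#' suprathreshold pixel density does not exceed `target_density` pixels per
#' 150 square micrometers, then binarizes the whole image at that
#' threshold (pixels strictly above threshold are foreground).
#'
#' @param image numeric intensity matrix.
#' @param background logical matrix marking background pixels (non-empty).
#' @param target_density maximum allowed suprathreshold background pixels
#'   per 150 square micrometers (the calibration range is 7-10).
#' @param pixel_size micrometers per pixel.
#' @return binary integer matrix with the chosen threshold attached as
#'   attribute `"threshold"`.
#' @export
threshold_by_background <- function(image, background, target_density = 10,
                                    pixel_size = 1) {
  if (!identical(dim(image), dim(background)))
    stop("image and background must share shape")
  bg <- image[background != 0]
  if (!length(bg)) stop("empty background region")
  bg_area <- length(bg) * pixel_size^2
  allowed <- floor(target_density * bg_area / 150)
  # candidate thresholds: one below the smallest value, then every observed
  # background level; pick the smallest with suprathreshold count <= allowed
  cand <- c(min(bg) - 1, sort(unique(bg)))
  counts <- vapply(cand, function(th) sum(bg > th), integer(1))
  ok <- which(counts <= allowed)
  thr <- cand[ok[1]]
  out <- matrix(as.integer(image > thr), nrow(image), ncol(image))
  if (sum(out) == 0 && thr >= max(image))
    stop("unattainable density: background saturated at the image maximum")
  attr(out, "threshold") <- thr
  out
}
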