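#' Object-based classification rules for building extraction
#'
#' Per-object thresholds applied after segmentation. Defaults are the rule
#' set used on the study imagery: index threshold 6 for MBI (1.45 for
#' PanTex), brightness >= 136, NDVI < 0.1, length/width ratio in
#' [1.5, 4.5], rectangular fit >= 0.6, shape index <= 2.6. All thresholds
#' are digital-number (0-255) based and should be recalibrated for other
#' radiometry.
#'
#' @param index_kind \code{"MBI"} or \code{"PANTEX"}.
#' @param index_min minimum mean index over the object; defaults to 6 for
#'   MBI and 1.45 for PanTex.
#' @param brightness_min minimum mean brightness.
#' @param ndvi_max NDVI strictly below this passes.
#' @param lw_ratio_range allowed \code{c(min, max)} length/width ratio.
#' @param rect_fit_min minimum rectangular fit.
#' @param shape_index_max maximum shape index.
#' @return An object of class \code{classification_rules}.
#' @export
classification_rules <- function(index_kind = c("MBI", "PANTEX"),
                                 index_min = NULL,
                                 brightness_min = 136,
                                 ndvi_max = 0.1,
                                 lw_ratio_range = c(1.5, 4.5),
                                 rect_fit_min = 0.6,
                                 shape_index_max = 2.6) {
  index_kind <- match.arg(index_kind)
  if (is.null(index_min))
    index_min <- if (index_kind == "MBI") 6 else 1.45
  stopifnot(lw_ratio_range[1] <= lw_ratio_range[2])
  structure(list(index_kind = index_kind, index_min = index_min,
                 brightness_min = brightness_min, ndvi_max = ndvi_max,
                 lw_ratio_range = lw_ratio_range,
                 rect_fit_min = rect_fit_min,
                 shape_index_max = shape_index_max),
            class = "classification_rules")
}

#' Rectangular fit of a pixel object
#'
#' Fraction of the object's pixels that fall inside the rectangle with the
#' same area, the same centroid and the orientation and aspect ratio of the
#' object's minimum-area oriented bounding box. Solid rectangles score 1.
#'
#' @param rows,cols pixel grid coordinates of the object.
#' @return value in (0, 1].
#' @export
rectangular_fit <- function(rows, cols) {
  n <- length(rows)
  stopifnot(n > 0)
  if (n == 1L) return(1)
  box <- min_area_rect(rows, cols)
  if (box$width == 0) return(1)  # degenerate line object
  aspect <- box$length / box$width
  # equal-area rectangle with the box's orientation and aspect, centred on
  # the pixel centroid
  w <- sqrt(n / aspect)
  l <- aspect * w
  cx <- mean(cols - 0.5)
  cy <- mean(rows - 0.5)
  u <- c(cos(box$angle), sin(box$angle))
  v <- c(-u[2], u[1])
  px <- cols - 0.5 - cx
  py <- rows - 0.5 - cy
  pu <- px * u[1] + py * u[2]
  pv <- px * v[1] + py * v[2]
  inside <- abs(pu) <= l / 2 & abs(pv) <= w / 2
  sum(inside) / n
}

#' Shape index of a pixel object
#'
#' Perimeter (exposed pixel-edge length) divided by four times the square
#' root of the pixel area. Squares score 1; elongated or ragged objects
#' score higher.
#'
#' @inheritParams rectangular_fit
#' @return value >= 1 (up to rasterisation effects).
#' @export
shape_index <- function(rows, cols) {
  pixel_perimeter(rows, cols) / (4 * sqrt(length(rows)))
}

#' Length/width ratio of a pixel object
#'
#' Longer over shorter side of the minimum-area oriented bounding box of the
#' object's pixel squares.
#'
#' @inheritParams rectangular_fit
#' @return value >= 1.
#' @export
length_width_ratio <- function(rows, cols) {
  box <- min_area_rect(rows, cols)
  if (box$width == 0) return(if (box$length == 0) 1 else Inf)
  box$length / box$width
}

#' Segment an index raster into candidate objects
#'
#' Thresholds the index at \code{rules$index_min}, labels the support with
#' 8-connected components, and computes the per-object features used by the
#' classification rules. This is the package's labelled-segmentation
#' provider; any other provider can be substituted by passing a prebuilt
#' label matrix via \code{labels}.
#'
#' @param scene an \code{\link{msp_scene}}.
#' @param index an \code{index_raster} (MBI or PanTex) on the scene grid.
#' @param rules a \code{\link{classification_rules}}.
#' @param labels optional integer label matrix overriding the internal
#'   threshold-and-label step (0 = background).
#' @return A data frame of class \code{segment_objects}, one row per object,
#'   with features and a list-column \code{pixels} of \code{(row, col)}
#'   matrices.
#' @export
segment_objects <- function(scene, index, rules = classification_rules(),
                            labels = NULL) {
  stopifnot(inherits(scene, "msp_scene"))
  v <- as_values(index)
  if (!identical(dim(v), dim(scene)))
    stop("index raster is not co-registered with the scene")
  if (is.null(labels)) {
    mask <- v >= rules$index_min
    labels <- cpp_label(mask, 8L)
  }
  nlab <- max(labels)
  bright <- compute_brightness(scene)$values
  ndvi <- compute_ndvi(scene)$values
  out <- vector("list", nlab)
  if (nlab > 0) {
    idx <- which(labels > 0)
    rr <- ((idx - 1L) %% nrow(labels)) + 1L
    cc <- ((idx - 1L) %/% nrow(labels)) + 1L
    ll <- labels[idx]
    ord <- order(ll)
    rr <- rr[ord]; cc <- cc[ord]; ll <- ll[ord]
    bounds <- c(0L, cumsum(tabulate(ll, nlab)))
    for (k in seq_len(nlab)) {
      sel <- (bounds[k] + 1L):bounds[k + 1L]
      r <- rr[sel]; c <- cc[sel]
      pix <- cbind(row = r, col = c)
      lin <- (c - 1L) * nrow(labels) + r
      out[[k]] <- data.frame(
        id = k,
        n_pixels = length(r),
        area_m2 = length(r) * scene$pixel_size^2,
        mean_index = mean(v[lin]),
        mean_brightness = mean(bright[lin]),
        mean_ndvi = mean(ndvi[lin]),
        lw_ratio = length_width_ratio(r, c),
        rect_fit = rectangular_fit(r, c),
        shape_index = shape_index(r, c),
        centroid_row = mean(r - 0.5),
        centroid_col = mean(c - 0.5)
      )
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df))
    df <- data.frame(id = integer(), n_pixels = integer(), area_m2 = numeric(),
                     mean_index = numeric(), mean_brightness = numeric(),
                     mean_ndvi = numeric(), lw_ratio = numeric(),
                     rect_fit = numeric(), shape_index = numeric(),
                     centroid_row = numeric(), centroid_col = numeric())
  df$pixels <- if (nlab > 0) {
    lapply(seq_len(nlab), function(k) {
      sel <- (bounds[k] + 1L):bounds[k + 1L]
      cbind(row = rr[sel], col = cc[sel])
    })
  } else list()
  # world coordinates of centroids (north-up geotransform)
  df$x <- scene$origin[1] + df$centroid_col * scene$pixel_size
  df$y <- scene$origin[2] - df$centroid_row * scene$pixel_size
  class(df) <- c("segment_objects", class(df))
  attr(df, "pixel_size") <- scene$pixel_size
  df
}

#' Apply the classification rules to segmented objects
#'
#' An object is labelled a building iff every rule passes: mean index,
#' mean brightness, mean NDVI, length/width ratio range, rectangular fit and
#' shape index.
#'
#' @param objects a \code{\link{segment_objects}} data frame.
#' @param rules a \code{\link{classification_rules}}.
#' @return \code{objects} with a logical column \code{building}.
#' @export
classify_buildings <- function(objects, rules = classification_rules()) {
  objects$building <-
    objects$mean_index >= rules$index_min &
    objects$mean_brightness >= rules$brightness_min &
    objects$mean_ndvi < rules$ndvi_max &
    objects$lw_ratio >= rules$lw_ratio_range[1] &
    objects$lw_ratio <= rules$lw_ratio_range[2] &
    objects$rect_fit >= rules$rect_fit_min &
    objects$shape_index <= rules$shape_index_max
  objects
}

#' Fill small interior holes in a building mask
#'
#' Background components (4-connected) that do not touch the image border,
#' whose bounding box fits inside \code{box x box} pixels, and that are
#' enclosed by a single object are filled. Holes bordered by two distinct
#' objects are left open so that filling never merges objects.
#'
#' @param mask logical matrix.
#' @param box maximum hole bounding-box side in pixels (default 5).
#' @return logical matrix with qualifying holes filled.
#' @export
fill_holes <- function(mask, box = 5L) {
  stopifnot(is.logical(mask))
  obj <- cpp_label(mask, 8L)
  holes <- cpp_label(!mask, 4L)
  nr <- nrow(mask); nc <- ncol(mask)
  border_labels <- unique(c(holes[1, ], holes[nr, ], holes[, 1], holes[, nc]))
  out <- mask
  for (h in setdiff(unique(holes[holes > 0]), border_labels)) {
    idx <- which(holes == h)
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    if (diff(range(r)) + 1L > box || diff(range(c)) + 1L > box) next
    # labels of 4-adjacent object pixels
    nb <- integer(0)
    for (k in seq_along(idx)) {
      rr <- r[k]; cc <- c[k]
      if (rr > 1)  nb <- c(nb, obj[rr - 1L, cc])
      if (rr < nr) nb <- c(nb, obj[rr + 1L, cc])
      if (cc > 1)  nb <- c(nb, obj[rr, cc - 1L])
      if (cc < nc) nb <- c(nb, obj[rr, cc + 1L])
    }
    nb <- unique(nb[nb > 0])
    if (length(nb) == 1L) out[idx] <- TRUE
  }
  out
}

#' Keep buildings whose nearest point of interest is residential
#'
#' For each building the nearest POI within \code{radius_m} (world
#' coordinates) is looked up; the building is kept iff that POI's category
#' is \code{"residential"}. Buildings with no POI in range are dropped.
#'
#' @param buildings data frame with world coordinates \code{x}, \code{y}
#'   (e.g. from \code{\link{segment_objects}}).
#' @param pois data frame with columns \code{x}, \code{y}, \code{category};
#'   categories come from \{public_service, financial, commercial,
#'   entertainment, residential\}.
#' @param radius_m search radius in metres (default 50).
#' @return The subset of \code{buildings} confirmed residential.
#' @export
refine_residential <- function(buildings, pois, radius_m = 50) {
  valid <- c("public_service", "financial", "commercial", "entertainment",
             "residential")
  if (nrow(pois) == 0) {
    warning("empty POI set: dropping all buildings")
    return(buildings[integer(0), , drop = FALSE])
  }
  if (!all(pois$category %in% valid))
    stop("unknown POI category: ",
         paste(setdiff(pois$category, valid), collapse = ", "))
  keep <- vapply(seq_len(nrow(buildings)), function(i) {
    d2 <- (pois$x - buildings$x[i])^2 + (pois$y - buildings$y[i])^2
    j <- which.min(d2)
    d2[j] <= radius_m^2 && pois$category[j] == "residential"
  }, logical(1))
  buildings[keep, , drop = FALSE]
}

#' End-to-end building extraction
#'
#' Segments the index raster, applies the rule set, fills small holes in the
#' building mask, re-segments the filled mask, and (optionally) refines to
#' residential buildings with POIs.
#'
#' @inheritParams segment_objects
#' @param pois optional POI data frame for residential refinement.
#' @param fill_box hole-filling box size in pixels.
#' @param poi_radius_m POI search radius in metres.
#' @return A \code{segment_objects} data frame of extracted buildings
#'   (all rows pass the rules).
#' @export
extract_buildings <- function(scene, index, rules = classification_rules(),
                              pois = NULL, fill_box = 5L, poi_radius_m = 50) {
  objs <- segment_objects(scene, index, rules)
  objs <- classify_buildings(objs, rules)
  keep <- objs[objs$building, , drop = FALSE]
  # rebuild the mask from accepted objects, fill holes, re-extract
  mask <- matrix(FALSE, nrow(scene$blue), ncol(scene$blue))
  for (p in keep$pixels) mask[p] <- TRUE
  mask <- fill_holes(mask, fill_box)
  labels <- cpp_label(mask, 8L)
  out <- segment_objects(scene, index, rules, labels = labels)
  out$building <- TRUE
  if (!is.null(pois)) out <- refine_residential(out, pois, poi_radius_m)
  out
}
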