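#' Maximum between-class-variance (Otsu) threshold
#'
#' Quantises the sample onto a 256-bin histogram over its observed range and
#' scans every candidate split, maximising the between-class variance
#' \code{w0 w1 (mu0 - mu1)^2}. Ties are broken by the mean of the maximising
#' bins. The returned threshold is on the original value scale (upper edge
#' of the chosen bin), so \code{values > threshold} selects the bright mode.
#'
#' @param values numeric vector (or matrix / \code{index_raster}) with at
#'   least two distinct finite values.
#' @param bins histogram resolution (default 256).
#' @return scalar threshold.
#' @export
mbcv_threshold <- function(values, bins = 256L) {
  v <- as.numeric(as_values(values))
  v <- v[is.finite(v)]
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("constant input: no two modes to separate")
  q <- floor((v - rng[1]) / (rng[2] - rng[1]) * bins)
  q[q > bins - 1] <- bins - 1L
  h <- tabulate(q + 1L, bins)
  n <- length(v)
  w0 <- cumsum(h) / n
  mu <- cumsum(h * (seq_len(bins) - 1L)) / n
  mu_tot <- mu[bins]
  w1 <- 1 - w0
  bcv <- (mu_tot * w0 - mu)^2 / (w0 * w1)
  bcv[!is.finite(bcv)] <- -Inf
  k <- which(bcv == max(bcv)) - 1L   # candidate split levels 0..bins-1
  k_star <- mean(k)
  rng[1] + (k_star + 1) / bins * (rng[2] - rng[1])
}

#' Threshold an index raster into a shadow mask with spectral filtering
#'
#' The index (MSI or the c3 variance image) is binarised at its MBCV
#' threshold; pixels that look vegetated (NDVI above \code{ndvi_max}) or
#' like water (NDWI above \code{ndwi_max}) are then removed, since both can
#' be as dark as cast shadow.
#'
#' @param index an \code{index_raster} or matrix scoring shadow presence.
#' @param ndvi,ndwi NDVI / NDWI rasters co-registered with the index.
#' @param ndvi_max,ndwi_max exclusion thresholds (defaults 0.1 each).
#' @return logical matrix.
#' @export
shadow_mask <- function(index, ndvi, ndwi, ndvi_max = 0.1, ndwi_max = 0.1) {
  v <- as_values(index)
  thr <- mbcv_threshold(v)
  mask <- v > thr
  mask[as_values(ndvi) > ndvi_max] <- FALSE
  mask[as_values(ndwi) > ndwi_max] <- FALSE
  mask
}

#' Remove speckles and road-like components from a shadow mask
#'
#' Connected components (8-connectivity) smaller than \code{min_area_m2} or
#' more elongated than \code{max_lw_ratio} are dropped: small speckles are
#' noise, very elongated dark strips are roads.
#'
#' @param mask logical matrix.
#' @param pixel_size metres per pixel.
#' @param min_area_m2 minimum component area in square metres.
#' @param max_lw_ratio maximum length/width ratio.
#' @return logical matrix of surviving components.
#' @export
component_filter <- function(mask, pixel_size, min_area_m2 = 50,
                             max_lw_ratio = 8) {
  lab <- cpp_label(mask, 8L)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab == 0) return(out)
  nr <- nrow(mask)
  idx <- which(lab > 0)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  l <- lab[idx]
  for (k in seq_len(nlab)) {
    sel <- l == k
    rk <- r[sel]; ck <- c[sel]
    if (length(rk) * pixel_size^2 < min_area_m2) next
    if (length_width_ratio(rk, ck) > max_lw_ratio) next
    out[idx[sel]] <- TRUE
  }
  out
}

#' Shadow extraction via the morphological shadow index
#'
#' MSI -> MBCV threshold -> NDVI/NDWI filtering -> component analysis.
#'
#' @param scene an \code{\link{msp_scene}}.
#' @param cfg a \code{\link{morph_config}} for the MSI.
#' @param min_area_m2,max_lw_ratio component-filter settings.
#' @param ndvi_max,ndwi_max spectral-filter settings.
#' @return logical shadow mask.
#' @export
msi_shadow <- function(scene, cfg = morph_config(), min_area_m2 = 50,
                       max_lw_ratio = 8, ndvi_max = 0.1, ndwi_max = 0.1) {
  m <- msi(scene, cfg)
  mask <- shadow_mask(m, compute_ndvi(scene), compute_ndwi(scene),
                      ndvi_max, ndwi_max)
  component_filter(mask, scene$pixel_size, min_area_m2, max_lw_ratio)
}

#' Shadow extraction via the colour-invariant index
#'
#' c3 raster -> 3x3 local variance? No: the c3 image itself localises
#' shadow; a 3x3 texture filter computes the local variance used to produce
#' contiguous shadow regions, which is then MBCV-thresholded and passed
#' through the same spectral and component filtering as the MSI route.
#'
#' @inheritParams msi_shadow
#' @param variance_filter apply the 3x3 local-variance texture filter to the
#'   c3 raster before thresholding (default TRUE).
#' @return logical shadow mask.
#' @export
ciit_shadow <- function(scene, min_area_m2 = 50, max_lw_ratio = 8,
                        ndvi_max = 0.1, ndwi_max = 0.1,
                        variance_filter = TRUE) {
  c3 <- c3_index(scene)$values
  v <- if (variance_filter) cpp_local_variance3(c3) else c3
  mask <- shadow_mask(v, compute_ndvi(scene), compute_ndwi(scene),
                      ndvi_max, ndwi_max)
  component_filter(mask, scene$pixel_size, min_area_m2, max_lw_ratio)
}

#' Decompose a shadow mask into measured components
#'
#' Labels the mask (8-connectivity) and measures each component's
#' scan-line lengths along the sun-shadow direction.
#'
#' @param mask logical shadow mask.
#' @param solar a \code{\link{solar_geometry}}.
#' @param pixel_size metres per pixel.
#' @param aggregator how to collapse per-line lengths into the component's
#'   representative length L: \code{"median"} (default), \code{"mean"} or
#'   \code{"max"}.
#' @return A data frame of class \code{shadow_components}: one row per
#'   component with \code{area_m2}, \code{L} (metres), anchor coordinates,
#'   and list-columns \code{pixels} and \code{line_lengths}.
#' @export
shadow_components <- function(mask, solar, pixel_size,
                              aggregator = c("median", "mean", "max")) {
  aggregator <- match.arg(aggregator)
  agg <- switch(aggregator, median = stats::median, mean = mean, max = max)
  lab <- cpp_label(mask, 8L)
  nlab <- max(lab)
  nr <- nrow(mask)
  rows <- list(); lens <- list(); pix <- list()
  out <- vector("list", nlab)
  for (k in seq_len(nlab)) {
    idx <- which(lab == k)
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    sl <- scanline_lengths(r, c, solar, pixel_size)
    anchor <- sun_side_anchor(r, c, solar)
    out[[k]] <- data.frame(id = k, n_pixels = length(r),
                           area_m2 = length(r) * pixel_size^2,
                           L = agg(sl),
                           anchor_row = anchor[1], anchor_col = anchor[2])
    pix[[k]] <- cbind(row = r, col = c)
    lens[[k]] <- sl
  }
  df <- if (nlab > 0) do.call(rbind, out) else
    data.frame(id = integer(), n_pixels = integer(), area_m2 = numeric(),
               L = numeric(), anchor_row = numeric(), anchor_col = numeric())
  df$pixels <- pix
  df$line_lengths <- lens
  class(df) <- c("shadow_components", class(df))
  df
}

# per-scan-line intersection lengths (metres) of a pixel set along the
# sun-shadow direction (solar azimuth + 180): pixel centres are projected
# onto the shadow axis and its perpendicular; the perpendicular offset is
# binned one pixel wide and each bin's along-axis extent is its length
scanline_lengths <- function(rows, cols, solar, pixel_size) {
  u <- compass_to_grid((solar$azimuth_deg + 180) %% 360)
  along <- (rows - 0.5) * u[1] + (cols - 0.5) * u[2]
  across <- (rows - 0.5) * -u[2] + (cols - 0.5) * u[1]
  bin <- floor(across - min(across))
  unname(vapply(split(along, bin),
                function(a) (max(a) - min(a) + 1) * pixel_size,
                numeric(1)))
}

# component pixel nearest the sun: maximal projection onto the sun azimuth
sun_side_anchor <- function(rows, cols, solar) {
  s <- compass_to_grid(solar$azimuth_deg)
  proj <- (rows - 0.5) * s[1] + (cols - 0.5) * s[2]
  i <- which.max(proj)
  c(rows[i] - 0.5, cols[i] - 0.5)
}

#' Building height from shadow length
#'
#' \code{H = L * tan(beta)} with \code{beta} the solar altitude. Valid for
#' ortho-imagery and flat terrain.
#'
#' @param L shadow length(s) in metres, >= 0.
#' @param solar a \code{\link{solar_geometry}}.
#' @return height(s) in metres.
#' @export
building_height <- function(L, solar) {
  if (!inherits(solar, "solar_geometry")) stop("solar must be a solar_geometry")
  stopifnot(all(L >= 0))
  L * tan(solar$altitude_deg * pi / 180)
}

#' Assign shadow-derived heights to buildings
#'
#' Each shadow component yields one height sample \code{H = L tan(beta)}
#' anchored at the component's sun-side pixel (the edge touching the casting
#' building). Samples are transferred to building centroids by
#' inverse-distance weighting; buildings farther than \code{max_distance_m}
#' from every sample get the median sample height instead.
#'
#' @param buildings \code{segment_objects} data frame (needs
#'   \code{centroid_row}, \code{centroid_col}).
#' @param components \code{\link{shadow_components}} data frame.
#' @param solar a \code{\link{solar_geometry}}.
#' @param pixel_size metres per pixel.
#' @param power IDW power (default 2).
#' @param max_distance_m beyond this the fallback median height is used.
#' @param default_height_m used for every building when there are no shadow
#'   components at all (with a warning).
#' @return \code{buildings} with a numeric column \code{BH_m}.
#' @export
assign_heights <- function(buildings, components, solar, pixel_size,
                           power = 2, max_distance_m = 100,
                           default_height_m = 10) {
  if (nrow(components) == 0) {
    warning("no shadow components: assigning the default height to all buildings")
    buildings$BH_m <- rep(default_height_m, nrow(buildings))
    return(buildings)
  }
  H <- building_height(components$L, solar)
  sx <- components$anchor_col * pixel_size
  sy <- components$anchor_row * pixel_size
  qx <- buildings$centroid_col * pixel_size
  qy <- buildings$centroid_row * pixel_size
  bh <- idw_interpolate(sx, sy, H, qx, qy, power)
  if (nrow(buildings) > 0) {
    dmin <- vapply(seq_along(qx), function(i)
      sqrt(min((sx - qx[i])^2 + (sy - qy[i])^2)), numeric(1))
    far <- dmin > max_distance_m
    bh[far] <- stats::median(H)
  }
  buildings$BH_m <- bh
  buildings
}

#' Absolute-error table and RMSE for height validation
#'
#' Bins the absolute height errors at 2.5 m steps (top bin open-ended at
#' 12.5 m) and reports counts, percentages and the RMSE.
#'
#' @param estimated,reference numeric vectors of heights (metres) at the
#'   validation points.
#' @return list with \code{table} (bin, count, percentage), \code{rmse}
#'   and \code{n}.
#' @export
height_error_table <- function(estimated, reference) {
  stopifnot(length(estimated) == length(reference))
  err <- abs(estimated - reference)
  edges <- c(0, 2.5, 5, 7.5, 10, 12.5, Inf)
  labels <- c("[0, 2.5)", "[2.5, 5.0)", "[5.0, 7.5)", "[7.5, 10.0)",
              "[10.0, 12.5)", ">=12.5")
  cuts <- cut(err, edges, right = FALSE, labels = labels)
  counts <- as.integer(table(cuts))
  list(table = data.frame(bin = labels, count = counts,
                          percentage = 100 * counts / length(err)),
       rmse = sqrt(mean((estimated - reference)^2)),
       n = length(err))
}
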