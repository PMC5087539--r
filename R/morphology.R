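#' Granulometry configuration for the morphological indices
#'
#' Directions and structuring-element (SE) scales of the
#' top-hat-by-reconstruction profile behind the morphological building index
#' (MBI) and morphological shadow index (MSI).
#'
#' @param directions SE directions in degrees (default 0, 45, 90, 135).
#' @param s_min,s_max smallest and largest SE length in pixels.
#' @param delta_s granulometry interval in pixels; the scale list is
#'   \code{seq(s_min, s_max, delta_s)} and must land exactly on \code{s_max}.
#'   The defaults give scales 2, 9, 16, 23, 30, 37, 44, 51, 58, 65 (S = 10).
#' @return An object of class \code{morph_config}.
#' @export
morph_config <- function(directions = c(0, 45, 90, 135), s_min = 2L,
                         s_max = 65L, delta_s = 7L) {
  stopifnot(s_min >= 2, s_max >= s_min, delta_s >= 1, length(directions) >= 1)
  if ((s_max - s_min) %% delta_s != 0)
    stop("(s_max - s_min) must be a multiple of delta_s")
  scales <- seq(s_min, s_max, by = delta_s)
  structure(list(directions = directions, s_min = s_min, s_max = s_max,
                 delta_s = delta_s, scales = scales,
                 D = length(directions), S = length(scales)),
            class = "morph_config")
}

#' Linear structuring element
#'
#' Digital line segment of the given length centred on its midpoint,
#' rasterised by integer (Bresenham) line drawing.
#'
#' @param length SE length in pixels (>= 1).
#' @param direction angle in degrees; 0 is horizontal (along columns), 90
#'   vertical, measured counter-clockwise in grid axes.
#' @return integer matrix of offsets with columns \code{(drow, dcol)}.
#' @export
linear_se <- function(length, direction = 0) {
  stopifnot(length >= 1)
  if (length == 1L) return(matrix(0L, 1L, 2L, dimnames = list(NULL, c("drow", "dcol"))))
  th <- direction * pi / 180
  if (direction %% 45 == 0) {
    # canonical directions: unit (possibly diagonal) integer steps so a
    # length-s element has exactly s pixels
    sr <- round(sin(th)); sc <- round(cos(th))
    k <- (0:(length - 1L)) - floor((length - 1L) / 2)
    off <- cbind(drow = -k * sr, dcol = k * sc)
    storage.mode(off) <- "integer"
    return(off)
  }
  # endpoint of a segment of `length` pixels: length - 1 steps
  ex <- (length - 1) * cos(th)
  ey <- (length - 1) * sin(th)
  x0 <- 0L; y0 <- 0L
  x1 <- as.integer(round(ex)); y1 <- as.integer(round(ey))
  # Bresenham from (0, 0) to (x1, y1)
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx - dy
  x <- x0; y <- y0
  pts <- matrix(0L, 0L, 2L)
  repeat {
    pts <- rbind(pts, c(x, y))
    if (x == x1 && y == y1) break
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx)  { err <- err + dx; y <- y + sy }
  }
  # centre on the midpoint; x is the column axis, -y the row axis (row down)
  mid <- pts[ceiling(nrow(pts) / 2), ]
  off <- cbind(drow = -(pts[, 2] - mid[2]), dcol = pts[, 1] - mid[1])
  storage.mode(off) <- "integer"
  off
}

#' Flat erosion / dilation by an offset structuring element
#'
#' Out-of-bounds offsets are ignored (equivalent to padding with +Inf for
#' erosion and -Inf for dilation).
#'
#' @param img numeric matrix.
#' @param se offset matrix as produced by \code{\link{linear_se}}.
#' @return numeric matrix of the same shape.
#' @export
erode_flat <- function(img, se) cpp_erode_offsets(img, se[, 1L], se[, 2L])

#' @rdname erode_flat
#' @export
dilate_flat <- function(img, se) cpp_dilate_offsets(img, se[, 1L], se[, 2L])

#' Opening and closing by reconstruction
#'
#' Opening-by-reconstruction erodes by the SE and then reconstructs
#' geodesically under the original image (8-connected), removing bright
#' structures narrower than the SE in its direction while preserving the
#' shape of everything that survives; the result is <= img pointwise.
#' Closing-by-reconstruction is the dual (dilation + reconstruction by
#' erosion above the image), result >= img pointwise.
#'
#' @param img numeric matrix.
#' @param se offset structuring element.
#' @return numeric matrix of the same shape.
#' @export
opening_by_reconstruction <- function(img, se) {
  cpp_reconstruct_dilate(erode_flat(img, se), img)
}

#' @rdname opening_by_reconstruction
#' @export
closing_by_reconstruction <- function(img, se) {
  -cpp_reconstruct_dilate(erode_flat(-img, se), -img)
}

#' White and black top-hat by reconstruction
#'
#' \code{white_top_hat = b - opening_by_reconstruction(b)} isolates bright
#' structures smaller than the SE; \code{black_top_hat =
#' closing_by_reconstruction(b) - b} isolates dark ones. Both are >= 0.
#'
#' @param b brightness matrix (or \code{index_raster}).
#' @param length,direction SE length (pixels) and direction (degrees).
#' @return numeric matrix of the same shape.
#' @export
white_top_hat <- function(b, length, direction) {
  b <- as_values(b)
  b - opening_by_reconstruction(b, linear_se(length, direction))
}

#' @rdname white_top_hat
#' @export
black_top_hat <- function(b, length, direction) {
  b <- as_values(b)
  closing_by_reconstruction(b, linear_se(length, direction)) - b
}

# per-direction top-hat stack: list over directions of list over scales
top_hat_profile <- function(b, cfg, hat = c("white", "black")) {
  hat <- match.arg(hat)
  f <- if (hat == "white") white_top_hat else black_top_hat
  lapply(cfg$directions, function(d)
    lapply(cfg$scales, function(s) f(b, s, d)))
}

#' Pointwise mean of the top-hat profile over directions at one scale
#'
#' @param profile list over directions of lists over scales of rasters, as
#'   built internally by \code{\link{mbi}}.
#' @param s_index scale position (1-based) in the configured scale list.
#' @return numeric matrix.
#' @export
directional_mean <- function(profile, s_index) {
  Reduce(`+`, lapply(profile, `[[`, s_index)) / length(profile)
}

#' Differential morphological profile
#'
#' Forward difference of the top-hat profile along the scale axis, in
#' absolute value: \code{|TH(d, s + delta_s) - TH(d, s)|}. Structures whose
#' width falls between two consecutive scales light up in the corresponding
#' difference.
#'
#' @param profile per-direction top-hat profile (see
#'   \code{\link{directional_mean}}).
#' @return list over directions of lists of S - 1 difference rasters.
#' @export
dmp <- function(profile) {
  lapply(profile, function(scales) {
    S <- length(scales)
    lapply(seq_len(S - 1L), function(k) abs(scales[[k + 1L]] - scales[[k]]))
  })
}

morph_index <- function(b, cfg, hat) {
  if (cfg$S < 2L) stop("granulometry needs at least two scales (S >= 2)")
  prof <- top_hat_profile(b, cfg, hat)
  diffs <- dmp(prof)
  acc <- 0
  for (d in diffs) for (g in d) acc <- acc + g
  acc / (cfg$D * cfg$S)
}

#' Morphological building index (MBI)
#'
#' Mean over directions and scales of the differential white
#' top-hat-by-reconstruction profile of the brightness image. Bright, compact,
#' locally contrasted structures (buildings) score high in all directions;
#' the divisor is D x S, the direction count times the scale count.
#'
#' @param scene an \code{\link{msp_scene}}, or a brightness matrix /
#'   \code{index_raster}.
#' @param cfg a \code{\link{morph_config}}.
#' @return An \code{index_raster} of kind \code{MBI}.
#' @export
mbi <- function(scene, cfg = morph_config()) {
  b <- if (inherits(scene, "msp_scene")) compute_brightness(scene)$values
       else as_values(scene)
  index_raster(morph_index(b, cfg, "white"), "MBI",
               provenance = unclass(cfg))
}

#' Morphological shadow index (MSI)
#'
#' Identical pipeline to \code{\link{mbi}} with the black top-hat in place of
#' the white one: dark, compact structures (cast shadows) score high.
#'
#' @inheritParams mbi
#' @return An \code{index_raster} of kind \code{MSI}.
#' @export
msi <- function(scene, cfg = morph_config()) {
  b <- if (inherits(scene, "msp_scene")) compute_brightness(scene)$values
       else as_values(scene)
  index_raster(morph_index(b, cfg, "black"), "MSI",
               provenance = unclass(cfg))
}
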