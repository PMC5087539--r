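#' Solar geometry
#'
#' Sun position at image acquisition. The altitude drives height retrieval
#' (\code{H = L * tan(beta)}); the azimuth, measured clockwise from grid
#' north, determines where shadows fall: the shadow direction is
#' \code{azimuth + 180} degrees (mod 360).
#'
#' @param altitude_deg solar altitude in degrees, strictly inside (0, 90).
#' @param azimuth_deg solar azimuth in degrees, in [0, 360), clockwise from
#'   grid north.
#' @return An object of class \code{solar_geometry}.
#' @export
solar_geometry <- function(altitude_deg, azimuth_deg) {
  stopifnot(is.numeric(altitude_deg), length(altitude_deg) == 1L,
            is.numeric(azimuth_deg), length(azimuth_deg) == 1L)
  if (!is.finite(altitude_deg) || altitude_deg <= 0 || altitude_deg >= 90)
    stop("solar altitude must lie strictly inside (0, 90) degrees")
  azimuth_deg <- azimuth_deg %% 360
  structure(list(altitude_deg = altitude_deg, azimuth_deg = azimuth_deg),
            class = "solar_geometry")
}

#' @export
print.solar_geometry <- function(x, ...) {
  cat(sprintf("Solar geometry: altitude %.2f deg, azimuth %.2f deg (shadow direction %.2f deg)\n",
              x$altitude_deg, x$azimuth_deg, (x$azimuth_deg + 180) %% 360))
  invisible(x)
}

#' Unit direction vector in grid coordinates for a compass angle
#'
#' Grid convention: row 1 is the north edge, rows increase southward,
#' columns increase eastward. A compass angle theta (clockwise from north)
#' therefore maps to the grid step (drow, dcol) = (-cos(theta), sin(theta)).
#'
#' @param compass_deg compass angle in degrees clockwise from north.
#' @return numeric length-2 vector \code{c(drow, dcol)} of unit length.
#' @export
compass_to_grid <- function(compass_deg) {
  th <- compass_deg * pi / 180
  c(drow = -cos(th), dcol = sin(th))
}

#' Multispectral scene
#'
#' Container for a co-registered band stack: blue/green/red/NIR digital
#' numbers (0-255 after normalisation) on one working grid, an optional
#' panchromatic band on the same grid, the ground pixel size, a simple
#' north-up geotransform (world coordinates of the top-left raster corner),
#' and the solar geometry.
#'
#' @param blue,green,red,nir numeric matrices of digital numbers, all the
#'   same shape, finite and non-negative.
#' @param pan optional panchromatic matrix on the same grid; defaults to the
#'   per-pixel band maximum when absent.
#' @param pixel_size ground sampling distance in metres per pixel (> 0).
#' @param solar a \code{\link{solar_geometry}}.
#' @param origin world coordinates \code{c(x, y)} of the top-left corner of
#'   pixel (1, 1); x increases east, y increases north.
#' @return An object of class \code{msp_scene}.
#' @export
msp_scene <- function(blue, green, red, nir, pan = NULL, pixel_size = 2.5,
                      solar = solar_geometry(68.68, 180),
                      origin = c(0, 0)) {
  bands <- list(blue = blue, green = green, red = red, nir = nir)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (!is.matrix(b) || !is.numeric(b))
      stop("band '", nm, "' must be a numeric matrix")
    if (any(!is.finite(b)) || any(b < 0))
      stop("band '", nm, "' must be finite and non-negative")
  }
  dm <- dim(blue)
  if (!all(vapply(bands, function(b) identical(dim(b), dm), logical(1))))
    stop("all multispectral bands must share one shape")
  if (is.null(pan)) pan <- pmax(blue, pmax(green, pmax(red, nir)))
  if (!identical(dim(pan), dm))
    stop("pan band must be co-registered on the multispectral grid")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a positive scalar (metres)")
  if (!inherits(solar, "solar_geometry")) stop("solar must be a solar_geometry")
  structure(list(blue = blue, green = green, red = red, nir = nir, pan = pan,
                 pixel_size = pixel_size, solar = solar,
                 origin = as.numeric(origin)),
            class = "msp_scene")
}

#' @export
print.msp_scene <- function(x, ...) {
  cat(sprintf("Multispectral scene: %d x %d pixels at %.2f m/pixel\n",
              nrow(x$blue), ncol(x$blue), x$pixel_size))
  print(x$solar)
  invisible(x)
}

#' @export
dim.msp_scene <- function(x) dim(x$blue)

#' Derived single-band index raster
#'
#' @param values numeric matrix.
#' @param kind one of \code{"PANTEX"}, \code{"MBI"}, \code{"MSI"},
#'   \code{"C3"}, \code{"NDVI"}, \code{"NDWI"}, \code{"BRIGHTNESS"}.
#' @param provenance list recording the parameters used to compute it.
#' @return An object of class \code{index_raster}.
#' @export
index_raster <- function(values, kind, provenance = list()) {
  kind <- match.arg(kind, c("PANTEX", "MBI", "MSI", "C3", "NDVI", "NDWI",
                            "BRIGHTNESS"))
  stopifnot(is.matrix(values), is.numeric(values))
  structure(list(values = values, kind = kind, provenance = provenance),
            class = "index_raster")
}

#' @export
print.index_raster <- function(x, ...) {
  rng <- range(x$values, finite = TRUE)
  cat(sprintf("%s index raster: %d x %d, range [%.4g, %.4g]\n",
              x$kind, nrow(x$values), ncol(x$values), rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.index_raster <- function(x) dim(x$values)

as_values <- function(x) {
  if (inherits(x, "index_raster")) x$values else x
}

#' Brightness: per-pixel maximum over the multispectral bands
#'
#' @param scene an \code{\link{msp_scene}}.
#' @return An \code{index_raster} of kind \code{BRIGHTNESS}.
#' @export
compute_brightness <- function(scene) {
  stopifnot(inherits(scene, "msp_scene"))
  b <- pmax(scene$blue, pmax(scene$green, pmax(scene$red, scene$nir)))
  index_raster(b, "BRIGHTNESS")
}

safe_ratio <- function(num, den) {
  out <- num / den
  out[den == 0] <- 0
  out
}

#' Normalised difference vegetation index
#'
#' \code{NDVI = (NIR - R) / (NIR + R)} per pixel; pixels with a zero
#' denominator map to 0.
#'
#' @inheritParams compute_brightness
#' @return An \code{index_raster} of kind \code{NDVI}, values in [-1, 1].
#' @export
compute_ndvi <- function(scene) {
  stopifnot(inherits(scene, "msp_scene"))
  index_raster(safe_ratio(scene$nir - scene$red, scene$nir + scene$red), "NDVI")
}

#' Normalised difference water index
#'
#' \code{NDWI = (G - NIR) / (G + NIR)} per pixel; zero-denominator pixels
#' map to 0.
#'
#' @inheritParams compute_brightness
#' @return An \code{index_raster} of kind \code{NDWI}, values in [-1, 1].
#' @export
compute_ndwi <- function(scene) {
  stopifnot(inherits(scene, "msp_scene"))
  index_raster(safe_ratio(scene$green - scene$nir, scene$green + scene$nir),
               "NDWI")
}

#' Colour-invariant shadow index c3
#'
#' \code{c3 = arctan(B / max(R, G))} per pixel. Shadowed pixels keep a
#' relatively strong blue response, so c3 is high over shadow. Conventions
#' for degenerate pixels: when \code{max(R, G) = 0} and \code{B > 0} the
#' value is \code{pi/2}; when all three bands are 0 the value is 0.
#'
#' @inheritParams compute_brightness
#' @return An \code{index_raster} of kind \code{C3}, values in [0, pi/2].
#' @export
c3_index <- function(scene) {
  stopifnot(inherits(scene, "msp_scene"))
  den <- pmax(scene$red, scene$green)
  v <- atan2(scene$blue, den)
  v[scene$blue == 0] <- 0
  index_raster(v, "C3")
}

#' Rescale a raster linearly onto integer gray levels
#'
#' Maps the observed range onto \code{0 .. levels - 1}. Constant rasters map
#' to all zeros.
#'
#' @param x numeric matrix or \code{index_raster}.
#' @param levels integer number of gray levels (>= 2).
#' @return integer matrix with values in \code{[0, levels)}.
#' @export
quantize_levels <- function(x, levels = 256L) {
  v <- as_values(x)
  stopifnot(levels >= 2)
  rng <- range(v, finite = TRUE)
  if (rng[2] == rng[1]) return(matrix(0L, nrow(v), ncol(v)))
  q <- floor((v - rng[1]) / (rng[2] - rng[1]) * levels)
  q[q > levels - 1] <- levels - 1L
  storage.mode(q) <- "integer"
  q
}
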