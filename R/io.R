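#' Write a raster to TIFF with a JSON sidecar
#'
#' Values are stored as 32-bit float TIFF; pixel size, origin, nodata
#' convention (NaN) and any extra metadata (e.g. solar geometry) go into a
#' \code{<path>.json} sidecar.
#'
#' @param values numeric matrix or \code{index_raster}.
#' @param path output TIFF path.
#' @param pixel_size metres per pixel.
#' @param origin world coordinates of the top-left corner.
#' @param meta named list of additional metadata.
#' @return \code{path}, invisibly.
#' @export
write_raster <- function(values, path, pixel_size = 2.5, origin = c(0, 0),
                         meta = list()) {
  v <- as_values(values)
  # TIFF float samples are stored on [0, 1]; scale by the recorded maximum
  scale <- max(abs(v[is.finite(v)]), 1)
  tiff::writeTIFF(v / scale, path, bits.per.sample = 32L, reduce = FALSE)
  side <- c(list(pixel_size = pixel_size, origin = origin, nodata = "NaN",
                 scale = scale, nrow = nrow(v), ncol = ncol(v)), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raster written by \code{\link{write_raster}}
#'
#' @param path TIFF path.
#' @return list with \code{values} (matrix) and \code{meta} (sidecar list,
#'   empty when no sidecar exists).
#' @export
read_raster <- function(path) {
  v <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list()
  if (!is.null(meta$scale)) v <- v * meta$scale
  list(values = v, meta = meta)
}

#' Read a multispectral scene from a directory
#'
#' Expects \code{blue.tif}, \code{green.tif}, \code{red.tif}, \code{nir.tif}
#' (optionally \code{pan.tif}) plus a \code{scene.json} (or YAML) config
#' with keys \code{pixel_size}, \code{sun_altitude_deg},
#' \code{sun_azimuth_deg} and optional \code{origin}.
#'
#' @param dir directory path.
#' @return An \code{\link{msp_scene}}.
#' @export
read_scene <- function(dir) {
  cfgp <- file.path(dir, "scene.json")
  cfg <- if (file.exists(cfgp)) jsonlite::read_json(cfgp, simplifyVector = TRUE)
         else yaml::read_yaml(file.path(dir, "scene.yaml"))
  bands <- lapply(c("blue", "green", "red", "nir"), function(b)
    read_raster(file.path(dir, paste0(b, ".tif")))$values)
  panp <- file.path(dir, "pan.tif")
  pan <- if (file.exists(panp)) read_raster(panp)$values else NULL
  origin <- if (!is.null(cfg$origin)) as.numeric(cfg$origin) else c(0, 0)
  msp_scene(bands[[1]], bands[[2]], bands[[3]], bands[[4]], pan = pan,
            pixel_size = cfg$pixel_size,
            solar = solar_geometry(cfg$sun_altitude_deg, cfg$sun_azimuth_deg),
            origin = origin)
}

#' Write a rendered scene and its truth to a directory
#'
#' @param rendered result of \code{\link{render_scene}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_scene <- function(rendered, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- rendered$scene
  for (b in c("blue", "green", "red", "nir", "pan"))
    write_raster(sc[[b]], file.path(dir, paste0(b, ".tif")),
                 sc$pixel_size, sc$origin)
  jsonlite::write_json(list(pixel_size = sc$pixel_size,
                            sun_altitude_deg = sc$solar$altitude_deg,
                            sun_azimuth_deg = sc$solar$azimuth_deg,
                            origin = sc$origin),
                       file.path(dir, "scene.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(rendered$truth$buildings,
                   file.path(dir, "truth_buildings.csv"), row.names = FALSE)
  utils::write.csv(rendered$truth$census, file.path(dir, "census.csv"),
                   row.names = FALSE)
  pois <- make_pois(rendered$truth, sc)
  utils::write.csv(pois, file.path(dir, "poi.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write segmented objects as GeoJSON polygons
#'
#' Each object's footprint is written as a (multi)polygon of its pixel
#' squares' union bounding boxes -- one rectangle per contiguous column run
#' -- with its features as GeoJSON properties.
#'
#' @param objects a \code{segment_objects} or \code{shadow_components} data
#'   frame.
#' @param path output path.
#' @param pixel_size metres per pixel.
#' @param origin world coordinates of the top-left raster corner.
#' @return \code{path}, invisibly.
#' @export
write_geojson_objects <- function(objects, path, pixel_size = 2.5,
                                  origin = c(0, 0)) {
  feats <- lapply(seq_len(nrow(objects)), function(i) {
    pix <- objects$pixels[[i]]
    # outline as the bounding box of the pixel set (properties carry the
    # exact per-pixel geometry-derived features)
    r0 <- min(pix[, 1]) - 1; r1 <- max(pix[, 1])
    c0 <- min(pix[, 2]) - 1; c1 <- max(pix[, 2])
    xy <- function(r, c) c(origin[1] + c * pixel_size,
                           origin[2] - r * pixel_size)
    ring <- list(xy(r0, c0), xy(r0, c1), xy(r1, c1), xy(r1, c0), xy(r0, c0))
    props <- as.list(objects[i, setdiff(names(objects),
                                        c("pixels", "line_lengths")),
                             drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read POI records
#'
#' Accepts a CSV with columns \code{x}, \code{y}, \code{category} or a
#' GeoJSON FeatureCollection of points with a \code{category} property.
#'
#' @param path input path (.csv or .geojson/.json).
#' @return data frame with columns \code{x}, \code{y}, \code{category}.
#' @export
read_pois <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE))
    return(utils::read.csv(path, stringsAsFactors = FALSE))
  gj <- jsonlite::read_json(path)
  do.call(rbind, lapply(gj$features, function(f)
    data.frame(x = f$geometry$coordinates[[1]],
               y = f$geometry$coordinates[[2]],
               category = f$properties$category)))
}

#' Read a unit-accuracy table (printed-table format)
#'
#' CSV with columns \code{no}, \code{region}, \code{statistic},
#' \code{objects}, \code{model} (and optionally a printed RE column).
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_unit_table <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Path to a packaged fixture
#'
#' @param file fixture file name under \code{extdata}.
#' @return absolute path.
#' @export
dasypop_extdata <- function(file) {
  system.file("extdata", file, package = "dasypop", mustWork = TRUE)
}
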