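#' Synthetic urban scene specification
#'
#' Declarative description of a fully ground-truthed scene: rectangular
#' bright rooftops that cast geometrically consistent shadows
#' (ground length \code{height / tan(beta)} along azimuth + 180), plus
#' vegetation, water and road distractor patches, additive Gaussian noise,
#' a zone/unit map and census totals generated by the forward population
#' model. Everything every pipeline stage consumes can be emulated from it.
#'
#' @param nrow,ncol image size in pixels.
#' @param pixel_size metres per pixel (default 2.5, the working resolution
#'   of the study imagery).
#' @param solar a \code{\link{solar_geometry}}; default altitude 68.68
#'   degrees, azimuth 180 (shadows fall due north).
#' @param buildings data frame with columns \code{row}, \code{col} (top-left
#'   footprint pixel), \code{nrow_px}, \code{ncol_px} (footprint size),
#'   \code{height_m}, \code{unit}, \code{zone}, \code{roof_dn},
#'   \code{residential}.
#' @param patches data frame of distractors with columns \code{row},
#'   \code{col}, \code{nrow_px}, \code{ncol_px}, \code{type} in
#'   \{vegetation, water, road\}.
#' @param background_dn,shadow_dn digital numbers of ground and shadow.
#' @param noise_sd additive Gaussian noise standard deviation (digital
#'   numbers).
#' @param seed integer controlling all randomness in rendering.
#' @return An object of class \code{scene_spec}.
#' @export
scene_spec <- function(nrow, ncol, pixel_size = 2.5,
                       solar = solar_geometry(68.68, 180),
                       buildings, patches = NULL,
                       background_dn = 80, shadow_dn = 20,
                       noise_sd = 0, seed = 1L) {
  stopifnot(nrow > 0, ncol > 0, pixel_size > 0,
            inherits(solar, "solar_geometry"))
  req <- c("row", "col", "nrow_px", "ncol_px", "height_m", "unit", "zone",
           "roof_dn", "residential")
  if (!all(req %in% names(buildings)))
    stop("buildings needs columns: ", paste(req, collapse = ", "))
  if (any(buildings$height_m <= 0)) stop("building heights must be positive")
  if (any(buildings$row < 1 | buildings$col < 1 |
          buildings$row + buildings$nrow_px - 1 > nrow |
          buildings$col + buildings$ncol_px - 1 > ncol))
    stop("buildings must lie within the image bounds")
  # reject overlapping footprints so every shadow is unambiguous
  occ <- matrix(FALSE, nrow, ncol)
  for (i in seq_len(base::nrow(buildings))) {
    r <- buildings$row[i]:(buildings$row[i] + buildings$nrow_px[i] - 1L)
    c <- buildings$col[i]:(buildings$col[i] + buildings$ncol_px[i] - 1L)
    if (any(occ[r, c])) stop("overlapping buildings rejected")
    occ[r, c] <- TRUE
  }
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 pixel_size = pixel_size, solar = solar,
                 buildings = buildings, patches = patches,
                 background_dn = background_dn, shadow_dn = shadow_dn,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 n_units = max(buildings$unit)),
            class = "scene_spec")
}

#' Random non-overlapping scene specification
#'
#' Draws rectangular buildings with footprint aspect ratios inside the
#' classifier's accepted range, heights that are whole multiples of the
#' shadow-resolvable step \code{pixel_size * tan(beta)}, vertical-strip
#' administrative units cycling through the three dasymetric density
#' classes, and a few vegetation/water/road distractors. Building and
#' shadow bounding boxes (plus a margin) are kept disjoint by rejection
#' sampling.
#'
#' @param n_buildings number of buildings to place.
#' @param nrow,ncol,pixel_size,solar,noise_sd,seed see
#'   \code{\link{scene_spec}}.
#' @param n_units number of vertical-strip administrative units.
#' @param n_patches number of distractor patches per type.
#' @param roof_dn rooftop digital number.
#' @return A \code{\link{scene_spec}}.
#' @export
random_scene_spec <- function(n_buildings = 20, nrow = 512, ncol = 512,
                              pixel_size = 2.5,
                              solar = solar_geometry(68.68, 180),
                              noise_sd = 0, seed = 1L, n_units = 4,
                              n_patches = 2, roof_dn = 200) {
  set.seed(seed)
  tanb <- tan(solar$altitude_deg * pi / 180)
  occ <- matrix(FALSE, nrow, ncol)
  blk <- function(r0, r1, c0, c1) {
    r0 <- max(1, r0); r1 <- min(nrow, r1)
    c0 <- max(1, c0); c1 <- min(ncol, c1)
    occ[r0:r1, c0:c1]
  }
  mark <- function(r0, r1, c0, c1) {
    r0 <- max(1, r0); r1 <- min(nrow, r1)
    c0 <- max(1, c0); c1 <- min(ncol, c1)
    occ[r0:r1, c0:c1] <<- TRUE
  }
  rows <- list()
  tries <- 0L
  while (length(rows) < n_buildings && tries < 20000L) {
    tries <- tries + 1L
    w <- sample(5:10, 1)                     # footprint columns
    l <- round(w * stats::runif(1, 1.8, 3.2)) # rows, aspect inside [1.5, 4.5]
    sh <- sample(2:8, 1)                     # shadow length in pixels
    h <- sh * pixel_size * tanb              # exactly resolvable height
    r <- sample(seq(sh + 4, nrow - l - 3), 1)
    c <- sample(seq(4, ncol - w - 3), 1)
    # footprint + due-north shadow + margin must be free
    if (any(blk(r - sh - 3, r + l + 2, c - 3, c + w + 2))) next
    mark(r - sh - 3, r + l + 2, c - 3, c + w + 2)
    rows[[length(rows) + 1L]] <-
      data.frame(row = r, col = c, nrow_px = l, ncol_px = w, height_m = h)
  }
  if (length(rows) < n_buildings)
    stop("could not place ", n_buildings, " disjoint buildings; reduce density")
  b <- do.call(rbind, rows)
  strip <- ceiling(ncol / n_units)
  # same centroid-to-strip mapping the pipeline uses
  b$unit <- pmin(floor(b$col + b$ncol_px / 2 - 0.5) %/% strip + 1L, n_units)
  b$zone <- c("high", "medium", "low")[(b$unit - 1L) %% 3L + 1L]
  b$roof_dn <- roof_dn
  b$residential <- TRUE
  patches <- NULL
  if (n_patches > 0) {
    mk <- function(type, nr_px, nc_px) {
      got <- list(); t2 <- 0L
      while (length(got) < n_patches && t2 < 5000L) {
        t2 <- t2 + 1L
        r <- sample(seq(2, nrow - nr_px - 1), 1)
        c <- sample(seq(2, ncol - nc_px - 1), 1)
        if (any(blk(r - 1, r + nr_px, c - 1, c + nc_px))) next
        mark(r - 1, r + nr_px, c - 1, c + nc_px)
        got[[length(got) + 1L]] <-
          data.frame(row = r, col = c, nrow_px = nr_px, ncol_px = nc_px,
                     type = type)
      }
      do.call(rbind, got)
    }
    patches <- rbind(mk("vegetation", 20L, 20L), mk("water", 15L, 15L),
                     mk("road", 3L, min(150L, ncol - 10L)))
  }
  sp <- scene_spec(nrow, ncol, pixel_size, solar, b, patches,
                   noise_sd = noise_sd, seed = seed)
  sp$n_units <- n_units   # strips are laid out for the requested unit count
  sp
}

#' Dasymetric zone presets
#'
#' Zone parameter table for the three density classes used in scenario
#' reproduction, labelled with the study densities (15448.06, 7942.72 and
#' 3060.53 people per square kilometre). The living area per person (LA, m2)
#' and height per floor (AH, m) values are package presets chosen to be
#' plausible for dense, medium and low-rise urban fabric; on real data both
#' are field-survey inputs.
#'
#' @return data frame with columns \code{zone}, \code{density_km2},
#'   \code{LA}, \code{AH}.
#' @export
zone_presets <- function() {
  data.frame(zone = c("high", "medium", "low"),
             density_km2 = c(15448.06, 7942.72, 3060.53),
             LA = c(20, 30, 40),
             AH = c(2.8, 3.0, 3.2))
}

#' Render a synthetic scene and its ground truth
#'
#' Paints background, distractor patches (vegetation with NIR much greater
#' than red, water with green much greater than NIR and a dark brightness,
#' bright elongated roads), cast shadows (dark quadrilaterals of ground
#' length \code{height / tan(beta)} along azimuth + 180) and rooftops
#' (bright in all bands); then adds seeded Gaussian noise clipped to
#' [0, 255].
#'
#' @param spec a \code{\link{scene_spec}}.
#' @param zones zone parameter table (see \code{\link{zone_presets}}) used
#'   to generate the census truth by the forward population model.
#' @return list with \code{scene} (an \code{\link{msp_scene}}) and
#'   \code{truth} (footprint mask, shadow mask, per-building table, unit
#'   map, zone table, per-unit census).
#' @export
render_scene <- function(spec, zones = zone_presets()) {
  stopifnot(inherits(spec, "scene_spec"))
  nr <- spec$nrow; nc <- spec$ncol
  bg <- spec$background_dn
  blue <- matrix(bg, nr, nc); green <- matrix(bg, nr, nc)
  red <- matrix(bg, nr, nc); nir <- matrix(bg, nr, nc)
  paint <- function(rows, cols, b, g, r, n) {
    blue[rows, cols] <<- b; green[rows, cols] <<- g
    red[rows, cols] <<- r;  nir[rows, cols] <<- n
  }
  if (!is.null(spec$patches)) for (i in seq_len(nrow(spec$patches))) {
    p <- spec$patches[i, ]
    rows <- p$row:(p$row + p$nrow_px - 1L)
    cols <- p$col:(p$col + p$ncol_px - 1L)
    switch(as.character(p$type),
           vegetation = paint(rows, cols, 50, 90, 40, 200),   # NDVI 0.67
           water      = paint(rows, cols, 50, 60, 30, 10),    # NDWI 0.71, dark
           road       = paint(rows, cols, 160, 160, 160, 160))
  }
  tanb <- tan(spec$solar$altitude_deg * pi / 180)
  u <- compass_to_grid((spec$solar$azimuth_deg + 180) %% 360)
  fp <- matrix(FALSE, nr, nc)
  sh <- matrix(FALSE, nr, nc)
  b <- spec$buildings
  for (i in seq_len(nrow(b))) {
    rows <- b$row[i]:(b$row[i] + b$nrow_px[i] - 1L)
    cols <- b$col[i]:(b$col[i] + b$ncol_px[i] - 1L)
    len_px <- round(b$height_m[i] / tanb / spec$pixel_size)
    if (len_px > 0) {
      # sweep every footprint pixel along the shadow direction
      for (k in seq_len(len_px)) {
        rr <- pmin(pmax(round(rep(rows, length(cols)) + k * u[1]), 1L), nr)
        cc <- pmin(pmax(round(rep(cols, each = length(rows)) + k * u[2]), 1L), nc)
        sh[cbind(rr, cc)] <- TRUE
      }
    }
  }
  for (i in seq_len(nrow(b))) {
    rows <- b$row[i]:(b$row[i] + b$nrow_px[i] - 1L)
    cols <- b$col[i]:(b$col[i] + b$ncol_px[i] - 1L)
    fp[rows, cols] <- TRUE
  }
  sh <- sh & !fp
  sdn <- spec$shadow_dn
  blue[sh] <- sdn; green[sh] <- sdn; red[sh] <- sdn; nir[sh] <- sdn
  for (i in seq_len(nrow(b))) {
    rows <- b$row[i]:(b$row[i] + b$nrow_px[i] - 1L)
    cols <- b$col[i]:(b$col[i] + b$ncol_px[i] - 1L)
    paint(rows, cols, b$roof_dn[i], b$roof_dn[i], b$roof_dn[i], b$roof_dn[i])
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    addn <- function(m) pmin(pmax(m + stats::rnorm(length(m), 0, spec$noise_sd), 0), 255)
    blue <- addn(blue); green <- addn(green); red <- addn(red); nir <- addn(nir)
  }
  scene <- msp_scene(blue, green, red, nir, pixel_size = spec$pixel_size,
                     solar = spec$solar, origin = c(0, nr * spec$pixel_size))
  units <- sort(unique(b$unit))
  bt <- data.frame(id = seq_len(nrow(b)),
                   FS_m2 = b$nrow_px * b$ncol_px * spec$pixel_size^2,
                   BH_m = b$height_m,
                   unit = b$unit, zone = b$zone,
                   residential = b$residential,
                   centroid_row = b$row + b$nrow_px / 2 - 0.5,
                   centroid_col = b$col + b$ncol_px / 2 - 0.5)
  truth <- list(footprint = fp, shadow = sh, buildings = bt,
                zones = zones,
                census = make_census(bt, zones))
  list(scene = scene, truth = truth)
}

#' Forward population model: per-unit census from ground truth
#'
#' Applies the population model with no constant and no error term
#' (\code{pop_i = (FS / LA_t)(BH / AH_t)}) to the true buildings and sums by
#' administrative unit.
#'
#' @param buildings truth building table with \code{FS_m2}, \code{BH_m},
#'   \code{zone}, \code{unit}.
#' @param zones zone table with \code{zone}, \code{LA}, \code{AH}.
#' @param round round the per-unit totals to whole persons.
#' @return data frame with columns \code{unit} and \code{census}.
#' @export
make_census <- function(buildings, zones = zone_presets(), round = FALSE) {
  zi <- match(buildings$zone, zones$zone)
  pop <- raw_population(buildings$FS_m2, buildings$BH_m,
                        zones$LA[zi], zones$AH[zi])
  tot <- tapply(pop, buildings$unit, sum)
  out <- data.frame(unit = as.integer(names(tot)), census = as.numeric(tot))
  if (round) out$census <- base::round(out$census)
  out
}

#' Point-of-interest records for a rendered scene
#'
#' One residential POI at the centroid of every residential building, plus
#' distractor POIs of the other categories at non-building locations.
#'
#' @param truth the truth component of \code{\link{render_scene}}.
#' @param scene the rendered \code{\link{msp_scene}} (for the
#'   geotransform).
#' @param n_distractors number of non-residential POIs.
#' @param seed integer seed for distractor placement.
#' @return data frame with columns \code{x}, \code{y}, \code{category}.
#' @export
make_pois <- function(truth, scene, n_distractors = 10, seed = 1L) {
  bt <- truth$buildings
  res <- bt[bt$residential, , drop = FALSE]
  ps <- scene$pixel_size
  pois <- data.frame(x = scene$origin[1] + res$centroid_col * ps,
                     y = scene$origin[2] - res$centroid_row * ps,
                     category = "residential")
  if (n_distractors > 0) {
    set.seed(seed)
    cats <- c("public_service", "financial", "commercial", "entertainment")
    free <- which(!truth$footprint)
    pick <- sample(free, n_distractors)
    nr <- nrow(truth$footprint)
    r <- ((pick - 1L) %% nr) + 0.5
    c <- ((pick - 1L) %/% nr) + 0.5
    pois <- rbind(pois,
                  data.frame(x = scene$origin[1] + c * ps,
                             y = scene$origin[2] - r * ps,
                             category = sample(cats, n_distractors,
                                               replace = TRUE)))
  }
  pois
}
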