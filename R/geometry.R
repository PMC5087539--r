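# Internal geometry helpers shared by the building and shadow modules.
# Pixel (r, c) is treated as the unit square [c-1, c] x [r-1, r] in grid
# units; its centre is (r - 0.5, c - 0.5).

# corner points (x = col, y = row axes) of a set of pixels, deduplicated
pixel_corners <- function(rows, cols) {
  x <- c(cols - 1, cols, cols - 1, cols)
  y <- c(rows - 1, rows - 1, rows, rows)
  pts <- unique(cbind(x, y))
  pts
}

# minimum-area oriented bounding box by rotating calipers over hull edges.
# Returns list(length, width, angle, center): length >= width, angle in
# radians of the long side in (x, y) axes.
min_area_rect <- function(rows, cols) {
  pts <- pixel_corners(rows, cols)
  if (nrow(pts) == 1L)
    return(list(length = 0, width = 0, angle = 0, center = pts[1, ]))
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  n <- nrow(hull)
  if (n == 2L) {
    d <- hull[2, ] - hull[1, ]
    return(list(length = sqrt(sum(d^2)), width = 0,
                angle = atan2(d[2], d[1]),
                center = colMeans(hull)))
  }
  best <- NULL
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len               # edge direction
    v <- c(-u[2], u[1])        # normal
    pu <- hull %*% u
    pv <- hull %*% v
    du <- max(pu) - min(pu)
    dv <- max(pv) - min(pv)
    area <- du * dv
    if (is.null(best) || area < best$area) {
      cu <- (max(pu) + min(pu)) / 2
      cv <- (max(pv) + min(pv)) / 2
      best <- list(area = area, du = du, dv = dv, u = u, v = v,
                   center = cu * u + cv * v)
    }
  }
  if (best$du >= best$dv) {
    list(length = best$du, width = best$dv,
         angle = atan2(best$u[2], best$u[1]), center = best$center)
  } else {
    list(length = best$dv, width = best$du,
         angle = atan2(best$v[2], best$v[1]), center = best$center)
  }
}

# exposed-edge perimeter of a pixel set, in pixel-edge units:
# 4n minus twice the number of 4-adjacent pixel pairs
pixel_perimeter <- function(rows, cols) {
  nc <- max(cols) + 2L
  key <- rows * nc + cols
  right <- sum((rows * nc + cols + 1L) %in% key)
  down  <- sum(((rows + 1L) * nc + cols) %in% key)
  as.integer(4L * length(rows) - 2L * (right + down))
}

# inverse-distance-weighted interpolation from sample points to query points
# (2-D, power p); exact hits take the sample value
idw_interpolate <- function(sx, sy, sv, qx, qy, power = 2) {
  vapply(seq_along(qx), function(i) {
    d2 <- (sx - qx[i])^2 + (sy - qy[i])^2
    hit <- d2 < 1e-12
    if (any(hit)) return(mean(sv[hit]))
    w <- 1 / d2^(power / 2)
    sum(w * sv) / sum(w)
  }, numeric(1))
}
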