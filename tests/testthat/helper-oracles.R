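# Independent brute-force oracles used across the suite. These deliberately
# take the slowest, most literal route so they share no code with the
# implementation they check.

# co-occurrence matrix by explicit double loop over all pixel pairs
oracle_glcm <- function(window, displacement, levels) {
  counts <- matrix(0, levels, levels)
  nr <- nrow(window); nc <- ncol(window)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + displacement[1]; c2 <- c + displacement[2]
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
      i <- window[r, c] + 1L; j <- window[r2, c2] + 1L
      counts[i, j] <- counts[i, j] + 1
    }
  }
  sym <- counts + t(counts)
  sym / sum(sym)
}

# contrast by explicit double loop over the matrix entries
oracle_contrast <- function(p) {
  s <- 0
  n <- nrow(p)
  for (i in seq_len(n)) for (j in seq_len(n))
    s <- s + (i - j)^2 * p[i, j]
  s
}

# PanTex by building all per-displacement GLCMs in each truncated window
oracle_pantex <- function(q, window, displacements, levels) {
  nr <- nrow(q); nc <- ncol(q)
  h <- (window - 1) / 2
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    w <- q[max(1, r - h):min(nr, r + h), max(1, c - h):min(nc, c + h),
           drop = FALSE]
    vals <- apply(displacements, 1L, function(d) {
      p <- tryCatch(oracle_glcm(w, d, levels), error = function(e) NULL)
      if (is.null(p) || any(is.na(p))) return(NA_real_)
      oracle_contrast(p)
    })
    vals <- vals[!is.na(vals)]
    out[r, c] <- if (length(vals)) min(vals) else 0
  }
  out
}

# grayscale reconstruction by dilation as a literal fixpoint of geodesic
# 3x3 (8-connected) dilations clipped under the mask
oracle_reconstruct <- function(marker, mask) {
  J <- marker
  repeat {
    nr <- nrow(J); nc <- ncol(J)
    D <- J
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      shifted <- matrix(-Inf, nr, nc)
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      shifted[rs, cs] <- J[rs - dr, cs - dc]
      D <- pmax(D, shifted)
    }
    D <- pmin(D, mask)
    if (all(D == J)) return(J)
    J <- D
  }
}

# between-class-variance threshold by scanning every candidate level
oracle_mbcv_level <- function(v, bins = 256L) {
  rng <- range(v)
  q <- floor((v - rng[1]) / (rng[2] - rng[1]) * bins)
  q[q > bins - 1] <- bins - 1
  best <- -Inf; ks <- integer(0)
  n <- length(q)
  for (k in 0:(bins - 1)) {
    in0 <- q <= k
    n0 <- sum(in0); n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    w0 <- n0 / n; w1 <- n1 / n
    bcv <- w0 * w1 * (mean(q[in0]) - mean(q[!in0]))^2
    if (bcv > best + 1e-12) { best <- bcv; ks <- k }
    else if (abs(bcv - best) <= 1e-12) ks <- c(ks, k)
  }
  mean(ks)
}

# minimum-area oriented bounding box by dense angle sweep over the pixel
# corner cloud
oracle_lw_ratio <- function(rows, cols) {
  x <- c(cols - 1, cols, cols - 1, cols)
  y <- c(rows - 1, rows - 1, rows, rows)
  best <- Inf; lw <- NA
  for (a in seq(0, 90, by = 0.05) * pi / 180) {
    u <- c(cos(a), sin(a)); v <- c(-sin(a), cos(a))
    du <- diff(range(x * u[1] + y * u[2]))
    dv <- diff(range(x * v[1] + y * v[2]))
    if (du * dv < best) { best <- du * dv; lw <- max(du, dv) / min(du, dv) }
  }
  lw
}

# small constant-background scene with painted rectangles
toy_scene <- function(nr = 24, nc = 24, bg = 80, rects = list(),
                      value = 200, solar = solar_geometry(68.68, 180),
                      pixel_size = 2.5) {
  m <- matrix(bg, nr, nc)
  for (rc in rects) m[rc[1]:rc[2], rc[3]:rc[4]] <- value
  msp_scene(m, m, m, m, pixel_size = pixel_size, solar = solar)
}
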