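#' GLCM / PanTex configuration
#'
#' @param levels number of gray levels n (>= 2); contrast is computed on
#'   values quantised to \code{[0, levels)}.
#' @param window_size odd moving-window size in pixels (>= 3).
#' @param displacements integer matrix with columns \code{(drow, dcol)}: the
#'   displacement vectors whose contrasts are fused by the min operator.
#'   The default is the ten distinct directions within Chebyshev distance 2,
#'   a set closed (up to sign) under 90-degree rotation.
#' @return An object of class \code{glcm_config}.
#' @export
glcm_config <- function(levels = 256L, window_size = 7L,
                        displacements = default_displacements()) {
  stopifnot(levels >= 2, window_size >= 3, window_size %% 2 == 1)
  displacements <- as.matrix(displacements)
  storage.mode(displacements) <- "integer"
  if (ncol(displacements) != 2L) stop("displacements must have two columns")
  if (any(rowSums(abs(displacements)) == 0)) stop("displacements must be non-zero")
  key <- apply(displacements, 1L, function(d) {
    if (d[1] < 0 || (d[1] == 0 && d[2] < 0)) d <- -d
    paste(d, collapse = ",")
  })
  if (anyDuplicated(key)) stop("displacements must be distinct up to sign")
  structure(list(levels = as.integer(levels),
                 window_size = as.integer(window_size),
                 displacements = displacements),
            class = "glcm_config")
}

#' @rdname glcm_config
#' @export
default_displacements <- function() {
  rbind(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L),
        c(0L, 2L), c(2L, 0L), c(2L, 1L), c(1L, 2L),
        c(2L, -1L), c(1L, -2L))
}

#' Gray-level co-occurrence matrix of a window
#'
#' Counts how often gray level i co-occurs with gray level j at the given
#' displacement; each ordered pair is counted once, then the matrix is
#' symmetrised and normalised to sum to 1.
#'
#' @param window integer matrix with values in \code{[0, levels)}.
#' @param displacement integer length-2 \code{(drow, dcol)} offset.
#' @param levels number of gray levels.
#' @return A \code{levels x levels} matrix of class \code{glcm}.
#' @export
glcm <- function(window, displacement, levels = 256L) {
  stopifnot(is.matrix(window), length(displacement) == 2L)
  if (any(window < 0 | window >= levels))
    stop("window values must be quantized to [0, levels)")
  dr <- displacement[1]; dc <- displacement[2]
  nr <- nrow(window); nc <- ncol(window)
  rows <- seq_len(nr); cols <- seq_len(nc)
  r1 <- rows[rows + dr >= 1 & rows + dr <= nr]
  c1 <- cols[cols + dc >= 1 & cols + dc <= nc]
  if (length(r1) == 0L || length(c1) == 0L)
    stop("displacement does not fit inside the window: no co-occurring pairs")
  a <- window[r1, c1, drop = FALSE]
  b <- window[r1 + dr, c1 + dc, drop = FALSE]
  counts <- matrix(0, levels, levels)
  tab <- table(factor(a, levels = 0:(levels - 1)),
               factor(b, levels = 0:(levels - 1)))
  counts <- counts + as.matrix(tab)
  sym <- counts + t(counts)
  p <- sym / sum(sym)
  dimnames(p) <- NULL
  structure(p, class = c("glcm", "matrix", "array"))
}

#' Contrast of a GLCM
#'
#' \code{sum_{i,j} (i - j)^2 P(i, j)} over the normalised co-occurrence
#' frequencies.
#'
#' @param g a \code{\link{glcm}} (or any normalised co-occurrence matrix).
#' @return non-negative scalar.
#' @export
glcm_contrast <- function(g) {
  n <- nrow(g)
  idx <- seq_len(n) - 1L
  d2 <- outer(idx, idx, function(i, j) (i - j)^2)
  sum(d2 * unclass(g))
}

#' PanTex built-up presence raster
#'
#' For every pixel, the GLCM contrast of the centred moving window is
#' computed for each displacement vector, and the minimum over displacements
#' is returned: built-up areas show high textural contrast in all
#' directions, so fusing with a min operator suppresses linear features.
#' Border pixels use the truncated window (no padding).
#'
#' @param pan panchromatic matrix (or \code{index_raster}).
#' @param cfg a \code{\link{glcm_config}}.
#' @param quantize if \code{TRUE} (default), \code{pan} is linearly rescaled
#'   to \code{[0, levels)} first; set \code{FALSE} when the input is already
#'   quantised gray levels.
#' @return An \code{index_raster} of kind \code{PANTEX}.
#' @export
pantex_raster <- function(pan, cfg = glcm_config(), quantize = TRUE) {
  v <- as_values(pan)
  if (cfg$window_size > min(dim(v)))
    stop("window larger than the image")
  q <- if (quantize) quantize_levels(v, cfg$levels) else {
    if (any(v < 0 | v >= cfg$levels))
      stop("pan values must be quantized to [0, levels) when quantize = FALSE")
    qq <- v; storage.mode(qq) <- "integer"; qq
  }
  out <- cpp_pantex(q, cfg$window_size, cfg$displacements[, 1L],
                    cfg$displacements[, 2L])
  index_raster(out, "PANTEX",
               provenance = list(levels = cfg$levels,
                                 window_size = cfg$window_size,
                                 displacements = cfg$displacements))
}
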