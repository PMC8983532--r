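#' Construct an intensity image
#'
#' Lightweight container for a single-channel microscopy image: a numeric
#' matrix of non-negative intensities with a physical pixel size attached.
#' Rows index the image y-axis, columns the x-axis. Most functions in the
#' package also accept a plain matrix; the pixel size then defaults to the
#' acquisition setting of 0.161 um/pixel.
#'
#' @param pixels numeric matrix of finite, non-negative intensities.
#' @param pixel_size_um physical edge length of one pixel in micrometres.
#' @return the matrix with class `intensity_image` and a `pixel_size_um`
#'   attribute.
#' @export
intensity_image <- function(pixels, pixel_size_um = 0.161) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!all(is.finite(pixels))) stop("intensity image must be finite")
  if (any(pixels < 0)) stop("intensity image must be non-negative")
  stopifnot(is.numeric(pixel_size_um), length(pixel_size_um) == 1L, pixel_size_um > 0)
  structure(pixels, pixel_size_um = pixel_size_um,
            class = c("intensity_image", class(pixels)))
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("intensity_image: %d x %d pixels, %.3f um/pixel, range [%g, %g]\n",
              nrow(x), ncol(x), pixel_size_um(x), min(x), max(x)))
  invisible(x)
}

#' Physical pixel size of an image
#'
#' @param img matrix or `intensity_image`.
#' @param default value used when the image carries no `pixel_size_um`
#'   attribute.
#' @return pixel edge length in micrometres.
#' @export
pixel_size_um <- function(img, default = 0.161) {
  ps <- attr(img, "pixel_size_um")
  if (is.null(ps)) default else ps
}

## strip class/attrs so arithmetic stays plain-matrix
as_matrix <- function(img) {
  m <- unclass(img)
  attr(m, "pixel_size_um") <- NULL
  m
}

## shift a matrix by (dr, dc): out[r, c] = m[r + dr, c + dc], `fill` outside
shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(rs) && length(cs)) out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

## offsets of the 8-neighbourhood; the first four are the "forward" half
.nbr8 <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L),
               c(-1L, 0L), c(0L, -1L), c(-1L, -1L), c(1L, -1L))

#' Label connected components
#'
#' Connected-component labelling of a binary mask with 8- (default) or
#' 4-connectivity. Unlike [EBImage::bwlabel()], diagonal neighbours belong
#' to the same component under the default.
#'
#' @param mask logical (or 0/1 numeric) matrix.
#' @param connectivity 8 or 4.
#' @return integer matrix of the same shape; 0 = background, k > 0 labels
#'   the k-th component.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(lab)
  vid <- integer(nr * nc)
  vid[idx] <- seq_len(n)
  pos <- arrayInd(idx, c(nr, nc))
  offs <- if (connectivity == 8) .nbr8[1:4, , drop = FALSE] else .nbr8[1:2, , drop = FALSE]
  efrom <- integer(0); eto <- integer(0)
  for (k in seq_len(nrow(offs))) {
    r2 <- pos[, 1] + offs[k, 1]; c2 <- pos[, 2] + offs[k, 2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- vid[j] > 0L
    efrom <- c(efrom, vid[idx[ok]][keep])
    eto <- c(eto, vid[j][keep])
  }
  g <- igraph::graph_from_edgelist(cbind(efrom, eto), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(n)]
  lab[idx] <- as.integer(comp)
  lab
}

## crossing number A(p): 0->1 transitions in the cyclic 8-neighbour sequence
## N, NE, E, SE, S, SW, W, NW (matrices of the whole image)
.crossing_number <- function(p) {
  n <- list(shift_mat(p, -1L, 0L), shift_mat(p, -1L, 1L), shift_mat(p, 0L, 1L),
            shift_mat(p, 1L, 1L), shift_mat(p, 1L, 0L), shift_mat(p, 1L, -1L),
            shift_mat(p, 0L, -1L), shift_mat(p, -1L, -1L))
  a <- matrix(0L, nrow(p), ncol(p))
  for (i in 1:8) {
    j <- if (i == 8L) 1L else i + 1L
    a <- a + (!n[[i]] & n[[j]])
  }
  a
}

.neighbour_count <- function(p) {
  b <- matrix(0L, nrow(p), ncol(p))
  for (k in 1:8) b <- b + shift_mat(p, .nbr8[k, 1], .nbr8[k, 2])
  b
}

#' Morphological thinning to a unit-width skeleton
#'
#' Two-subiteration thinning (Zhang-Suen scheme) of a binary mask down to
#' 8-connected, one-pixel-wide centrelines, followed by a cleanup pass that
#' removes redundant pixels left in 2x2 blocks while preserving
#' connectivity. Thinning is idempotent: applying it to its own output
#' returns the same mask.
#'
#' @param mask logical (or 0/1 numeric) matrix; foreground is thinned.
#' @return logical matrix of the same shape containing the skeleton.
#' @export
thin_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  p <- mask > 0
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      P2 <- shift_mat(p, -1L, 0L); P3 <- shift_mat(p, -1L, 1L)
      P4 <- shift_mat(p, 0L, 1L);  P5 <- shift_mat(p, 1L, 1L)
      P6 <- shift_mat(p, 1L, 0L);  P7 <- shift_mat(p, 1L, -1L)
      P8 <- shift_mat(p, 0L, -1L); P9 <- shift_mat(p, -1L, -1L)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- .crossing_number(p)
      cond <- p & B >= 2L & B <= 6L & A == 1L
      if (sub == 1L) {
        cond <- cond & !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        cond <- cond & !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(cond)) {
        p[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  .remove_2x2_blocks(p)
}

## delete one removable (simple, non-end) pixel per remaining full 2x2 block
.remove_2x2_blocks <- function(p) {
  nr <- nrow(p); nc <- ncol(p)
  repeat {
    blk <- p & shift_mat(p, 1L, 0L) & shift_mat(p, 0L, 1L) & shift_mat(p, 1L, 1L)
    tl <- which(blk)
    if (!length(tl)) break
    removed <- FALSE
    for (i in tl) {
      rc <- arrayInd(i, c(nr, nc))
      quad <- rbind(rc, rc + c(1L, 0L), rc + c(0L, 1L), rc + c(1L, 1L))
      if (!all(p[quad])) next          # block already broken by earlier removal
      for (q in 1:4) {
        r <- quad[q, 1]; c <- quad[q, 2]
        r0 <- max(1L, r - 2L); c0 <- max(1L, c - 2L)
        r1 <- min(nr, r + 2L); c1 <- min(nc, c + 2L)
        loc <- p[r0:r1, c0:c1]
        ## removal is safe if the pixel is simple (crossing number 1, so its
        ## neighbours stay connected without it) and not an endpoint
        a <- .crossing_number(loc)[r - r0 + 1L, c - c0 + 1L]
        b <- .neighbour_count(loc)[r - r0 + 1L, c - c0 + 1L]
        if (a == 1L && b >= 2L) {
          p[r, c] <- FALSE
          removed <- TRUE
          break
        }
      }
      if (removed) break
    }
    if (!removed) break
  }
  p
}

#' Threshold an intensity image
#'
#' Converts a grayscale image into a binary foreground mask either with a
#' fixed threshold or with Otsu's method. The threshold actually applied is
#' recorded on the result so that a run can document that the same
#' parameters were used for every image in a comparison.
#'
#' @param image numeric matrix or `intensity_image`.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold numeric cutoff, required for `method = "fixed"`.
#'   Foreground is strictly greater than the threshold.
#' @return logical matrix with attributes `threshold` and `method`.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  img <- as_matrix(image)
  if (method == "fixed") {
    if (is.null(threshold)) stop("method = 'fixed' requires a threshold")
    th <- threshold
  } else {
    rng <- range(img)
    if (diff(rng) == 0) {
      stop("automatic thresholding of a constant image is undefined; ",
           "use method = 'fixed' with an explicit threshold")
    }
    scaled <- (img - rng[1]) / diff(rng)
    th01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256L)
    th <- rng[1] + th01 * diff(rng)
  }
  mask <- img > th
  attr(mask, "threshold") <- th
  attr(mask, "method") <- method
  mask
}

## vectorised bilinear interpolation at (row, col) positions; positions must
## lie inside [1, nrow] x [1, ncol]
bilinear_sample <- function(img, r, c) {
  img <- as_matrix(img)
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  if (nr == 1L) r0 <- rep(1, length(r))
  if (nc == 1L) c0 <- rep(1, length(c))
  fr <- r - r0; fc <- c - c0
  r1 <- pmin(r0 + 1L, nr); c1 <- pmin(c0 + 1L, nc)
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c1)] * (1 - fr) * fc +
    img[cbind(r1, c1)] * fr * fc
}

## evaluate an expression with a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  expr
}
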