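#' Irregularity score of a membrane intensity profile
#'
#' Quantifies how dominant supra-average intensities are along a traced
#' cell membrane. With profile intensities \eqn{I_1..I_N} and mean
#' \eqn{\bar{x}}, every pixel brighter than the mean contributes its excess
#' \eqn{I_i - \bar{x}}; sub-average pixels contribute zero. The average
#' contribution over all N pixels is then divided by \eqn{\bar{x}} to
#' normalize for differently strong staining:
#' \deqn{score = \frac{1}{N \bar{x}} \sum_i \max(I_i - \bar{x}, 0).}
#' A score of 0 means all pixels have the same intensity; the score is
#' invariant to multiplying the whole profile by a positive constant, and
#' depends only on the multiset of intensities (it measures amplitude
#' dispersion, not spatial frequency — see the package vignette).
#'
#' @param profile numeric vector of ordered border intensities (N >= 2,
#'   all >= 0), or a `border_profile` from [border_profile()].
#' @param denominator `"all_pixels"` (default) averages the summed excess
#'   over all N pixels; `"bright_pixels"` averages over only the pixels
#'   brighter than the mean. The default follows the reading that the
#'   deviation is averaged over all membrane pixels.
#' @return `irregularity_score` object: list with `score`, `n_pixels`,
#'   `mean_intensity`, `denominator`.
#' @export
irregularity_score <- function(profile,
                               denominator = c("all_pixels", "bright_pixels")) {
  denominator <- match.arg(denominator)
  x <- if (inherits(profile, "border_profile")) profile$intensities else profile
  stopifnot(is.numeric(x))
  if (length(x) < 2L) stop("profile needs at least 2 pixels")
  if (any(x < 0) || any(!is.finite(x))) stop("intensities must be finite and >= 0")
  xbar <- mean(x)
  if (xbar == 0) stop("mean intensity is zero; score undefined")
  excess <- pmax(x - xbar, 0)
  n_den <- if (denominator == "all_pixels") length(x) else max(1L, sum(excess > 0))
  out <- list(score = sum(excess) / n_den / xbar,
              n_pixels = length(x), mean_intensity = xbar,
              denominator = denominator)
  class(out) <- "irregularity_score"
  out
}

#' @export
print.irregularity_score <- function(x, ...) {
  cat(sprintf("irregularity_score: %.4f (N = %d, mean intensity = %.3f, denominator = %s)\n",
              x$score, x$n_pixels, x$mean_intensity, x$denominator))
  invisible(x)
}

#' Border intensity profile
#'
#' Ordered intensity samples along one traced bicellular border, the input
#' to [irregularity_score()].
#'
#' @param intensities numeric vector of samples along the membrane.
#' @return `border_profile` object with `intensities`, `n_pixels` and
#'   `mean_intensity`.
#' @export
border_profile <- function(intensities) {
  stopifnot(is.numeric(intensities), length(intensities) >= 2L)
  out <- list(intensities = as.numeric(intensities),
              n_pixels = length(intensities),
              mean_intensity = mean(intensities))
  class(out) <- "border_profile"
  out
}

#' Irregularity score of a traced border in an image
#'
#' Builds the border intensity profile by averaging `width_px` samples
#' perpendicular to the trace at every trace pixel (bilinear
#' interpolation), then applies [irregularity_score()].
#'
#' @param image numeric matrix or `intensity_image`.
#' @param trace a `border_trace` from [trace_borders()].
#' @param width_px averaging width across the border.
#' @param denominator passed to [irregularity_score()].
#' @return an `irregularity_score` object.
#' @export
border_irregularity <- function(image, trace, width_px = 3L,
                                denominator = c("all_pixels", "bright_pixels")) {
  stopifnot(inherits(trace, "border_trace"))
  img <- as_matrix(image)
  prof <- .trace_profile(img, trace, width_px)
  irregularity_score(prof, denominator = match.arg(denominator))
}

## intensity profile along a trace, averaged across the local normal
.trace_profile <- function(img, trace, width_px) {
  path <- trace$path
  npx <- nrow(path)
  nr <- nrow(img); nc <- ncol(img)
  offs <- seq_len(width_px) - (width_px + 1) / 2
  win <- 5L
  vapply(seq_len(npx), function(i) {
    lo <- max(1L, i - win); hi <- min(npx, i + win)
    w <- path[lo:hi, , drop = FALSE]
    ev <- eigen(stats::cov(w), symmetric = TRUE)
    tangent <- ev$vectors[, 1L]
    normal <- c(-tangent[2L], tangent[1L])
    rr <- path[i, 1L] + offs * normal[1L]
    cc <- path[i, 2L] + offs * normal[2L]
    keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    if (!any(keep)) return(img[path[i, 1L], path[i, 2L]])
    mean(bilinear_sample(img, rr[keep], cc[keep]))
  }, 0)
}
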