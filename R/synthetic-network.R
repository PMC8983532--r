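#' Parameters for synthetic keratin filament networks
#'
#' Filaments grow from random anchor points as random walks with small
#' angular jitter; at each growth step a new branch can split off. The
#' resulting centrelines are rasterized, and the image renders them as
#' Gaussian-profile ridges. The ground-truth network graph (branches,
#' junctions, end points) is extracted from the exact rasterized
#' centreline, so filament crossings created during growth count as
#' junctions exactly as they will appear to any image-based analysis.
#'
#' @param image_shape integer (rows, cols).
#' @param n_seeds number of filament anchor points (>= 1).
#' @param branch_prob probability of spawning a branch per growth step.
#' @param step_len_px growth step length in pixels.
#' @param filament_sigma_px Gaussian rendering width (ridge sigma).
#' @param noise_sd additive Gaussian intensity noise SD.
#' @param max_steps growth steps per filament tip.
#' @param max_filaments hard cap on the total number of filaments grown;
#'   branching stops spawning once reached (keeps the branching process
#'   from running away on dense settings).
#' @param turn_sd angular jitter SD per step (radians); 0 grows straight
#'   filaments.
#' @param amplitude peak ridge intensity of a single straight filament.
#' @param rng_seed integer seed (required).
#' @return a `filament_params` list.
#' @export
filament_params <- function(image_shape = c(256L, 256L),
                            n_seeds = 8L,
                            branch_prob = 0.08,
                            step_len_px = 6,
                            filament_sigma_px = 1.2,
                            noise_sd = 2,
                            max_steps = 25L,
                            turn_sd = 0.15,
                            amplitude = 100,
                            max_filaments = 64L,
                            rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is required")
  stopifnot(length(image_shape) == 2L, all(image_shape >= 1L), n_seeds >= 1L,
            branch_prob >= 0, branch_prob <= 1, step_len_px > 0,
            filament_sigma_px > 0, noise_sd >= 0, max_steps >= 1L,
            turn_sd >= 0, amplitude > 0, max_filaments >= n_seeds)
  if (prod(image_shape) == 0L) stop("zero-area image")
  structure(list(image_shape = as.integer(image_shape),
                 n_seeds = as.integer(n_seeds), branch_prob = branch_prob,
                 step_len_px = step_len_px,
                 filament_sigma_px = filament_sigma_px, noise_sd = noise_sd,
                 max_steps = as.integer(max_steps), turn_sd = turn_sd,
                 amplitude = amplitude,
                 max_filaments = as.integer(max_filaments),
                 rng_seed = as.integer(rng_seed)),
            class = "filament_params")
}

#' Generate a synthetic filament network image with ground-truth graph
#'
#' @param params a [filament_params()] object.
#' @param polylines optional list of n x 2 (row, col) coordinate matrices
#'   overriding random growth — used to build constructed fixtures such as
#'   two crossing straight filaments.
#' @return list with `image` ([intensity_image()]), `centerline` (logical
#'   matrix of true filament centrelines), `graph` (the ground-truth
#'   `skeleton_graph` of the centreline) and `polylines`.
#' @export
generate_filament_network <- function(params, polylines = NULL) {
  stopifnot(inherits(params, "filament_params"))
  p <- params
  with_seed(p$rng_seed, {
    if (is.null(polylines)) polylines <- .grow_filaments(p)
    centre <- rasterize_polylines(polylines, p$image_shape)
    graph <- skeletonize(centre, thin = TRUE)
    img <- render_filament_image(graph$skeleton, p$filament_sigma_px,
                                 p$amplitude, p$noise_sd)
    list(image = intensity_image(img),
         centerline = graph$skeleton,
         graph = graph,
         polylines = polylines)
  })
}

## random-walk growth with branching; returns a list of polylines
.grow_filaments <- function(p) {
  nr <- p$image_shape[1]; nc <- p$image_shape[2]
  tips <- lapply(seq_len(p$n_seeds), function(i) {
    list(pos = c(stats::runif(1, 1, nr), stats::runif(1, 1, nc)),
         dir = stats::runif(1, 0, 2 * pi))
  })
  polylines <- list()
  total <- length(tips)
  while (length(tips)) {
    tip <- tips[[1L]]; tips <- tips[-1L]
    pts <- matrix(tip$pos, 1L)
    dir <- tip$dir
    for (s in seq_len(p$max_steps)) {
      dir <- dir + stats::rnorm(1, sd = p$turn_sd)
      nxt <- pts[nrow(pts), ] + p$step_len_px * c(sin(dir), cos(dir))
      if (nxt[1] < 1 || nxt[1] > nr || nxt[2] < 1 || nxt[2] > nc) break
      pts <- rbind(pts, nxt)
      if (stats::runif(1) < p$branch_prob && total < p$max_filaments) {
        side <- sample(c(-1, 1), 1L)
        tips[[length(tips) + 1L]] <-
          list(pos = nxt, dir = dir + side * stats::runif(1, 0.6, 1.2))
        total <- total + 1L
      }
    }
    if (nrow(pts) >= 2L) polylines[[length(polylines) + 1L]] <- pts
  }
  polylines
}

#' Rasterize polylines into a centreline mask
#'
#' @param polylines list of n x 2 (row, col) coordinate matrices.
#' @param image_shape integer (rows, cols).
#' @return logical matrix marking every pixel touched by a polyline.
#' @export
rasterize_polylines <- function(polylines, image_shape) {
  nr <- image_shape[1]; nc <- image_shape[2]
  if (nr * nc == 0L) stop("zero-area image")
  mask <- matrix(FALSE, nr, nc)
  for (pl in polylines) {
    pl <- as.matrix(pl)
    for (i in seq_len(nrow(pl) - 1L)) {
      a <- pl[i, ]; b <- pl[i + 1L, ]
      n <- max(2L, ceiling(2 * sqrt(sum((b - a)^2))))
      t <- seq(0, 1, length.out = n)
      rr <- round(a[1] + t * (b[1] - a[1]))
      cc <- round(a[2] + t * (b[2] - a[2]))
      keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      mask[cbind(rr[keep], cc[keep])] <- TRUE
    }
  }
  mask
}

#' Render a centreline mask as Gaussian-profile ridges
#'
#' Blurs the unit-width centreline with an isotropic Gaussian and scales
#' so a long straight filament has peak intensity `amplitude` (crossings
#' add up), then adds Gaussian noise and clips at zero.
#'
#' @param centerline logical matrix.
#' @param sigma_px Gaussian sigma in pixels.
#' @param amplitude peak ridge intensity.
#' @param noise_sd additive noise SD.
#' @return numeric intensity matrix.
#' @export
render_filament_image <- function(centerline, sigma_px, amplitude, noise_sd) {
  nr <- nrow(centerline); nc <- ncol(centerline)
  blurred <- EBImage::gblur(EBImage::Image(centerline * 1), sigma = sigma_px)
  img <- matrix(as.numeric(blurred), nr, nc)
  ## a unit line blurred with a 2D gaussian peaks at 1/(sigma*sqrt(2*pi))
  img <- img * amplitude * sigma_px * sqrt(2 * pi)
  if (noise_sd > 0)
    img <- img + matrix(stats::rnorm(nr * nc, sd = noise_sd), nr, nc)
  img[img < 0] <- 0
  img
}
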