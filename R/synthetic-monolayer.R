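#' Parameters for synthetic epithelial monolayer images
#'
#' Describes an immunofluorescence-like image of a cell monolayer with
#' border-enriched signal: cells are a seeded nearest-seed tessellation,
#' the junctional signal is a stripe of width `border_width_px` centred on
#' every bicellular interface at `enrichment_ratio` times the cytoplasmic
#' intensity, optionally modulated on a fraction of each border
#' (patchiness), plus i.i.d. Gaussian noise.
#'
#' @param image_shape integer (rows, cols).
#' @param pixel_size_um physical pixel size (default 0.161 um/pixel, the
#'   acquisition setting the pipeline mirrors).
#' @param n_cells number of cells (>= 2).
#' @param enrichment_ratio target junction/cytoplasm intensity ratio
#'   (>= 0; 1 means no enrichment).
#' @param patchiness fraction of each border's length whose intensity is
#'   modulated, in \[0, 1\].
#' @param patch_amplitude multiplicative modulation depth (>= 0); patched
#'   stretches are scaled by `1 + patch_amplitude`.
#' @param cytoplasm_mean cytoplasmic intensity (> 0).
#' @param noise_sd additive Gaussian noise SD (>= 0); intensities are
#'   clipped at 0.
#' @param border_width_px width of the junctional stripe in pixels (>= 1).
#' @param rng_seed integer seed; required, every generated dataset is
#'   reproducible from its parameters.
#' @return a `monolayer_params` list.
#' @export
monolayer_params <- function(image_shape = c(256L, 256L),
                             pixel_size_um = 0.161,
                             n_cells = 6L,
                             enrichment_ratio = 3,
                             patchiness = 0,
                             patch_amplitude = 0,
                             cytoplasm_mean = 100,
                             noise_sd = 5,
                             border_width_px = 5L,
                             rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is required")
  stopifnot(length(image_shape) == 2L, all(image_shape >= 32L),
            n_cells >= 2L, enrichment_ratio >= 0,
            patchiness >= 0, patchiness <= 1, patch_amplitude >= 0,
            cytoplasm_mean > 0, noise_sd >= 0, border_width_px >= 1L)
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size_um = pixel_size_um, n_cells = as.integer(n_cells),
                 enrichment_ratio = enrichment_ratio, patchiness = patchiness,
                 patch_amplitude = patch_amplitude,
                 cytoplasm_mean = cytoplasm_mean, noise_sd = noise_sd,
                 border_width_px = as.integer(border_width_px),
                 rng_seed = as.integer(rng_seed)),
            class = "monolayer_params")
}

#' Generate a synthetic monolayer image with ground truth
#'
#' Produces an intensity image, the cell label mask partitioning it, and a
#' machine-readable ground-truth record sufficient to score the line-scan
#' and irregularity estimators: the true enrichment ratio, the border
#' pixel set, the rendered junctional stripe, and the patched pixels per
#' border. Identical parameters (same seed) give bit-identical output.
#'
#' @param params a [monolayer_params()] object.
#' @param seed_points optional n x 2 matrix of (row, col) cell seed
#'   positions overriding random placement (used for constructed
#'   fixtures). Coincident seeds (< 1 px apart) are a degenerate geometry
#'   and raise an error.
#' @return list with `image` ([intensity_image()]), `mask` (integer label
#'   matrix) and `truth` (list: `enrichment_ratio`, `border_pixels`,
#'   `stripe` (logical matrix), `stripe_width_px`, `patches` (list per
#'   border: labels + patched pixel indices), `seed_points`, `params`).
#' @export
generate_monolayer <- function(params, seed_points = NULL) {
  stopifnot(inherits(params, "monolayer_params"))
  p <- params
  nr <- p$image_shape[1]; nc <- p$image_shape[2]
  with_seed(p$rng_seed, {
    if (is.null(seed_points)) {
      seed_points <- .place_seeds(nr, nc, p$n_cells)
    } else {
      seed_points <- as.matrix(seed_points)
      stopifnot(ncol(seed_points) == 2L)
    }
    d <- as.matrix(stats::dist(seed_points))
    diag(d) <- Inf
    if (min(d) < 1) stop("degenerate cell geometry: coincident seed points")
    if (nrow(seed_points) < 2L) stop("need at least 2 cells")

    ## nearest-seed tessellation
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    best <- matrix(Inf, nr, nc)
    labels <- matrix(0L, nr, nc)
    for (k in seq_len(nrow(seed_points))) {
      dk <- (rows - seed_points[k, 1])^2 + (cols - seed_points[k, 2])^2
      upd <- dk < best
      best[upd] <- dk[upd]
      labels[upd] <- k
    }

    ## border centreline: pixels whose right or bottom neighbour belongs to
    ## a different cell
    diff_r <- labels != shift_mat(labels, 1L, 0L, fill = NA)
    diff_c <- labels != shift_mat(labels, 0L, 1L, fill = NA)
    border <- (diff_r & !is.na(diff_r)) | (diff_c & !is.na(diff_c))
    border[is.na(border)] <- FALSE

    ## junctional stripe: pixels within (w - 1)/2 of the border centreline
    halfw <- (p$border_width_px - 1) / 2
    stripe <- .within_distance(border, halfw)

    img <- matrix(p$cytoplasm_mean, nr, nc)
    img[stripe] <- p$enrichment_ratio * p$cytoplasm_mean

    ## patchy modulation along randomly chosen border arcs
    patches <- list()
    if (p$patchiness > 0 && p$patch_amplitude > 0) {
      traces <- trace_borders(labels)
      for (tr in traces) {
        npx <- nrow(tr$path)
        n_patch <- round(p$patchiness * npx)
        if (n_patch < 1L) next
        start <- sample.int(max(1L, npx - n_patch + 1L), 1L)
        arc <- tr$pixel_idx[start:(start + n_patch - 1L)]
        pm <- matrix(FALSE, nr, nc)
        pm[arc] <- TRUE
        region <- .within_distance(pm, halfw) & stripe
        img[region] <- img[region] * (1 + p$patch_amplitude)
        patches[[length(patches) + 1L]] <-
          list(labels = tr$labels, arc_pixels = arc,
               region_pixels = which(region))
      }
    }

    if (p$noise_sd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, sd = p$noise_sd), nr, nc)
    img[img < 0] <- 0

    list(image = intensity_image(img, p$pixel_size_um),
         mask = labels,
         truth = list(enrichment_ratio = p$enrichment_ratio,
                      border_pixels = which(border),
                      stripe = stripe,
                      stripe_width_px = p$border_width_px,
                      patches = patches,
                      seed_points = seed_points,
                      params = unclass(p)))
  })
}

## pixels within `dist` of the TRUE set (Euclidean, via EBImage distance map)
.within_distance <- function(mask, dist) {
  if (dist <= 0) return(mask)
  d <- EBImage::distmap(EBImage::Image(1 - mask))
  matrix(as.numeric(d) <= dist, nrow(mask), ncol(mask))
}

## random seed placement with a minimum separation, deterministic under the
## caller's RNG state
.place_seeds <- function(nr, nc, n) {
  minsep <- 0.45 * sqrt(nr * nc / n)
  pts <- matrix(NA_real_, n, 2)
  for (k in seq_len(n)) {
    best <- NULL; best_d <- -Inf
    for (try in 1:200) {
      cand <- c(stats::runif(1, 0.06 * nr, 0.94 * nr),
                stats::runif(1, 0.06 * nc, 0.94 * nc))
      d <- if (k == 1L) Inf
      else min(sqrt((pts[1:(k - 1), 1] - cand[1])^2 +
                      (pts[1:(k - 1), 2] - cand[2])^2))
      if (d >= minsep) { best <- cand; break }
      if (d > best_d) { best <- cand; best_d <- d }
    }
    pts[k, ] <- best
  }
  pts
}
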