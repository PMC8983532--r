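#' Parameters for simulated force-distance curves
#'
#' Piecewise model of a single-molecule AFM force-distance cycle on a soft
#' sample. The z axis is tip-sample displacement in nm, from 0 (deepest
#' indentation) to `1000 * z_length_um` (full extension). On approach the
#' force rises linearly with slope `contact_stiffness_pN_per_nm` below the
#' contact point; the contact point sits where the contact ramp reaches the
#' setpoint at z = 0, i.e. at `setpoint / stiffness` nm. On retract, a
#' binding curve carries exactly one unbinding event at
#' `step_position_nm` beyond the contact point: either a linear
#' ramp-to-rupture (force builds linearly to the unbinding force, then
#' snaps back to baseline) or, with `tether_plateau = TRUE`, a
#' near-constant-force membrane tether ending in the same instantaneous
#' step. The rupture is snapped to the nearest z sample and the realized
#' values recorded in the ground truth. Noise is additive i.i.d. Gaussian.
#'
#' @param z_length_um ramp length in um (default 1.5).
#' @param setpoint_nN contact-force setpoint in nN (default 0.5).
#' @param pulling_speed_um_s retraction speed, metadata only (default 10).
#' @param n_points samples per sweep (>= 50).
#' @param baseline_noise_sd_pN force noise SD in pN.
#' @param contact_stiffness_pN_per_nm slope of the contact ramp in pN/nm.
#' @param binding whether the retract curve contains an unbinding event.
#' @param unbinding_force_pN rupture force in pN (> 0, required if
#'   binding).
#' @param step_position_nm distance from the contact point to the rupture
#'   in nm, in (0, 1000 * z_length_um) (required if binding).
#' @param tether_plateau pre-rupture segment shape: constant-force tether
#'   (`TRUE`) or linear ramp (`FALSE`, default).
#' @param contact_time_s,spring_constant_N_m,tip_radius_nm acquisition
#'   metadata (defaults 0.1 s, 0.03 N/m, 20 nm).
#' @param rng_seed integer seed (required).
#' @return a `curve_params` list.
#' @export
curve_params <- function(z_length_um = 1.5,
                         setpoint_nN = 0.5,
                         pulling_speed_um_s = 10,
                         n_points = 1024L,
                         baseline_noise_sd_pN = 5,
                         contact_stiffness_pN_per_nm = 5,
                         binding = FALSE,
                         unbinding_force_pN = NULL,
                         step_position_nm = NULL,
                         tether_plateau = FALSE,
                         contact_time_s = 0.1,
                         spring_constant_N_m = 0.03,
                         tip_radius_nm = 20,
                         rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is required")
  stopifnot(z_length_um > 0, setpoint_nN > 0, n_points >= 50L,
            baseline_noise_sd_pN >= 0, contact_stiffness_pN_per_nm > 0,
            contact_time_s > 0, spring_constant_N_m > 0, tip_radius_nm > 0)
  if (binding) {
    if (is.null(unbinding_force_pN) || unbinding_force_pN <= 0)
      stop("binding = TRUE requires unbinding_force_pN > 0")
    if (is.null(step_position_nm) || step_position_nm <= 0 ||
        step_position_nm >= 1000 * z_length_um)
      stop("step_position_nm must lie in (0, 1000 * z_length_um)")
  }
  structure(list(z_length_um = z_length_um, setpoint_nN = setpoint_nN,
                 pulling_speed_um_s = pulling_speed_um_s,
                 n_points = as.integer(n_points),
                 baseline_noise_sd_pN = baseline_noise_sd_pN,
                 contact_stiffness_pN_per_nm = contact_stiffness_pN_per_nm,
                 binding = isTRUE(binding),
                 unbinding_force_pN = unbinding_force_pN,
                 step_position_nm = step_position_nm,
                 tether_plateau = isTRUE(tether_plateau),
                 contact_time_s = contact_time_s,
                 spring_constant_N_m = spring_constant_N_m,
                 tip_radius_nm = tip_radius_nm,
                 rng_seed = as.integer(rng_seed)),
            class = "curve_params")
}

#' Simulate one force-distance curve
#'
#' @param params a [curve_params()] object.
#' @return a `force_curve`: data frame with columns `z_nm`, `force_pN`,
#'   `sweep` (`"approach"`/`"retract"`), with attributes `meta`
#'   (acquisition parameters) and `truth` (`contact_point_nm`, `binding`,
#'   and for binding curves the realized `unbinding_force_pN`,
#'   `step_position_nm` and `rupture_z_nm`).
#' @export
generate_force_curve <- function(params) {
  stopifnot(inherits(params, "curve_params"))
  p <- params
  z_len <- 1000 * p$z_length_um
  k <- p$contact_stiffness_pN_per_nm
  cp <- (p$setpoint_nN * 1000) / k
  if (cp >= 0.5 * z_len)
    stop("contact region covers most of the ramp; increase stiffness or z length")
  z <- seq(0, z_len, length.out = p$n_points)

  contact <- pmax(0, k * (cp - z))
  approach <- contact
  retract <- contact
  truth <- list(contact_point_nm = cp, binding = p$binding)

  if (p$binding) {
    target <- cp + p$step_position_nm
    if (target >= z_len) stop("step position beyond ramp end")
    ir <- which.min(abs(z - target))
    if (z[ir] <= cp) ir <- min(which(z > cp)) + 1L
    pre <- z > cp & seq_along(z) <= ir
    f_rupture <- -p$unbinding_force_pN
    retract[pre] <- if (p$tether_plateau) f_rupture
    else f_rupture * (z[pre] - cp) / (z[ir] - cp)
    truth$unbinding_force_pN <- p$unbinding_force_pN
    truth$step_position_nm <- z[ir] - cp
    truth$requested_step_position_nm <- p$step_position_nm
    truth$rupture_z_nm <- z[ir]
    truth$rupture_index <- ir
  }

  with_seed(p$rng_seed, {
    if (p$baseline_noise_sd_pN > 0) {
      approach <- approach + stats::rnorm(length(z), sd = p$baseline_noise_sd_pN)
      retract <- retract + stats::rnorm(length(z), sd = p$baseline_noise_sd_pN)
    }
    curve <- data.frame(
      z_nm = c(z, z),
      force_pN = c(approach, retract),
      sweep = rep(c("approach", "retract"), each = length(z)),
      stringsAsFactors = FALSE
    )
    attr(curve, "meta") <- p
    attr(curve, "truth") <- truth
    class(curve) <- c("force_curve", class(curve))
    curve
  })
}

## extract one sweep as list(z, f), ordered by increasing z
sweep_of <- function(curve, sweep = c("retract", "approach")) {
  sweep <- match.arg(sweep)
  sel <- curve$sweep == sweep
  if (!any(sel)) stop("curve has no ", sweep, " sweep")
  z <- curve$z_nm[sel]; f <- curve$force_pN[sel]
  o <- order(z)
  list(z = z[o], f = f[o])
}

#' Parameters for simulated AFM force maps
#'
#' A rectangular scan region along an intercellular border, sampled on a
#' regular grid with one force-distance curve per pixel. A horizontal
#' junctional stripe crosses the region; pixels inside it bind with
#' probability `p_bind_border`, the remaining surface pixels with
#' `p_bind_surface`. Defaults mirror the acquisition geometry the pipeline
#' targets: a 6 x 2 um region at 0.1 um spacing, i.e. 1200 curves per map.
#'
#' @param region_um numeric (width, height) in um.
#' @param grid_spacing_um grid pitch in um; must divide the region
#'   dimensions to within one grid cell.
#' @param border_stripe list with `center_frac` (stripe centre as a
#'   fraction of the region height) and `width_um` (stripe width).
#' @param p_bind_border,p_bind_surface per-pixel binding probabilities.
#' @param curve_params a [curve_params()] template for the per-pixel
#'   curves; its `binding` flag and seed are overridden per pixel.
#' @param rng_seed integer seed (required).
#' @return a `map_params` list.
#' @export
map_params <- function(region_um = c(6, 2),
                       grid_spacing_um = 0.1,
                       border_stripe = list(center_frac = 0.5, width_um = 0.6),
                       p_bind_border = 0.6,
                       p_bind_surface = 0.3,
                       curve_params = NULL,
                       rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is required")
  stopifnot(length(region_um) == 2L, all(region_um > 0), grid_spacing_um > 0,
            p_bind_border >= 0, p_bind_border <= 1,
            p_bind_surface >= 0, p_bind_surface <= 1)
  nx <- round(region_um[1] / grid_spacing_um)
  ny <- round(region_um[2] / grid_spacing_um)
  if (abs(nx * grid_spacing_um - region_um[1]) > grid_spacing_um ||
      abs(ny * grid_spacing_um - region_um[2]) > grid_spacing_um)
    stop("grid spacing must divide the region dimensions to within one cell")
  structure(list(region_um = region_um, grid_spacing_um = grid_spacing_um,
                 border_stripe = border_stripe,
                 p_bind_border = p_bind_border,
                 p_bind_surface = p_bind_surface,
                 curve_params = curve_params,
                 rng_seed = as.integer(rng_seed)),
            class = "map_params")
}

#' Simulate a force map over a border region
#'
#' @param params a [map_params()] object.
#' @return a `force_map`: list with `curves` (list of `force_curve`, in
#'   column-major grid order), `grid_dim` (rows, cols), `spacing_um`,
#'   `junction_mask` (logical matrix, TRUE inside the border stripe) and
#'   `truth` (per-pixel binding matrix and the binding probabilities).
#' @export
generate_force_map <- function(params) {
  stopifnot(inherits(params, "map_params"))
  p <- params
  nx <- round(p$region_um[1] / p$grid_spacing_um)
  ny <- round(p$region_um[2] / p$grid_spacing_um)
  tmpl <- p$curve_params
  if (is.null(tmpl))
    tmpl <- curve_params(binding = TRUE, unbinding_force_pN = 50,
                         step_position_nm = 80, rng_seed = 0L)

  ## stripe geometry on pixel-centre y coordinates
  y <- (seq_len(ny) - 0.5) * p$grid_spacing_um
  center <- p$border_stripe$center_frac * p$region_um[2]
  in_stripe_row <- abs(y - center) <= p$border_stripe$width_um / 2
  if (!any(in_stripe_row)) stop("border stripe is empty")
  junction_mask <- matrix(in_stripe_row, ny, nx)

  with_seed(p$rng_seed, {
    pb <- ifelse(junction_mask, p$p_bind_border, p$p_bind_surface)
    bind <- matrix(stats::runif(ny * nx) < pb, ny, nx)
    seeds <- sample.int(.Machine$integer.max - 1L, ny * nx)
    curves <- vector("list", ny * nx)
    for (i in seq_len(ny * nx)) {
      cp_i <- tmpl
      cp_i$binding <- bind[i]
      cp_i$rng_seed <- seeds[i]
      if (!bind[i]) {
        cp_i$unbinding_force_pN <- NULL
        cp_i$step_position_nm <- NULL
      }
      curves[[i]] <- generate_force_curve(cp_i)
    }
    out <- list(curves = curves, grid_dim = c(ny, nx),
                spacing_um = p$grid_spacing_um,
                junction_mask = junction_mask,
                truth = list(bind = bind,
                             p_bind_border = p$p_bind_border,
                             p_bind_surface = p$p_bind_surface,
                             params = unclass(p)))
    class(out) <- "force_map"
    out
  })
}

#' @export
print.force_map <- function(x, ...) {
  cat(sprintf("force_map: %d x %d grid (%d curves) at %.3g um spacing, %d border px\n",
              x$grid_dim[1], x$grid_dim[2], length(x$curves), x$spacing_um,
              sum(x$junction_mask)))
  invisible(x)
}

#' Parameters for synthetic dispase-fragment well images
#'
#' A binary well image containing a known number of pairwise non-touching
#' monolayer fragments (elliptical blobs with areas between `min_frag_px`
#' and `max_frag_px`) plus sub-threshold debris specks strictly smaller
#' than `min_frag_px`.
#'
#' @param image_shape integer (rows, cols).
#' @param n_fragments number of fragments (>= 0).
#' @param min_frag_px,max_frag_px fragment pixel-area range.
#' @param debris_count number of debris specks.
#' @param rng_seed integer seed (required).
#' @return a `fragment_params` list.
#' @export
fragment_params <- function(image_shape = c(512L, 512L),
                            n_fragments = 37L,
                            min_frag_px = 50L,
                            max_frag_px = 400L,
                            debris_count = 10L,
                            rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is required")
  stopifnot(length(image_shape) == 2L, all(image_shape >= 8L),
            n_fragments >= 0L, min_frag_px >= 2L, max_frag_px >= min_frag_px,
            debris_count >= 0L)
  structure(list(image_shape = as.integer(image_shape),
                 n_fragments = as.integer(n_fragments),
                 min_frag_px = as.integer(min_frag_px),
                 max_frag_px = as.integer(max_frag_px),
                 debris_count = as.integer(debris_count),
                 rng_seed = as.integer(rng_seed)),
            class = "fragment_params")
}

#' Generate a synthetic fragment image with known count
#'
#' Places `n_fragments` non-touching elliptical fragments (separated by at
#' least 2 px so they stay distinct under 8-connectivity) and
#' `debris_count` specks smaller than `min_frag_px`. Placement retries a
#' bounded number of times and errors if the requested fragments cannot be
#' packed.
#'
#' @param params a [fragment_params()] object.
#' @return list with `image` (logical matrix), `n_fragments` (true count)
#'   and `truth` (list: `labels` matrix with fragments 1..n and debris
#'   coded as negative labels, `fragment_sizes`, `debris_sizes`, `params`).
#' @export
generate_fragment_image <- function(params) {
  stopifnot(inherits(params, "fragment_params"))
  p <- params
  nr <- p$image_shape[1]; nc <- p$image_shape[2]
  with_seed(p$rng_seed, {
    img <- matrix(FALSE, nr, nc)
    labels <- matrix(0L, nr, nc)
    blocked <- matrix(FALSE, nr, nc)   # occupied + 2 px separation halo

    place_blob <- function(area_px, label) {
      for (try in 1:400) {
        aspect <- stats::runif(1, 0.5, 1)
        b <- sqrt(area_px / (pi * aspect))
        a <- aspect * b
        r0 <- stats::runif(1, a + 2, nr - a - 1)
        c0 <- stats::runif(1, b + 2, nc - b - 1)
        rs <- floor(r0 - a):ceiling(r0 + a)
        cs <- floor(c0 - b):ceiling(c0 + b)
        rs <- rs[rs >= 1 & rs <= nr]; cs <- cs[cs >= 1 & cs <= nc]
        sub <- outer((rs - r0)^2 / a^2, (cs - c0)^2 / b^2, `+`) <= 1
        if (!any(sub)) next
        cells <- cbind(rep(rs, times = length(cs))[as.vector(sub)],
                       rep(cs, each = length(rs))[as.vector(sub)])
        if (any(blocked[cells])) next
        img[cells] <<- TRUE
        labels[cells] <<- label
        halo <- matrix(FALSE, nr, nc)
        halo[cells] <- TRUE
        for (k in 1:8) halo <- halo | shift_mat(halo, .nbr8[k, 1], .nbr8[k, 2])
        for (k in 1:8) halo <- halo | shift_mat(halo, .nbr8[k, 1], .nbr8[k, 2])
        blocked <<- blocked | halo
        return(TRUE)
      }
      FALSE
    }

    frag_sizes <- integer(0)
    for (i in seq_len(p$n_fragments)) {
      area <- stats::runif(1, p$min_frag_px, p$max_frag_px)
      if (!place_blob(area, i))
        stop("could not place ", p$n_fragments,
             " non-touching fragments; reduce count or sizes")
      frag_sizes <- c(frag_sizes, sum(labels == i))
    }
    debris_sizes <- integer(0)
    for (j in seq_len(p$debris_count)) {
      area <- stats::runif(1, 1, max(1, p$min_frag_px - 2))
      area <- min(area, p$min_frag_px - 2)
      if (!place_blob(max(2, area), -j))
        stop("could not place debris speck ", j)
      sz <- sum(labels == -j)
      if (sz >= p$min_frag_px) stop("debris speck grew above min_frag_px")
      debris_sizes <- c(debris_sizes, sz)
    }

    list(image = img, n_fragments = p$n_fragments,
         truth = list(labels = labels, fragment_sizes = frag_sizes,
                      debris_sizes = debris_sizes, params = unclass(p)))
  })
}
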