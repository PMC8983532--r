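## closed-form simple linear regression: returns c(intercept, slope)
.linfit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2)
  if (vx == 0) return(c(my, 0))
  b <- sum((x - mx) * (y - my)) / vx
  c(my - b * mx, b)
}

#' Locate the tip-sample contact point of a force-distance curve
#'
#' Fits a robust baseline to the outer 30% of the extension (largest z),
#' estimates the baseline noise by median absolute deviation, flags the
#' contact regime as samples exceeding the baseline by more than
#' `sigma_mult` times that noise, fits a line to the contact regime, and
#' returns the z position where the two lines intersect.
#'
#' @param curve a `force_curve` (or data frame with `z_nm`, `force_pN`,
#'   `sweep`).
#' @param sweep which sweep to use (default `"retract"`).
#' @param baseline_frac fraction of the extension used for the baseline
#'   fit (outermost samples; default 0.3).
#' @param sigma_mult detection multiple for the contact regime (default 5).
#' @return contact point position in nm along z.
#' @export
find_contact_point <- function(curve, sweep = "retract", baseline_frac = 0.3,
                               sigma_mult = 5) {
  s <- sweep_of(curve, sweep)
  n <- length(s$z)
  nb <- max(5L, floor(baseline_frac * n))
  bi <- (n - nb + 1L):n
  base <- .linfit(s$z[bi], s$f[bi])
  resid <- s$f[bi] - (base[1] + base[2] * s$z[bi])
  sigma <- max(stats::mad(resid), 1e-12)
  above <- s$f > base[1] + base[2] * s$z + sigma_mult * sigma
  ## contact regime: the repulsive ramp at small z
  ci <- which(above)
  ci <- ci[ci < n / 2]
  if (length(ci) < 2L) stop("no contact region found in curve")
  contact <- .linfit(s$z[ci], s$f[ci])
  if (contact[2] == base[2]) stop("contact and baseline slopes coincide")
  (base[1] - contact[1]) / (contact[2] - base[2])
}

#' Detect unbinding events on a retract curve
#'
#' Scans the retract sweep for force steps in which the force returns
#' toward the baseline after a sustained adhesive (negative) excursion.
#' The baseline level and noise sigma are estimated from the final 20% of
#' the extension (median and median absolute deviation). A step statistic
#' compares running medians just after and just before each sample; samples
#' where the statistic exceeds `threshold_sigma * sigma` while the
#' pre-step median sits below the adhesive gate are event candidates, and
#' each contiguous candidate run yields one event localized at its largest
#' single-sample force jump. The event force (reported positive for
#' adhesive rupture) is the post-step median minus a linear pre-step fit
#' evaluated at the rupture sample, and the step position is the rupture z
#' minus the contact point from [find_contact_point()].
#'
#' @param curve a `force_curve`.
#' @param threshold_sigma detection threshold in baseline sigmas (default
#'   6).
#' @param window_px running-median window (odd; default 9).
#' @param pre_fit_px samples in the pre-step linear fit (default 15).
#' @param post_px samples in the post-step median (default 15).
#' @param contact_point optional precomputed contact point (nm); computed
#'   on demand otherwise.
#' @return data frame with one row per event: `force_pN`,
#'   `step_position_nm`, `rupture_index`. Zero rows when no binding is
#'   detected.
#' @export
detect_unbinding_events <- function(curve, threshold_sigma = 6,
                                    window_px = 9L, pre_fit_px = 15L,
                                    post_px = 15L, contact_point = NULL) {
  stopifnot(threshold_sigma > 0, window_px >= 3L, window_px %% 2L == 1L)
  s <- sweep_of(curve, "retract")
  z <- s$z; f <- s$f
  n <- length(z)
  empty <- data.frame(force_pN = numeric(0), step_position_nm = numeric(0),
                      rupture_index = integer(0))
  if (!is.finite(threshold_sigma)) return(empty)

  ti <- (n - max(5L, floor(0.2 * n)) + 1L):n
  b <- stats::median(f[ti])
  sigma <- stats::mad(f[ti])
  sigma_eff <- max(sigma, 1e-9)

  w <- window_px
  h <- (w - 1L) %/% 2L
  rm <- stats::runmed(f, w, endrule = "median")
  i_rng <- (w + 1L):(n - w - 1L)
  pre_med <- rm[i_rng - h]        # median of samples (i-w+1)..i
  post_med <- rm[i_rng + h + 1L]  # median of samples (i+1)..(i+w)
  step <- post_med - pre_med
  gate <- b - max(2 * sigma, 1e-9)
  cand <- which(step > threshold_sigma * sigma_eff & pre_med < gate)
  if (!length(cand)) return(empty)
  cand <- i_rng[cand]

  ## group contiguous candidates into runs, one event per run
  runs <- split(cand, cumsum(c(1L, diff(cand) > w)))
  d <- c(diff(f), 0)
  events <- lapply(runs, function(r) {
    i <- r[which.max(d[r])]
    pre_i <- max(1L, i - pre_fit_px + 1L):i
    fit <- .linfit(z[pre_i], f[pre_i])
    pre_val <- fit[1] + fit[2] * z[i]
    post_i <- (i + 1L):min(n, i + post_px)
    post_val <- stats::median(f[post_i])
    data.frame(force_pN = post_val - pre_val, rupture_index = i)
  })
  ev <- do.call(rbind, events)
  ev <- ev[ev$force_pN > 0, , drop = FALSE]
  if (!nrow(ev)) return(empty)
  if (is.null(contact_point)) contact_point <- find_contact_point(curve)
  ev$step_position_nm <- z[ev$rupture_index] - contact_point
  rownames(ev) <- NULL
  ev[, c("force_pN", "step_position_nm", "rupture_index")]
}

#' Detect events for every curve of a force map
#'
#' @param map a `force_map`.
#' @param threshold_sigma passed to [detect_unbinding_events()].
#' @return list of per-pixel event data frames, in the map's grid order.
#' @export
detect_map_events <- function(map, threshold_sigma = 6) {
  stopifnot(inherits(map, "force_map"))
  lapply(map$curves, detect_unbinding_events, threshold_sigma = threshold_sigma)
}

#' Binding frequency and junctional distribution coefficient of a force map
#'
#' The binding frequency is the fraction of map pixels whose curve shows
#' at least one unbinding event, computed overall, inside the junctional
#' stripe, and on the surrounding surface. The distribution coefficient is
#' the ratio of the on-border to off-border binding frequency; values
#' above 1 indicate binding events concentrated along the intercellular
#' border. When the surface binding frequency is zero the coefficient is
#' reported as `NA` (undefined), together with the raw counts.
#'
#' @param map a `force_map`.
#' @param threshold_sigma detection threshold (default 6).
#' @param events optional precomputed result of [detect_map_events()].
#' @return `map_statistics` object: list with `binding_frequency`,
#'   `bf_border`, `bf_surface`, `distribution_coefficient`,
#'   `se_log_coefficient` (delta-method SE of the log coefficient at the
#'   realized counts), `n_border_px`, `n_surface_px`, `n_bound_border`,
#'   `n_bound_surface` and the per-pixel `bound` matrix.
#' @export
map_statistics <- function(map, threshold_sigma = 6, events = NULL) {
  stopifnot(inherits(map, "force_map"))
  mask <- map$junction_mask
  if (!any(mask) || all(mask))
    stop("junction mask needs at least one border and one surface pixel")
  if (is.null(events)) events <- detect_map_events(map, threshold_sigma)
  bound <- matrix(vapply(events, nrow, 0L) > 0L, map$grid_dim[1], map$grid_dim[2])

  n_b <- sum(mask); n_s <- sum(!mask)
  x_b <- sum(bound & mask); x_s <- sum(bound & !mask)
  bf_b <- x_b / n_b; bf_s <- x_s / n_s
  coef <- if (bf_s == 0) NA_real_ else bf_b / bf_s
  se_log <- if (x_b > 0 && x_s > 0)
    sqrt((1 - bf_b) / x_b + (1 - bf_s) / x_s) else NA_real_

  out <- list(binding_frequency = mean(bound),
              bf_border = bf_b, bf_surface = bf_s,
              distribution_coefficient = coef,
              se_log_coefficient = se_log,
              n_border_px = n_b, n_surface_px = n_s,
              n_bound_border = x_b, n_bound_surface = x_s,
              bound = bound)
  class(out) <- "map_statistics"
  out
}

#' @export
print.map_statistics <- function(x, ...) {
  cat(sprintf(paste0("map_statistics: binding frequency %.3f ",
                     "(border %.3f over %d px, surface %.3f over %d px), ",
                     "distribution coefficient %s\n"),
              x$binding_frequency, x$bf_border, x$n_border_px,
              x$bf_surface, x$n_surface_px,
              if (is.na(x$distribution_coefficient)) "undefined"
              else sprintf("%.3f", x$distribution_coefficient)))
  invisible(x)
}

#' Pool unbinding events across force maps
#'
#' Collects per-event unbinding force and step position from one or more
#' maps into a long-format table carrying map and group identifiers, the
#' form used to compare conditions (one-way ANOVA with Bonferroni
#' correction via [anova_bonferroni()], or [compare_groups()] for two
#' groups).
#'
#' @param maps list of `force_map` objects.
#' @param groups group label per map (recycled if length 1).
#' @param threshold_sigma detection threshold (default 6).
#' @param events optional list of precomputed [detect_map_events()]
#'   results, one per map.
#' @return data frame with columns `group`, `map`, `pixel`, `force_pN`,
#'   `step_position_nm`.
#' @export
pool_events <- function(maps, groups = "all", threshold_sigma = 6,
                        events = NULL) {
  if (inherits(maps, "force_map")) maps <- list(maps)
  stopifnot(length(maps) >= 1L)
  ## a bare per-pixel event list for a single map is accepted too
  if (!is.null(events) && length(events) && is.data.frame(events[[1]]))
    events <- list(events)
  groups <- rep_len(as.character(groups), length(maps))
  rows <- list()
  for (m in seq_along(maps)) {
    ev <- if (is.null(events)) detect_map_events(maps[[m]], threshold_sigma)
    else events[[m]]
    for (px in seq_along(ev)) {
      e <- ev[[px]]
      if (!nrow(e)) next
      rows[[length(rows) + 1L]] <-
        data.frame(group = groups[m], map = m, pixel = px,
                   force_pN = e$force_pN,
                   step_position_nm = e$step_position_nm,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(group = character(0), map = integer(0),
                      pixel = integer(0), force_pN = numeric(0),
                      step_position_nm = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
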