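#' Trace bicellular borders from a cell label mask
#'
#' Identifies, for every pair of adjacent cells, the ordered pixel path
#' running along their shared interface. The trace is taken on the side of
#' the lower-numbered cell (pixels of that cell touching the other cell
#' 4-connectedly), thinned to a unit-width 8-connected path and ordered by
#' walking it end to end. Pixels whose 8-neighbourhood touches three or
#' more different cells (tricellular corners) are excluded from all traces,
#' so line scans and border profiles stay strictly bicellular.
#'
#' @param mask integer matrix; 0 = background, k > 0 = cell k.
#' @return list of `border_trace` objects, each a list with `labels`
#'   (the two cell ids), `path` (n x 2 matrix of row/col positions, in
#'   walking order) and `pixel_idx` (linear indices into the mask). An
#'   empty list if no two cells touch.
#' @export
trace_borders <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  labs <- sort(unique(mask[mask > 0L]))
  if (length(labs) < 2L) return(list())
  nr <- nrow(mask); nc <- ncol(mask)

  ## tricellular pixels: >= 3 distinct positive labels within the
  ## 8-neighbourhood (own pixel included)
  lab_count <- matrix(0L, nr, nc)
  for (l in labs) {
    here <- mask == l
    near <- here
    for (k in 1:8) near <- near | shift_mat(here, .nbr8[k, 1], .nbr8[k, 2])
    lab_count <- lab_count + near
  }
  tricell <- lab_count >= 3L

  traces <- list()
  for (i in seq_along(labs)) {
    a <- labs[i]
    in_a <- mask == a
    for (j in seq_along(labs)) {
      if (j <= i) next
      b <- labs[j]
      in_b <- mask == b
      touch_b <- shift_mat(in_b, 1L, 0L) | shift_mat(in_b, -1L, 0L) |
        shift_mat(in_b, 0L, 1L) | shift_mat(in_b, 0L, -1L)
      side <- in_a & touch_b & !tricell
      if (!any(side)) next
      ## keep the largest connected piece of the interface
      comp <- label_components(side, connectivity = 8)
      sizes <- tabulate(comp[comp > 0L])
      side <- comp == which.max(sizes)
      path_idx <- .order_path(side)
      if (length(path_idx) < 2L) next
      tr <- list(labels = c(a, b),
                 path = arrayInd(path_idx, c(nr, nc)),
                 pixel_idx = path_idx)
      class(tr) <- "border_trace"
      traces[[length(traces) + 1L]] <- tr
    }
  }
  traces
}

## thin a path-like mask and return its longest branch as an ordered index
## vector (handles open paths and closed loops)
.order_path <- function(side) {
  g <- skeletonize(side, thin = TRUE)
  if (!nrow(g$edges)) return(integer(0))
  g$edge_pixels[[which.max(g$edges$length_px)]]
}

#' Place line-scan segments across a traced border
#'
#' Distributes sampling segments of equal length and width along a border
#' trace, one every `spacing_px` trace pixels, each oriented along the
#' local border normal (estimated from a centred window of the trace by
#' principal axis). Segments that would leave the image, or whose scan line
#' crosses a cell other than the two the border separates (or background),
#' are dropped. Each segment carries a junctional band (central
#' `3 * border_width_px` samples) and a cytoplasmic band (the outer 25% of
#' samples at each end), the defaults used for junctional/cytoplasmic
#' ratio measurement; both are configurable through `border_width_px` and
#' `cytoplasm_frac`.
#'
#' @param trace a `border_trace` from [trace_borders()].
#' @param mask the cell label mask the trace came from (defines the image
#'   geometry and the third-cell exclusion).
#' @param spacing_px distance between segment centres along the trace.
#' @param length_px total number of profile samples; odd, >= 5.
#' @param width_px averaging width perpendicular to the scan direction.
#' @param border_width_px nominal width of the junctional signal in pixels;
#'   the junctional band spans the central `3 * border_width_px` samples
#'   (rounded up to odd).
#' @param cytoplasm_frac fraction of samples at each profile end treated as
#'   cytoplasm.
#' @return list of `line_scan_segment` objects: `center` (row, col),
#'   `direction` (unit normal), `tangent`, `length_px`, `width_px`,
#'   `junctional_band` and `cytoplasmic_band` (sample index vectors).
#' @export
place_line_scans <- function(trace, mask, spacing_px, length_px = 31L,
                             width_px = 3L, border_width_px = 1L,
                             cytoplasm_frac = 0.25) {
  stopifnot(inherits(trace, "border_trace"), is.matrix(mask))
  length_px <- as.integer(length_px)
  if (length_px < 5L || length_px %% 2L == 0L)
    stop("length_px must be odd and >= 5")
  stopifnot(spacing_px >= 1, width_px >= 1, border_width_px >= 1)
  path <- trace$path
  npx <- nrow(path)
  if (npx <= spacing_px && npx < 2L) return(list())

  half <- (length_px - 1L) / 2L
  jb_half <- (3L * as.integer(border_width_px)) %/% 2L
  junctional_band <- (half + 1L - jb_half):(half + 1L + jb_half)
  cyt_n <- max(1L, floor(length_px * cytoplasm_frac))
  cytoplasmic_band <- c(seq_len(cyt_n), (length_px - cyt_n + 1L):length_px)
  if (max(junctional_band) >= min((length_px - cyt_n + 1L):length_px) ||
      min(junctional_band) <= cyt_n)
    stop("junctional and cytoplasmic bands overlap; ",
         "increase length_px or decrease border_width_px")

  centroid <- colMeans(path)
  nr <- nrow(mask); nc <- ncol(mask)
  win <- 5L
  ## closed traces (loops) wrap the tangent-estimation window at the seam
  closed <- npx > 2L * win &&
    sqrt(sum((path[1L, ] - path[npx, ])^2)) < 2
  centers <- seq(1L, npx, by = as.integer(spacing_px))
  segs <- list()
  offs_t <- seq_len(width_px) - (width_px + 1) / 2
  offs_n <- seq_len(length_px) - (half + 1L)
  ok_labels <- c(trace$labels)

  for (ci in centers) {
    wi <- (ci - win):(ci + win)
    wi <- if (closed) ((wi - 1L) %% npx) + 1L else wi[wi >= 1L & wi <= npx]
    w <- path[wi, , drop = FALSE]
    if (nrow(w) < 2L) next
    cv <- stats::cov(w)
    ev <- eigen(cv, symmetric = TRUE)
    tangent <- ev$vectors[, 1L]
    tangent <- tangent / sqrt(sum(tangent^2))
    normal <- c(-tangent[2L], tangent[1L])
    ## orient the normal away from the trace centroid (radial for loops)
    ctr <- path[ci, ]
    outward <- ctr - centroid
    if (sum(normal * outward) < 0) normal <- -normal

    ## sample grid: length_px along the normal x width_px along the tangent
    rr <- outer(offs_n * normal[1L], offs_t * tangent[1L], `+`) + ctr[1L]
    cc <- outer(offs_n * normal[2L], offs_t * tangent[2L], `+`) + ctr[2L]
    if (min(rr) < 1 || max(rr) > nr || min(cc) < 1 || max(cc) > nc) next
    lab_at <- mask[cbind(pmin(pmax(round(rr), 1L), nr),
                         pmin(pmax(round(cc), 1L), nc))]
    if (!all(lab_at %in% ok_labels)) next

    seg <- list(center = ctr, direction = normal, tangent = tangent,
                length_px = length_px, width_px = as.integer(width_px),
                junctional_band = junctional_band,
                cytoplasmic_band = cytoplasmic_band)
    class(seg) <- "line_scan_segment"
    segs[[length(segs) + 1L]] <- seg
  }
  segs
}

#' Measure one line scan
#'
#' Samples the intensity profile of a segment by bilinear interpolation,
#' averaging across `width_px` parallel lines, and computes the junctional
#' and cytoplasmic means, their ratio, and the profile normalized to the
#' cytoplasmic mean. This is the per-scan statistic behind junctional
#' enrichment ratios: mean junctional intensity divided by the mean
#' cytoplasmic intensity of the same scan. No background subtraction is
#' performed; pre-subtract if required.
#'
#' @param image numeric matrix or `intensity_image`.
#' @param segment a `line_scan_segment`.
#' @return `line_scan_result`: list with `junctional_mean`,
#'   `cytoplasmic_mean`, `ratio`, `profile`, `normalized_profile`.
#' @export
measure_line_scan <- function(image, segment) {
  stopifnot(inherits(segment, "line_scan_segment"))
  img <- as_matrix(image)
  half <- (segment$length_px - 1L) / 2L
  offs_n <- seq_len(segment$length_px) - (half + 1L)
  offs_t <- seq_len(segment$width_px) - (segment$width_px + 1) / 2
  rr <- outer(offs_n * segment$direction[1L], offs_t * segment$tangent[1L], `+`) +
    segment$center[1L]
  cc <- outer(offs_n * segment$direction[2L], offs_t * segment$tangent[2L], `+`) +
    segment$center[2L]
  if (min(rr) < 1 || max(rr) > nrow(img) || min(cc) < 1 || max(cc) > ncol(img))
    stop("segment lies outside the image")
  vals <- matrix(bilinear_sample(img, as.vector(rr), as.vector(cc)),
                 nrow = segment$length_px)
  profile <- rowMeans(vals)
  jm <- mean(profile[segment$junctional_band])
  cm <- mean(profile[segment$cytoplasmic_band])
  if (cm == 0) stop("cytoplasmic mean is zero; ratio undefined")
  out <- list(junctional_mean = jm, cytoplasmic_mean = cm, ratio = jm / cm,
              profile = profile, normalized_profile = profile / cm)
  class(out) <- "line_scan_result"
  out
}

#' Summarise junctional/cytoplasmic ratios by group
#'
#' Collects per-scan ratios into the per-group five-number summary shown as
#' boxplots (first to third quartile with the full range of variation;
#' quartiles by linear interpolation, quantile type 7) and compares groups
#' with the rank-sum test (pairwise with Bonferroni correction when more
#' than two groups are given).
#'
#' @param results list of `line_scan_result` objects or a numeric vector of
#'   ratios.
#' @param groups group label per result.
#' @return list of class `ratio_summary` with elements `summary`
#'   (data frame: `group`, `n`, `median`, `q1`, `q3`, `min`, `max`) and
#'   `comparisons` (data frame of pairwise rank-sum tests: `group_a`,
#'   `group_b`, `p_value`, `p_adjusted`, `stars`).
#' @export
aggregate_ratios <- function(results, groups) {
  ratios <- if (is.numeric(results)) results
  else vapply(results, function(r) r$ratio, 0)
  stopifnot(length(ratios) == length(groups))
  groups <- as.character(groups)
  gl <- unique(groups)
  if (any(tabulate(factor(groups, levels = gl)) < 1L) || !length(ratios))
    stop("every group needs at least one result")

  summ <- do.call(rbind, lapply(gl, function(g) {
    x <- ratios[groups == g]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = g, n = length(x), median = q[2], q1 = q[1], q3 = q[3],
               min = min(x), max = max(x))
  }))

  comparisons <- NULL
  if (length(gl) >= 2L) {
    pairs <- utils::combn(gl, 2L)
    k <- ncol(pairs)
    comparisons <- do.call(rbind, lapply(seq_len(k), function(i) {
      a <- ratios[groups == pairs[1L, i]]
      b <- ratios[groups == pairs[2L, i]]
      cmp <- compare_groups(a, b, test = "mann_whitney")
      data.frame(group_a = pairs[1L, i], group_b = pairs[2L, i],
                 p_value = cmp$p_value, stringsAsFactors = FALSE)
    }))
    comparisons$p_adjusted <- pmin(1, comparisons$p_value * k)
    if (k == 1L) comparisons$p_adjusted <- comparisons$p_value
    comparisons$stars <- vapply(comparisons$p_adjusted, significance_stars, "")
  }
  out <- list(summary = summ, comparisons = comparisons)
  class(out) <- "ratio_summary"
  out
}

#' @export
print.ratio_summary <- function(x, ...) {
  cat("ratio_summary\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$comparisons)) print(x$comparisons, row.names = FALSE)
  invisible(x)
}
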