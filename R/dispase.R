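#' Count monolayer fragments in a dispase-assay well image
#'
#' Counts 8-connected foreground components of a well image, discarding
#' components smaller than `min_size_px` as debris. Intensity images are
#' binarized first (fixed threshold if given, Otsu otherwise). Automated
#' counting with a disclosed size filter stands in for manual fragment
#' counting; the filter applied is reported with the count.
#'
#' @param image logical matrix (binary) or numeric intensity matrix.
#' @param threshold fixed binarization threshold for intensity input;
#'   `NULL` selects Otsu.
#' @param min_size_px components smaller than this are discarded
#'   (default 50; 0 keeps everything).
#' @param well_id identifier carried into the result.
#' @return `fragment_count` object: list with `well_id`, `n_fragments`,
#'   `min_size_px`, `component_sizes` (all components, unfiltered),
#'   `kept_sizes` and the component `labels` matrix (filtered, relabelled
#'   1..n).
#' @export
count_fragments <- function(image, threshold = NULL, min_size_px = 50L,
                            well_id = "well") {
  stopifnot(is.matrix(image), min_size_px >= 0)
  if (is.logical(image)) {
    mask <- image
  } else if (all(image %in% c(0, 1))) {
    mask <- image > 0
  } else {
    mask <- if (is.null(threshold)) binarize(image, "otsu")
    else binarize(image, "fixed", threshold = threshold)
  }
  lab <- label_components(mask, connectivity = 8)
  sizes <- if (max(lab) > 0L) tabulate(lab[lab > 0L]) else integer(0)
  keep <- which(sizes >= min_size_px)
  relab <- integer(max(lab, 1L))
  relab[keep] <- seq_along(keep)
  out_lab <- matrix(0L, nrow(lab), ncol(lab))
  out_lab[lab > 0L] <- relab[lab[lab > 0L]]
  out <- list(well_id = well_id, n_fragments = length(keep),
              min_size_px = as.integer(min_size_px),
              component_sizes = sizes, kept_sizes = sizes[keep],
              labels = out_lab)
  class(out) <- "fragment_count"
  out
}

#' @export
print.fragment_count <- function(x, ...) {
  cat(sprintf("fragment_count '%s': %d fragments (of %d components, min size %d px)\n",
              x$well_id, x$n_fragments, length(x$component_sizes),
              x$min_size_px))
  invisible(x)
}

#' Compare fragment counts between conditions
#'
#' Per-group mean and standard error of the fragment count plus pairwise
#' two-tailed Student's t tests (Bonferroni-corrected when more than one
#' pair). A group with fewer than two wells reports `NA` SEM.
#'
#' @param counts numeric vector of fragment counts, or a list of
#'   `fragment_count` objects.
#' @param groups condition label per count.
#' @return `fragment_comparison` object with `summary` (data frame:
#'   `group`, `n`, `mean`, `sem`) and `comparisons` (data frame:
#'   `group_a`, `group_b`, `statistic`, `p_value`, `p_adjusted`, `stars`).
#' @export
compare_conditions <- function(counts, groups) {
  x <- if (is.numeric(counts)) counts
  else vapply(counts, function(cc) cc$n_fragments, 0L)
  stopifnot(length(x) == length(groups))
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) < 2L) stop("need at least 2 groups to compare")

  summ <- do.call(rbind, lapply(gl, function(g) {
    v <- x[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sem = if (length(v) >= 2L) stats::sd(v) / sqrt(length(v))
               else NA_real_)
  }))

  pairs <- utils::combn(gl, 2L)
  k <- ncol(pairs)
  comparisons <- do.call(rbind, lapply(seq_len(k), function(i) {
    a <- x[groups == pairs[1L, i]]
    b <- x[groups == pairs[2L, i]]
    if (length(a) < 2L || length(b) < 2L) {
      ## too few wells for a t test: reported as NA, not an error
      return(data.frame(group_a = pairs[1L, i], group_b = pairs[2L, i],
                        statistic = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    cmp <- compare_groups(a, b, test = "student_t")
    data.frame(group_a = pairs[1L, i], group_b = pairs[2L, i],
               statistic = cmp$statistic, p_value = cmp$p_value,
               stringsAsFactors = FALSE)
  }))
  comparisons$p_adjusted <- if (k > 1L) pmin(1, comparisons$p_value * k)
  else comparisons$p_value
  comparisons$stars <- vapply(comparisons$p_adjusted, function(p)
    if (is.na(p)) NA_character_ else significance_stars(p), "")

  out <- list(summary = summ, comparisons = comparisons)
  class(out) <- "fragment_comparison"
  out
}

#' @export
print.fragment_comparison <- function(x, ...) {
  cat("fragment_comparison\n")
  print(x$summary, row.names = FALSE)
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}
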