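#' Write / read a single-channel intensity image
#'
#' Images are stored as single-channel TIFF or PNG (chosen by file
#' extension); intensities are divided by `max_value` on write and
#' rescaled on read. TIFF is written at 16 bits per sample, so integer
#' intensities up to 65535 round-trip exactly; PNG output is 8-bit and
#' only suitable for binary or low-dynamic-range images.
#'
#' @param image numeric matrix or [intensity_image()].
#' @param path output file (`.tif`, `.tiff` or `.png`).
#' @param max_value full-scale intensity (default 65535).
#' @return `path`, invisibly.
#' @export
write_intensity_image <- function(image, path, max_value = 65535) {
  img <- as_matrix(image)
  if (max(img) > max_value) stop("intensities exceed max_value")
  EBImage::writeImage(EBImage::Image(img / max_value), path,
                      bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_intensity_image
#' @param pixel_size_um pixel size attached to the image on read.
#' @return for `read_intensity_image`, an [intensity_image()].
#' @export
read_intensity_image <- function(path, pixel_size_um = 0.161,
                                 max_value = 65535) {
  x <- EBImage::readImage(path)
  m <- round(matrix(as.numeric(x), dim(x)[1], dim(x)[2]) * max_value, 6)
  intensity_image(m, pixel_size_um)
}

#' Write / read an integer label mask as 16-bit TIFF
#'
#' @param mask integer matrix (0 = background).
#' @param path output `.tif` file.
#' @return `path` invisibly; for `read_label_mask`, the integer matrix.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(max(mask) < 65536)
  EBImage::writeImage(EBImage::Image(mask / 65535), path,
                      bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  x <- EBImage::readImage(path)
  matrix(as.integer(round(as.numeric(x) * 65535)), dim(x)[1], dim(x)[2])
}

#' Write / read a ground-truth sidecar as JSON
#'
#' Ground-truth records from the synthetic generators are serialized as
#' JSON next to the rendered data (`<basename>.truth.json` by
#' convention). Matrices are stored as run-length-encoded vectors with
#' their dimensions.
#'
#' @param truth list of ground-truth fields.
#' @param path output `.json` file.
#' @return `path` invisibly; for `read_ground_truth`, the list.
#' @export
write_ground_truth <- function(truth, path) {
  enc <- .encode_matrices(truth)
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

.encode_matrices <- function(x) {
  if (is.matrix(x)) {
    r <- rle(as.vector(x * 1))
    list(`_matrix` = TRUE, dim = dim(x), lengths = r$lengths,
         values = r$values, logical = is.logical(x))
  } else if (is.list(x)) {
    lapply(x, .encode_matrices)
  } else x
}

.decode_matrices <- function(x) {
  if (is.list(x) && isTRUE(x$`_matrix`)) {
    v <- inverse.rle(structure(list(lengths = unlist(x$lengths),
                                    values = unlist(x$values)), class = "rle"))
    m <- matrix(v, unlist(x$dim)[1], unlist(x$dim)[2])
    if (isTRUE(x$logical)) m <- m > 0
    m
  } else if (is.list(x)) {
    lapply(x, .decode_matrices)
  } else x
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  .decode_matrices(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write / read a force-distance curve as 3-column TSV
#'
#' The interchange format for force curves: tab-separated columns `z_nm`,
#' `force_pN`, `sweep` (approach/retract). Acquisition metadata and any
#' ground truth are written to a `.truth.json` sidecar when present.
#'
#' @param curve a `force_curve`.
#' @param path output `.tsv` file.
#' @param sidecar write the `<path minus extension>.truth.json` sidecar
#'   when the curve carries ground truth (default TRUE).
#' @return `path` invisibly; for `read_force_curve`, a `force_curve`.
#' @export
write_force_curve <- function(curve, path, sidecar = TRUE) {
  df <- as.data.frame(curve)[, c("z_nm", "force_pN", "sweep")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- attr(curve, "truth")
  if (sidecar && !is.null(truth)) {
    side <- paste0(sub("\\.[^.]*$", "", path), ".truth.json")
    jsonlite::write_json(truth, side, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' @rdname write_force_curve
#' @export
read_force_curve <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("z_nm", "force_pN", "sweep") %in% names(df)))
  side <- paste0(sub("\\.[^.]*$", "", path), ".truth.json")
  if (file.exists(side))
    attr(df, "truth") <- jsonlite::read_json(side, simplifyVector = TRUE)
  class(df) <- c("force_curve", class(df))
  df
}

#' Write / read a force map as a directory of curve TSVs
#'
#' The map directory holds one TSV per curve (`curve_0001.tsv`, ... in
#' column-major grid order) and a `map.json` with the grid shape, the grid
#' spacing and the junctional stripe mask (run-length encoded).
#'
#' @param map a `force_map`.
#' @param dir output directory (created if needed).
#' @return `dir` invisibly; for `read_force_map`, a `force_map`.
#' @export
write_force_map <- function(map, dir) {
  stopifnot(inherits(map, "force_map"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("curve_%04d.tsv", seq_along(map$curves))
  for (i in seq_along(map$curves))
    write_force_curve(map$curves[[i]], file.path(dir, files[i]),
                      sidecar = FALSE)
  r <- rle(as.vector(map$junction_mask))
  meta <- list(grid_dim = map$grid_dim, spacing_um = map$spacing_um,
               junction_mask_rle = list(lengths = r$lengths,
                                        values = r$values),
               files = files)
  jsonlite::write_json(meta, file.path(dir, "map.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_force_map
#' @export
read_force_map <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "map.json"),
                              simplifyVector = TRUE)
  curves <- lapply(file.path(dir, meta$files), read_force_curve)
  rl <- structure(list(lengths = meta$junction_mask_rle$lengths,
                       values = meta$junction_mask_rle$values),
                  class = "rle")
  mask <- matrix(inverse.rle(rl), meta$grid_dim[1], meta$grid_dim[2])
  out <- list(curves = curves, grid_dim = meta$grid_dim,
              spacing_um = meta$spacing_um, junction_mask = mask,
              truth = NULL)
  class(out) <- "force_map"
  out
}

## write an RGB array (values 0..1) as PNG; used for QC overlays
.write_rgb_png <- function(rgb, path) {
  png::writePNG(aperm(rgb, c(2, 1, 3)), path)  # to (y, x, channel)
  invisible(path)
}

#' QC overlay images
#'
#' `write_skeleton_overlay` renders the skeleton in red over the
#' normalized source image; `write_adhesion_map` colours force-map pixels
#' by binding (bound border pixels blue, bound surface pixels green,
#' stripe outline grey); `write_fragment_overlay` colours each kept
#' fragment with a distinct hue.
#'
#' @param image source intensity matrix.
#' @param graph a `skeleton_graph`.
#' @param path output `.png` file.
#' @return `path`, invisibly.
#' @export
write_skeleton_overlay <- function(image, graph, path) {
  img <- as_matrix(image)
  rng <- range(img)
  base <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  rgb <- array(rep(base, 3L), c(dim(img), 3L))
  sk <- graph$skeleton
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  r[sk] <- 1; g[sk] <- 0; b[sk] <- 0
  .write_rgb_png(array(c(r, g, b), c(dim(img), 3L)), path)
}

#' @rdname write_skeleton_overlay
#' @param map a `force_map`.
#' @param stats a `map_statistics` for the map.
#' @param scale_px integer upscaling factor for visibility.
#' @export
write_adhesion_map <- function(map, stats, path, scale_px = 8L) {
  bound <- stats$bound
  mask <- map$junction_mask
  d <- dim(bound)
  r <- matrix(0.85, d[1], d[2]); g <- r; b <- r
  r[mask] <- 0.7; g[mask] <- 0.7; b[mask] <- 0.7
  bb <- bound & mask
  r[bb] <- 0; g[bb] <- 0.2; b[bb] <- 0.9
  bs <- bound & !mask
  r[bs] <- 0; g[bs] <- 0.7; b[bs] <- 0.2
  up <- function(m) m[rep(seq_len(d[1]), each = scale_px),
                      rep(seq_len(d[2]), each = scale_px)]
  .write_rgb_png(array(c(up(r), up(g), up(b)),
                       c(d[1] * scale_px, d[2] * scale_px, 3L)), path)
}

#' @rdname write_skeleton_overlay
#' @param count a `fragment_count`.
#' @export
write_fragment_overlay <- function(count, path) {
  lab <- count$labels
  n <- max(lab)
  d <- dim(lab)
  r <- matrix(0, d[1], d[2]); g <- r; b <- r
  if (n > 0) {
    hues <- (seq_len(n) * 0.618) %% 1
    cols <- grDevices::hsv(hues, 0.8, 0.95)
    rgbv <- grDevices::col2rgb(cols) / 255
    sel <- lab > 0
    r[sel] <- rgbv[1, lab[sel]]
    g[sel] <- rgbv[2, lab[sel]]
    b[sel] <- rgbv[3, lab[sel]]
  }
  .write_rgb_png(array(c(r, g, b), c(d, 3L)), path)
}
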