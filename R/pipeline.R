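#' Run the quantification pipeline from a configuration
#'
#' Executes the requested stages of the desmosome quantification pipeline
#' from a YAML/JSON configuration (or an equivalent list): synthetic data
#' generation, line-scan ratios, border irregularity, keratin skeleton
#' density, AFM force-map analysis and dispase fragment counting, plus a
#' summary table over all computed metrics. Every output is written under
#' one run directory together with a manifest (parameters, seeds,
#' thresholds, file list) and a log. Reruns with the same configuration
#' and seed produce byte-identical CSVs (the log carries the only
#' timestamps).
#'
#' Configuration keys (all optional except `output_dir`):
#' \describe{
#'   \item{seed}{integer base seed for all simulated stages (default 1).}
#'   \item{simulate}{sub-lists `monolayer`, `network`, `force_map` (with
#'     optional `n_maps`, `groups`), `fragments` (list `wells` of per-well
#'     specs with optional `group`): arguments passed to the matching
#'     `*_params()` constructor.}
#'   \item{linescan}{`spacing_px`, `length_px`, `width_px`,
#'     `border_width_px`; or `image`/`mask` paths instead of the simulated
#'     monolayer.}
#'   \item{irregularity}{`width_px`, `denominator`.}
#'   \item{skeleton}{`method`, `threshold`, `min_branch_px`, `roi`
#'     (rectangle `c(r0, r1, c0, c1)`); or an `image` path.}
#'   \item{afm}{`threshold_sigma`; or `map_dirs` paths.}
#'   \item{dispase}{`min_size_px`, `threshold`; or `images` paths with
#'     `groups`.}
#' }
#'
#' @param config configuration list, or path to a `.yaml`/`.yml`/`.json`
#'   file.
#' @param output_dir overrides `config$output_dir`.
#' @return invisibly, a `report_bundle`: list of per-stage results and
#'   output paths.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  out_dir <- output_dir %||% config$output_dir
  if (is.null(out_dir)) stop("config needs an output_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)

  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  wcsv <- function(df, path) {
    utils::write.csv(df, path, row.names = FALSE)
    path
  }

  bundle <- list(output_dir = out_dir)
  files <- character(0)
  summary_rows <- list()
  add_summary <- function(stage, metric, group, value) {
    summary_rows[[length(summary_rows) + 1L]] <<-
      data.frame(stage = stage, metric = metric, group = group,
                 value = value, stringsAsFactors = FALSE)
  }
  logf("pipeline start (seed %d)", seed)

  ## ---- simulate ----------------------------------------------------------
  sim <- list()
  sc <- config$simulate
  if (!is.null(sc)) {
    sim_dir <- file.path(out_dir, "sim")
    dir.create(sim_dir, showWarnings = FALSE)
    if (!is.null(sc$monolayer)) {
      args <- sc$monolayer
      args$rng_seed <- args$rng_seed %||% (seed + 101L)
      sim$monolayer <- generate_monolayer(do.call(monolayer_params, args))
      files <- c(files,
                 write_intensity_image(sim$monolayer$image,
                                       file.path(sim_dir, "monolayer.tif")),
                 write_label_mask(sim$monolayer$mask,
                                  file.path(sim_dir, "monolayer_mask.tif")),
                 write_ground_truth(sim$monolayer$truth,
                                    file.path(sim_dir, "monolayer.truth.json")))
      logf("simulate: monolayer %dx%d, %d cells",
           nrow(sim$monolayer$mask), ncol(sim$monolayer$mask),
           max(sim$monolayer$mask))
    }
    if (!is.null(sc$network)) {
      args <- sc$network
      args$rng_seed <- args$rng_seed %||% (seed + 202L)
      sim$network <- generate_filament_network(do.call(filament_params, args))
      files <- c(files,
                 write_intensity_image(sim$network$image,
                                       file.path(sim_dir, "network.tif")),
                 write_ground_truth(
                   list(n_branches = n_branches(sim$network$graph),
                        n_junctions = n_junctions(sim$network$graph),
                        centerline = sim$network$centerline),
                   file.path(sim_dir, "network.truth.json")))
      logf("simulate: filament network (%d true branches, %d true junctions)",
           n_branches(sim$network$graph), n_junctions(sim$network$graph))
    }
    if (!is.null(sc$force_map)) {
      args <- sc$force_map
      n_maps <- args$n_maps %||% 1L
      map_groups <- args$groups %||% rep("all", n_maps)
      args$n_maps <- NULL; args$groups <- NULL
      base_seed <- args$rng_seed %||% (seed + 303L)
      sim$force_maps <- lapply(seq_len(n_maps), function(i) {
        args$rng_seed <- base_seed + i
        generate_force_map(do.call(map_params, args))
      })
      sim$force_map_groups <- rep_len(map_groups, n_maps)
      for (i in seq_len(n_maps))
        files <- c(files, write_force_map(sim$force_maps[[i]],
                                          file.path(sim_dir, sprintf("map_%02d", i))))
      logf("simulate: %d force map(s), %d curves each",
           n_maps, length(sim$force_maps[[1]]$curves))
    }
    if (!is.null(sc$fragments)) {
      wells <- sc$fragments$wells
      if (is.null(wells)) stop("simulate$fragments needs a 'wells' list")
      base_seed <- sc$fragments$rng_seed %||% (seed + 404L)
      sim$fragment_wells <- lapply(seq_along(wells), function(i) {
        w <- wells[[i]]
        grp <- w$group %||% "all"
        w$group <- NULL
        w$rng_seed <- w$rng_seed %||% (base_seed + i)
        list(group = grp, data = generate_fragment_image(do.call(fragment_params, w)))
      })
      for (i in seq_along(sim$fragment_wells))
        files <- c(files,
                   write_intensity_image(sim$fragment_wells[[i]]$data$image * 65535,
                                         file.path(sim_dir, sprintf("well_%02d.png", i))))
      logf("simulate: %d fragment well(s)", length(wells))
    }
    bundle$simulate <- sim
  }

  ## ---- line scans --------------------------------------------------------
  lc <- config$linescan
  if (!is.null(lc)) {
    if (!is.null(lc$image) && !is.null(lc$mask)) {
      image <- read_intensity_image(lc$image)
      mask <- read_label_mask(lc$mask)
    } else if (!is.null(sim$monolayer)) {
      image <- sim$monolayer$image
      mask <- sim$monolayer$mask
    } else stop("stage 'linescan': missing inputs (no image/mask and no simulated monolayer)")
    ls_dir <- file.path(out_dir, "linescan")
    dir.create(ls_dir, showWarnings = FALSE)
    traces <- trace_borders(mask)
    seg_rows <- list(); prof_rows <- list()
    for (bi in seq_along(traces)) {
      segs <- place_line_scans(traces[[bi]], mask,
                               spacing_px = lc$spacing_px %||% 10L,
                               length_px = lc$length_px %||% 31L,
                               width_px = lc$width_px %||% 3L,
                               border_width_px = lc$border_width_px %||% 1L)
      for (si in seq_along(segs)) {
        res <- measure_line_scan(image, segs[[si]])
        seg_rows[[length(seg_rows) + 1L]] <-
          data.frame(border_id = bi, segment_id = si,
                     junctional_mean = res$junctional_mean,
                     cytoplasmic_mean = res$cytoplasmic_mean,
                     ratio = res$ratio)
        prof_rows[[length(prof_rows) + 1L]] <-
          data.frame(border_id = bi, segment_id = si,
                     sample = seq_along(res$normalized_profile),
                     normalized_intensity = res$normalized_profile)
      }
    }
    if (!length(seg_rows)) stop("stage 'linescan': no valid segments placed")
    seg_df <- do.call(rbind, seg_rows)
    files <- c(files, wcsv(seg_df, file.path(ls_dir, "segments.csv")),
               wcsv(do.call(rbind, prof_rows), file.path(ls_dir, "profiles.csv")))
    agg <- aggregate_ratios(seg_df$ratio, rep("all", nrow(seg_df)))
    files <- c(files, wcsv(agg$summary, file.path(ls_dir, "summary.csv")))
    add_summary("linescan", "median_ratio", "all", agg$summary$median[1])
    bundle$linescan <- list(segments = seg_df, summary = agg)
    logf("linescan: %d segments on %d borders, median ratio %.3f",
         nrow(seg_df), length(traces), agg$summary$median[1])
  }

  ## ---- irregularity ------------------------------------------------------
  ic <- config$irregularity
  if (!is.null(ic)) {
    if (!is.null(sim$monolayer)) {
      image <- sim$monolayer$image
      mask <- sim$monolayer$mask
    } else if (!is.null(ic$image) && !is.null(ic$mask)) {
      image <- read_intensity_image(ic$image)
      mask <- read_label_mask(ic$mask)
    } else stop("stage 'irregularity': missing inputs")
    ir_dir <- file.path(out_dir, "irregularity")
    dir.create(ir_dir, showWarnings = FALSE)
    traces <- trace_borders(mask)
    rows <- do.call(rbind, lapply(seq_along(traces), function(bi) {
      sc <- border_irregularity(image, traces[[bi]],
                                width_px = ic$width_px %||% 3L,
                                denominator = ic$denominator %||% "all_pixels")
      data.frame(border_id = bi, n_pixels = sc$n_pixels,
                 mean_intensity = sc$mean_intensity, score = sc$score)
    }))
    if (is.null(rows)) stop("stage 'irregularity': no borders found")
    files <- c(files, wcsv(rows, file.path(ir_dir, "borders.csv")))
    add_summary("irregularity", "median_score", "all", stats::median(rows$score))
    bundle$irregularity <- rows
    logf("irregularity: %d borders, median score %.4f", nrow(rows),
         stats::median(rows$score))
  }

  ## ---- skeleton ----------------------------------------------------------
  kc <- config$skeleton
  if (!is.null(kc)) {
    if (!is.null(kc$image)) {
      image <- read_intensity_image(kc$image)
    } else if (!is.null(sim$network)) {
      image <- sim$network$image
    } else stop("stage 'skeleton': missing inputs")
    sk_dir <- file.path(out_dir, "skeleton")
    dir.create(sk_dir, showWarnings = FALSE)
    mask <- if (!is.null(kc$threshold))
      binarize(image, "fixed", threshold = kc$threshold)
    else binarize(image, kc$method %||% "otsu")
    graph <- skeletonize(mask)
    graph <- prune_spurs(graph, kc$min_branch_px %||% 3L)
    roi <- if (!is.null(kc$roi)) unlist(kc$roi)
    else c(1, nrow(as_matrix(image)), 1, ncol(as_matrix(image)))
    met <- skeleton_metrics(graph, roi, pixel_size_um = pixel_size_um(image))
    df <- data.frame(roi_id = 1L, area_um2 = met$roi_area_um2,
                     n_bundles = met$n_bundles, n_junctions = met$n_junctions,
                     bundle_density = met$bundle_density,
                     junction_density = met$junction_density,
                     threshold = attr(mask, "threshold"))
    files <- c(files, wcsv(df, file.path(sk_dir, "metrics.csv")),
               write_skeleton_overlay(image, graph,
                                      file.path(sk_dir, "overlay.png")))
    add_summary("skeleton", "bundle_density", "all", met$bundle_density)
    add_summary("skeleton", "junction_density", "all", met$junction_density)
    bundle$skeleton <- met
    logf("skeleton: %d bundles, %d junctions (threshold %.3f)",
         met$n_bundles, met$n_junctions, attr(mask, "threshold"))
  }

  ## ---- afm ---------------------------------------------------------------
  ac <- config$afm
  if (!is.null(ac)) {
    if (!is.null(ac$map_dirs)) {
      maps <- lapply(ac$map_dirs, read_force_map)
      map_groups <- ac$groups %||% rep("all", length(maps))
    } else if (!is.null(sim$force_maps)) {
      maps <- sim$force_maps
      map_groups <- sim$force_map_groups
    } else stop("stage 'afm': missing inputs")
    afm_dir <- file.path(out_dir, "afm")
    dir.create(afm_dir, showWarnings = FALSE)
    thr <- ac$threshold_sigma %||% 6
    all_events <- lapply(maps, detect_map_events, threshold_sigma = thr)
    stats_rows <- list()
    for (i in seq_along(maps)) {
      ms <- map_statistics(maps[[i]], events = all_events[[i]])
      stats_rows[[i]] <- data.frame(
        map = i, group = map_groups[i],
        binding_frequency = ms$binding_frequency,
        bf_border = ms$bf_border, bf_surface = ms$bf_surface,
        distribution_coefficient = ms$distribution_coefficient,
        n_border_px = ms$n_border_px, n_surface_px = ms$n_surface_px,
        threshold_sigma = thr)
      files <- c(files, write_adhesion_map(maps[[i]], ms,
                                           file.path(afm_dir, sprintf("adhesion_map_%02d.png", i))))
    }
    stats_df <- do.call(rbind, stats_rows)
    ev_df <- pool_events(maps, map_groups, events = all_events)
    files <- c(files, wcsv(stats_df, file.path(afm_dir, "map_stats.csv")),
               wcsv(ev_df, file.path(afm_dir, "events.csv")))
    for (i in seq_len(nrow(stats_df))) {
      add_summary("afm", "binding_frequency", stats_df$group[i],
                  stats_df$binding_frequency[i])
      add_summary("afm", "distribution_coefficient", stats_df$group[i],
                  stats_df$distribution_coefficient[i])
    }
    bundle$afm <- list(map_stats = stats_df, events = ev_df)
    logf("afm: %d map(s), %d events pooled", length(maps), nrow(ev_df))
  }

  ## ---- dispase -----------------------------------------------------------
  dc <- config$dispase
  if (!is.null(dc)) {
    if (!is.null(dc$images)) {
      wells <- lapply(seq_along(dc$images), function(i)
        list(group = (dc$groups %||% rep("all", length(dc$images)))[i],
             image = as_matrix(read_intensity_image(dc$images[[i]]))))
    } else if (!is.null(sim$fragment_wells)) {
      wells <- lapply(sim$fragment_wells, function(w)
        list(group = w$group, image = w$data$image))
    } else stop("stage 'dispase': missing inputs")
    dp_dir <- file.path(out_dir, "dispase")
    dir.create(dp_dir, showWarnings = FALSE)
    counts <- lapply(seq_along(wells), function(i)
      count_fragments(wells[[i]]$image, threshold = dc$threshold,
                      min_size_px = dc$min_size_px %||% 50L,
                      well_id = sprintf("well_%02d", i)))
    groups <- vapply(wells, function(w) w$group, "")
    df <- data.frame(well_id = vapply(counts, function(x) x$well_id, ""),
                     group = groups,
                     n_fragments = vapply(counts, function(x) x$n_fragments, 0L),
                     min_size_px = vapply(counts, function(x) x$min_size_px, 0L))
    files <- c(files, wcsv(df, file.path(dp_dir, "counts.csv")))
    for (i in seq_along(counts))
      files <- c(files, write_fragment_overlay(counts[[i]],
                                               file.path(dp_dir, sprintf("overlay_%02d.png", i))))
    if (length(unique(groups)) >= 2L) {
      cmp <- compare_conditions(df$n_fragments, groups)
      files <- c(files, wcsv(cmp$summary, file.path(dp_dir, "group_summary.csv")),
                 wcsv(cmp$comparisons, file.path(dp_dir, "comparison.csv")))
      bundle$dispase_comparison <- cmp
    }
    for (g in unique(groups))
      add_summary("dispase", "mean_fragments", g,
                  mean(df$n_fragments[df$group == g]))
    bundle$dispase <- df
    logf("dispase: %d wells counted", nrow(df))
  }

  ## ---- report ------------------------------------------------------------
  if (length(summary_rows)) {
    summary_df <- do.call(rbind, summary_rows)
    files <- c(files, wcsv(summary_df, file.path(out_dir, "summary.csv")))
    bundle$summary <- summary_df
  }
  manifest <- list(
    package = "desmoquant",
    version = as.character(utils::packageVersion("desmoquant")),
    seed = seed,
    config = .strip_classes(config),
    outputs = sort(unique(sub(paste0("^", out_dir, "/?"), "", files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  logf("pipeline done: %d output files", length(files))
  class(bundle) <- "report_bundle"
  invisible(bundle)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## drop S3 classes so a configuration serializes cleanly to JSON
.strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), .strip_classes) else x
}
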