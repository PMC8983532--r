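test_that("skeletonize reproduces hand counts on constructed fixtures", {
  ## straight thick bar: one branch, two end points, no junction
  g <- skeletonize(bar_mask())
  expect_equal(n_branches(g), 1L)
  expect_equal(n_junctions(g), 0L)
  expect_equal(sum(g$nodes$type == "end"), 2L)

  ## plus sign: four arms around one junction
  gp <- skeletonize(plus_mask())
  expect_equal(n_branches(gp), 4L)
  expect_equal(n_junctions(gp), 1L)
  expect_equal(sum(gp$nodes$type == "end"), 4L)

  ## empty mask: empty graph
  ge <- skeletonize(matrix(FALSE, 10, 10))
  expect_equal(n_branches(ge), 0L)
  expect_equal(n_junctions(ge), 0L)
})

test_that("skeleton pixels partition into junction nodes and branches", {
  for (m in list(plus_mask(), bar_mask(), line_with_spur())) {
    g <- skeletonize(m)
    jpx <- unlist(g$node_pixels[g$nodes$type == "junction"], use.names = FALSE)
    epx <- setdiff(unlist(g$edge_pixels, use.names = FALSE), jpx)
    ## every skeleton pixel is junction-node or branch, never both
    expect_same_multiset(c(jpx, epx), which(g$skeleton))
    ## non-junction pixels belong to exactly one branch
    counts <- table(setdiff(unlist(g$edge_pixels, use.names = FALSE), jpx))
    expect_true(all(counts == 1L))
  }
})

test_that("spur pruning removes short side branches and is idempotent", {
  m <- line_with_spur(31L, spur_len = 2L)
  g <- skeletonize(m, thin = FALSE)
  expect_equal(n_branches(g), 3L)
  expect_equal(n_junctions(g), 1L)

  ## pruning dissolves the junction into a single through-path
  gp <- prune_spurs(g, min_branch_px = 3L)
  expect_equal(n_branches(gp), 1L)
  expect_equal(n_junctions(gp), 0L)

  ## min_branch_px = 0 leaves the graph unchanged
  expect_identical(prune_spurs(g, 0L)$skeleton, g$skeleton)

  ## idempotence
  gpp <- prune_spurs(gp, min_branch_px = 3L)
  expect_identical(gpp$skeleton, gp$skeleton)
})

test_that("skeleton metrics compute densities with 1/area scaling", {
  g <- skeletonize(bar_mask(20L, 30L))
  ps <- 1  # 1 um/px for round numbers
  roi_small <- c(1, 10, 1, 30)   # 300 um^2, contains the full bar
  roi_big <- c(1, 20, 1, 30)     # 600 um^2
  m_small <- skeleton_metrics(g, roi_small, pixel_size_um = ps)
  m_big <- skeleton_metrics(g, roi_big, pixel_size_um = ps)
  expect_equal(m_small$n_bundles, 1L)
  expect_equal(m_big$n_bundles, 1L)
  expect_equal(m_small$bundle_density, 1 / 300)
  ## doubling the ROI with no new skeleton halves the density
  expect_equal(m_big$bundle_density, m_small$bundle_density / 2)

  ## empty graph: all metrics zero
  ge <- skeletonize(matrix(FALSE, 10, 10))
  me <- skeleton_metrics(ge, c(1, 10, 1, 10), pixel_size_um = ps)
  expect_equal(me$n_bundles, 0L)
  expect_equal(me$n_junctions, 0L)
  expect_equal(me$bundle_density, 0)

  ## arithmetic check: 1 branch in 10 um^2 -> 0.1 per um^2
  mb <- skeleton_metrics(g, c(6, 15, 11, 11), pixel_size_um = 1)
  expect_equal(mb$roi_area_um2, 10)

  expect_error(skeleton_metrics(g, c(5, 4, 1, 1), pixel_size_um = 1), "ROI")
})

test_that("branch ROI membership uses the half-inside rule", {
  ## horizontal line of 20 px; ROI covering 60% of it counts the branch,
  ## ROI covering 40% does not
  m <- matrix(FALSE, 11, 24); m[6, 3:22] <- TRUE
  g <- skeletonize(m, thin = FALSE)
  expect_equal(skeleton_metrics(g, c(1, 11, 1, 14), 1)$n_bundles, 1L)  # 12/20 inside
  expect_equal(skeleton_metrics(g, c(1, 11, 1, 10), 1)$n_bundles, 0L)  # 8/20 inside
})

test_that("image pipeline recovers generated network topology at zero noise", {
  ## filament density kept below the resolution limit of the rendering
  ## (ridges separated by less than the PSF merge and cannot be recovered
  ## by any image-based method; see the vignette)
  recovered_vs_truth <- function(seed) {
    p <- filament_params(image_shape = c(256L, 256L), n_seeds = 6L,
                         branch_prob = 0.05, max_filaments = 16L,
                         noise_sd = 0, rng_seed = seed)
    nw <- generate_filament_network(p)
    mask <- binarize(nw$image, "otsu")
    g <- prune_spurs(skeletonize(mask), 3L)
    tg <- prune_spurs(nw$graph, 3L)     # identical pruning on the oracle
    c(n_branches(g), n_branches(tg), n_junctions(g), n_junctions(tg))
  }
  v <- rowSums(vapply(1:8, recovered_vs_truth, numeric(4)))
  ## pooled over replicates: counts within 10% of ground truth
  expect_lt(abs(v[1] - v[2]) / v[2], 0.10)
  expect_lte(abs(v[3] - v[4]) / max(v[4], 1), 0.10)
})

test_that("Otsu foreground covers the rendered ridge centrelines", {
  p <- filament_params(image_shape = c(128L, 128L), noise_sd = 2, rng_seed = 6)
  nw <- generate_filament_network(p)
  mask <- binarize(nw$image, "otsu")
  cl <- which(nw$centerline)
  ## interior centreline pixels (away from the image border, where ridge
  ## ends taper) are foreground
  pos <- arrayInd(cl, dim(mask))
  interior <- pos[, 1] > 3 & pos[, 1] < 126 & pos[, 2] > 3 & pos[, 2] < 126
  expect_gte(mean(mask[cl[interior]]), 0.99)
})

test_that("denser generation parameters yield higher measured densities", {
  density_of <- function(n_seeds, branch_prob, seed) {
    p <- filament_params(image_shape = c(128L, 128L), n_seeds = n_seeds,
                         branch_prob = branch_prob, noise_sd = 0,
                         rng_seed = seed)
    nw <- generate_filament_network(p)
    g <- prune_spurs(skeletonize(binarize(nw$image, "otsu")), 3L)
    m <- skeleton_metrics(g, c(1, 128, 1, 128), pixel_size_um = 0.161)
    c(m$bundle_density, m$junction_density)
  }
  seeds <- 1:20
  sparse <- vapply(seeds, function(s) density_of(3L, 0.02, s), numeric(2))
  dense <- vapply(seeds, function(s) density_of(10L, 0.15, s + 100L), numeric(2))
  expect_gt(mean(dense[1, ]), mean(sparse[1, ]))
  expect_gt(mean(dense[2, ]), mean(sparse[2, ]))
})
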