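test_that("monolayer generator honours the identity case and determinism", {
  p <- monolayer_params(image_shape = c(128L, 128L), enrichment_ratio = 1,
                        patchiness = 0, noise_sd = 0, rng_seed = 3)
  out <- generate_monolayer(p)
  expect_true(all(out$image == p$cytoplasm_mean))

  out2 <- generate_monolayer(p)
  expect_identical(unclass(out$image), unclass(out2$image))
  expect_identical(out$mask, out2$mask)

  ## different seed moves the seeds
  out3 <- generate_monolayer(monolayer_params(image_shape = c(128L, 128L),
                                              enrichment_ratio = 1, noise_sd = 0,
                                              rng_seed = 4))
  expect_false(identical(out$mask, out3$mask))
})

test_that("monolayer generator rejects degenerate geometry", {
  p <- monolayer_params(image_shape = c(64L, 64L), n_cells = 2L, rng_seed = 1)
  expect_error(generate_monolayer(p, seed_points = rbind(c(20, 20), c(20.5, 20))),
               "degenerate")
})

test_that("monolayer intensities are non-negative and ground truth is complete", {
  p <- monolayer_params(image_shape = c(128L, 128L), noise_sd = 40, rng_seed = 9,
                        patchiness = 0.3, patch_amplitude = 1)
  out <- generate_monolayer(p)
  expect_true(all(out$image >= 0))
  expect_true(length(out$truth$border_pixels) > 0)
  expect_true(is.matrix(out$truth$stripe))
  expect_equal(out$truth$enrichment_ratio, 3)
  expect_true(length(out$truth$patches) > 0)
})

test_that("filament generator records the true graph, including crossings", {
  ## single straight filament: 1 edge, no junctions
  p1 <- filament_params(image_shape = c(64L, 64L), n_seeds = 1L,
                        branch_prob = 0, turn_sd = 0, max_steps = 6L,
                        noise_sd = 0, rng_seed = 2)
  nw1 <- generate_filament_network(p1)
  expect_equal(n_branches(nw1$graph), 1L)
  expect_equal(n_junctions(nw1$graph), 0L)

  ## two crossing straight filaments: 4 edges around 1 junction
  pf <- filament_params(image_shape = c(51L, 51L), noise_sd = 0, rng_seed = 1)
  nwx <- generate_filament_network(pf, polylines = crossing_polylines(51L))
  expect_equal(n_branches(nwx$graph), 4L)
  expect_equal(n_junctions(nwx$graph), 1L)

  ## determinism
  p <- filament_params(rng_seed = 5)
  a <- generate_filament_network(p)
  b <- generate_filament_network(p)
  expect_identical(a$centerline, b$centerline)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_equal(n_branches(a$graph), n_branches(b$graph))

  expect_error(filament_params(image_shape = c(0L, 10L), rng_seed = 1))
})

test_that("force-curve generator embeds exactly one step with known truth", {
  p <- curve_params(binding = TRUE, unbinding_force_pN = 50,
                    step_position_nm = 80, baseline_noise_sd_pN = 0,
                    rng_seed = 1)
  cv <- generate_force_curve(p)
  tr <- attr(cv, "truth")
  s <- desmoquant:::sweep_of(cv, "retract")
  dz <- diff(s$z[1:2])
  ## beyond the rupture the retract force is exactly zero
  expect_true(all(s$f[s$z > tr$rupture_z_nm] == 0))
  ## realized step position within one sample of the request
  expect_lt(abs(tr$step_position_nm - 80), dz + 1e-9)
  ## the force at the rupture sample equals minus the unbinding force
  expect_equal(s$f[tr$rupture_index], -50)
  ## non-binding, zero-noise: force is zero beyond the contact point
  p0 <- curve_params(baseline_noise_sd_pN = 0, rng_seed = 1)
  s0 <- desmoquant:::sweep_of(generate_force_curve(p0), "retract")
  expect_true(all(s0$f[s0$z > tr$contact_point_nm] == 0))
  ## errors
  expect_error(curve_params(binding = TRUE, unbinding_force_pN = -5,
                            step_position_nm = 80, rng_seed = 1), "unbinding_force")
  expect_error(curve_params(binding = TRUE, unbinding_force_pN = 5,
                            step_position_nm = 2000, rng_seed = 1), "step_position")
})

test_that("tether-plateau curves hold constant force until the rupture", {
  p <- curve_params(binding = TRUE, unbinding_force_pN = 40,
                    step_position_nm = 200, tether_plateau = TRUE,
                    baseline_noise_sd_pN = 0, rng_seed = 1)
  cv <- generate_force_curve(p)
  tr <- attr(cv, "truth")
  s <- desmoquant:::sweep_of(cv, "retract")
  plateau <- s$z > tr$contact_point_nm & s$z <= tr$rupture_z_nm
  expect_true(all(s$f[plateau] == -40))
})

test_that("force-map geometry, Bernoulli structure and determinism hold", {
  tmpl <- curve_params(binding = TRUE, unbinding_force_pN = 50,
                       step_position_nm = 80, n_points = 64L,
                       baseline_noise_sd_pN = 0, rng_seed = 0)
  ## n_points >= 50 keeps curves cheap here; geometry is what matters
  p <- map_params(curve_params = tmpl, rng_seed = 8)
  fm <- generate_force_map(p)
  expect_equal(length(fm$curves), 1200L)
  expect_equal(fm$grid_dim, c(20L, 60L))
  expect_true(any(fm$junction_mask) && !all(fm$junction_mask))
  ## per-pixel truth matches each curve's own truth
  bind_from_curves <- vapply(fm$curves, function(cv) attr(cv, "truth")$binding, TRUE)
  expect_identical(as.vector(fm$truth$bind), bind_from_curves)
  ## determinism
  fm2 <- generate_force_map(p)
  expect_identical(fm$truth$bind, fm2$truth$bind)
  expect_identical(fm$curves[[1]]$force_pN, fm2$curves[[1]]$force_pN)
  ## empty stripe errors
  expect_error(generate_force_map(
    map_params(border_stripe = list(center_frac = 5, width_um = 0.1),
               curve_params = tmpl, rng_seed = 1)), "stripe")
})

test_that("fragment generator packs non-touching blobs with exact counts", {
  p <- fragment_params(image_shape = c(256L, 256L), n_fragments = 12L,
                       min_frag_px = 40L, max_frag_px = 150L,
                       debris_count = 6L, rng_seed = 4)
  out <- generate_fragment_image(p)
  lab <- label_components(out$image)
  ## conservation: components before size filtering = fragments + debris
  expect_equal(max(lab), 12L + 6L)
  expect_true(all(out$truth$fragment_sizes >= 40))
  expect_true(all(out$truth$debris_sizes < 40))
  ## blank case
  blank <- generate_fragment_image(fragment_params(n_fragments = 0L,
                                                   debris_count = 0L,
                                                   rng_seed = 1))
  expect_equal(sum(blank$image), 0L)
  ## determinism
  out2 <- generate_fragment_image(p)
  expect_identical(out$image, out2$image)
  ## impossible packing errors out
  expect_error(generate_fragment_image(
    fragment_params(image_shape = c(32L, 32L), n_fragments = 60L,
                    min_frag_px = 30L, max_frag_px = 40L, debris_count = 0L,
                    rng_seed = 1)), "place")
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_monolayer(monolayer_params(image_shape = c(64L, 64L),
                                                rng_seed = 1)))
  expect_identical(.Random.seed, before)
})
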