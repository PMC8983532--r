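test_that("contact point is recovered exactly on noiseless curves", {
  p <- curve_params(baseline_noise_sd_pN = 0, rng_seed = 1)
  cv <- generate_force_curve(p)
  truth <- attr(cv, "truth")$contact_point_nm
  dz <- 1500 / (p$n_points - 1)
  expect_lt(abs(find_contact_point(cv) - truth), dz)

  ## equivariance: shifting z shifts the contact point by the same amount
  cv2 <- cv
  cv2$z_nm <- cv2$z_nm + 57
  expect_equal(find_contact_point(cv2), find_contact_point(cv) + 57,
               tolerance = 1e-6)

  ## pure baseline curve has no contact region
  flat <- cv
  flat$force_pN <- rep(0, nrow(flat))
  expect_error(find_contact_point(flat), "no contact region")
})

test_that("zero-noise binding curves round-trip force and step position", {
  for (tether in c(FALSE, TRUE)) {
    p <- curve_params(binding = TRUE, unbinding_force_pN = 50,
                      step_position_nm = 80, baseline_noise_sd_pN = 0,
                      tether_plateau = tether, rng_seed = 1)
    cv <- generate_force_curve(p)
    tr <- attr(cv, "truth")
    ev <- detect_unbinding_events(cv, threshold_sigma = 6)
    dz <- 1500 / (p$n_points - 1)
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$force_pN, 50, tolerance = 1e-6)
    expect_lt(abs(ev$step_position_nm - tr$step_position_nm), dz)
    expect_lt(abs(ev$step_position_nm - 80), 2 * dz)
  }
})

test_that("non-binding curves yield no events; infinite threshold silences all", {
  p <- curve_params(baseline_noise_sd_pN = 5, rng_seed = 77)
  cv <- generate_force_curve(p)
  expect_equal(nrow(detect_unbinding_events(cv)), 0L)

  pb <- curve_params(binding = TRUE, unbinding_force_pN = 100,
                     step_position_nm = 100, baseline_noise_sd_pN = 5,
                     rng_seed = 78)
  expect_equal(nrow(detect_unbinding_events(generate_force_curve(pb),
                                            threshold_sigma = Inf)), 0L)
})

test_that("false-positive rate at 6 sigma stays below 1%", {
  n_rep <- 500L
  fp <- vapply(seq_len(n_rep), function(i) {
    p <- curve_params(baseline_noise_sd_pN = 5, n_points = 512L,
                      rng_seed = 1000L + i)
    nrow(detect_unbinding_events(generate_force_curve(p), threshold_sigma = 6)) > 0L
  }, TRUE)
  expect_lt(mean(fp), 0.01)
})

test_that("detection power and accuracy at SNR 10 meet the recovery targets", {
  n_rep <- 200L
  res <- vapply(seq_len(n_rep), function(i) {
    p <- curve_params(binding = TRUE, unbinding_force_pN = 50,
                      step_position_nm = 80, baseline_noise_sd_pN = 5,
                      n_points = 512L, rng_seed = 2000L + i)
    cv <- generate_force_curve(p)
    tr <- attr(cv, "truth")
    ev <- detect_unbinding_events(cv, threshold_sigma = 6)
    if (!nrow(ev)) return(c(NA_real_, NA_real_))
    i_best <- which.max(ev$force_pN)
    c(ev$force_pN[i_best], ev$step_position_nm[i_best] - tr$step_position_nm)
  }, numeric(2))
  detected <- !is.na(res[1, ])
  ## power at F = 10 sigma
  expect_gte(mean(detected), 0.95)
  ## median recovered force within 5% of 50 pN
  expect_lt(abs(median(res[1, detected]) - 50) / 50, 0.05)
  ## median step-position error within 5 nm
  expect_lt(abs(median(res[2, detected])), 5)
})

test_that("map statistics recover binding probabilities and the coefficient", {
  tmpl <- curve_params(binding = TRUE, unbinding_force_pN = 50,
                       step_position_nm = 80, n_points = 512L,
                       baseline_noise_sd_pN = 5, rng_seed = 0)
  p <- map_params(p_bind_border = 0.6, p_bind_surface = 0.3,
                  curve_params = tmpl, rng_seed = 42)
  fm <- generate_force_map(p)
  ms <- map_statistics(fm)

  ## estimated coefficient close to 2 within its 95% binomial interval
  expect_false(is.na(ms$distribution_coefficient))
  expect_lt(abs(log(ms$distribution_coefficient) - log(2)),
            1.96 * ms$se_log_coefficient)
  ## per-pixel binding recovered almost everywhere
  expect_gte(mean(unname(ms$bound) == unname(fm$truth$bind)), 0.99)

  ## uniform binding: coefficient within the 95% CI of 1
  pu <- map_params(p_bind_border = 0.3, p_bind_surface = 0.3,
                   curve_params = tmpl, rng_seed = 43)
  msu <- map_statistics(generate_force_map(pu))
  expect_lt(abs(log(msu$distribution_coefficient)), 1.96 * msu$se_log_coefficient)
})

test_that("map statistics handle degenerate masks and all-bound maps", {
  tmpl <- curve_params(binding = TRUE, unbinding_force_pN = 80,
                       step_position_nm = 80, n_points = 256L,
                       baseline_noise_sd_pN = 2, rng_seed = 0)
  stripe <- list(center_frac = 0.5, width_um = 0.2)
  p <- map_params(region_um = c(1, 0.5), border_stripe = stripe,
                  p_bind_border = 1, p_bind_surface = 1,
                  curve_params = tmpl, rng_seed = 5)
  fm <- generate_force_map(p)
  ms <- map_statistics(fm)
  expect_equal(ms$binding_frequency, 1)
  expect_equal(ms$distribution_coefficient, 1)

  ## a stripe covering the whole region leaves no surface pixels
  pall <- map_params(region_um = c(1, 0.5), p_bind_border = 1,
                     p_bind_surface = 1, curve_params = tmpl, rng_seed = 5)
  expect_error(map_statistics(generate_force_map(pall)), "surface")

  ## zero surface binding: coefficient undefined, counts still reported
  p0 <- map_params(region_um = c(1, 0.5), border_stripe = stripe,
                   p_bind_border = 1, p_bind_surface = 0,
                   curve_params = tmpl, rng_seed = 6)
  ms0 <- map_statistics(generate_force_map(p0))
  expect_true(is.na(ms0$distribution_coefficient))
  expect_equal(ms0$n_bound_surface, 0L)
})

test_that("pooled event tables are complete and order-invariant", {
  tmpl <- curve_params(binding = TRUE, unbinding_force_pN = 60,
                       step_position_nm = 100, n_points = 256L,
                       baseline_noise_sd_pN = 3, rng_seed = 0)
  p1 <- map_params(region_um = c(1.5, 0.5), curve_params = tmpl, rng_seed = 21)
  p2 <- map_params(region_um = c(1.5, 0.5), curve_params = tmpl, rng_seed = 22)
  m1 <- generate_force_map(p1); m2 <- generate_force_map(p2)
  e1 <- detect_map_events(m1); e2 <- detect_map_events(m2)

  tab <- pool_events(list(m1, m2), c("a", "b"), events = list(e1, e2))
  n_events <- sum(vapply(c(e1, e2), nrow, 0L))
  expect_equal(nrow(tab), n_events)
  expect_lte(nrow(tab), length(m1$curves) + length(m2$curves))

  ## order invariance: same multiset of (force, position) rows
  tab_rev <- pool_events(list(m2, m1), c("b", "a"), events = list(e2, e1))
  expect_same_multiset(tab$force_pN, tab_rev$force_pN)
  expect_same_multiset(tab$step_position_nm, tab_rev$step_position_nm)

  ## empty maps pool to an empty table
  expect_equal(nrow(pool_events(list(m1), "a",
                                events = list(rep(list(
                                  data.frame(force_pN = numeric(0),
                                             step_position_nm = numeric(0),
                                             rupture_index = integer(0))),
                                  length(m1$curves))))), 0L)
})
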