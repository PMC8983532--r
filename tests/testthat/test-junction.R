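test_that("trace_borders finds one full-height trace between half-plane cells", {
  mask <- two_cell_mask(40L, 40L, 20L)
  traces <- trace_borders(mask)
  expect_length(traces, 1L)
  expect_equal(traces[[1]]$labels, c(1L, 2L))
  expect_equal(nrow(traces[[1]]$path), 40L)
  expect_true(all(traces[[1]]$path[, 2] == 20L))
  ## walking order is monotone along the border
  expect_true(all(diff(traces[[1]]$path[, 1]) %in% c(-1L, 1L)))
})

test_that("trace_borders excludes tricellular pixels and handles edge cases", {
  mask <- three_cell_mask(60L)
  traces <- trace_borders(mask)
  expect_length(traces, 3L)
  mid <- 30L
  ## the 2x2 block around the meeting corner is tricellular (each of its
  ## pixels sees all three labels in its 8-neighbourhood) and must appear
  ## in no trace
  tricellular <- rbind(c(mid, mid), c(mid, mid + 1L),
                       c(mid + 1L, mid), c(mid + 1L, mid + 1L))
  tri_idx <- tricellular[, 1] + (tricellular[, 2] - 1L) * 60L
  for (tr in traces) expect_length(intersect(tr$pixel_idx, tri_idx), 0L)
  expect_length(trace_borders(matrix(1L, 10, 10)), 0L)
  expect_length(trace_borders(matrix(0L, 10, 10)), 0L)
})

test_that("line scans on a straight vertical border are horizontal", {
  mask <- two_cell_mask(60L, 60L, 30L)
  tr <- trace_borders(mask)[[1]]
  segs <- place_line_scans(tr, mask, spacing_px = 7L, length_px = 15L)
  expect_gt(length(segs), 3L)
  for (s in segs) {
    expect_equal(abs(s$direction), c(0, 1), tolerance = 1e-6)
    expect_equal(sum(s$direction^2), 1, tolerance = 1e-12)
  }
})

test_that("line scans on a circular border point radially", {
  mask <- disc_mask(121L, 45)
  tr <- trace_borders(mask)[[1]]
  segs <- place_line_scans(tr, mask, spacing_px = 9L, length_px = 15L)
  expect_gt(length(segs), 5L)
  centre <- c(61, 61)
  for (s in segs) {
    radial <- s$center - centre
    radial <- radial / sqrt(sum(radial^2))
    expect_gt(sum(radial * s$direction), 0.99)
  }
})

test_that("segment spacing and placement are deterministic", {
  mask <- two_cell_mask(60L, 60L, 30L)
  tr <- trace_borders(mask)[[1]]
  a <- place_line_scans(tr, mask, spacing_px = 10L)
  b <- place_line_scans(tr, mask, spacing_px = 10L)
  expect_identical(a, b)
  ## spacing larger than the trace leaves at most one segment
  few <- place_line_scans(tr, mask, spacing_px = 1000L)
  expect_lte(length(few), 1L)
  expect_error(place_line_scans(tr, mask, spacing_px = 5L, length_px = 10L),
               "odd")
})

test_that("measure_line_scan computes ratio, normalization and invariances", {
  mask <- two_cell_mask(60L, 60L, 30L)
  tr <- trace_borders(mask)[[1]]
  seg <- place_line_scans(tr, mask, spacing_px = 15L, length_px = 21L)[[1]]

  ## constant image: ratio 1, normalized profile identically 1
  res <- measure_line_scan(matrix(7, 60, 60), seg)
  expect_equal(res$ratio, 1)
  expect_equal(res$normalized_profile, rep(1, 21))
  ## normalized profile has unit cytoplasmic mean by construction
  expect_equal(mean(res$normalized_profile[seg$cytoplasmic_band]), 1)

  ## enriched border: junctional band sits on the bright stripe
  img <- matrix(10, 60, 60); img[, 29:31] <- 30
  res2 <- measure_line_scan(img, seg)
  expect_equal(res2$ratio, 3, tolerance = 0.05)

  ## scale invariance
  res3 <- measure_line_scan(img * 2, seg)
  expect_equal(res3$ratio, res2$ratio)

  ## zero cytoplasm errors
  expect_error(measure_line_scan(matrix(0, 60, 60), seg), "zero")
})

test_that("line-scan pipeline recovers the generator's enrichment ratio", {
  recover_median_ratio <- function(noise_sd, seed) {
    p <- monolayer_params(image_shape = c(256L, 256L), enrichment_ratio = 3,
                          cytoplasm_mean = 100, noise_sd = noise_sd,
                          border_width_px = 5L, rng_seed = seed)
    out <- generate_monolayer(p)
    ## junctional band narrower than the true stripe width (ground truth)
    bw <- max(1L, (out$truth$stripe_width_px - 2L) %/% 3L)
    ratios <- unlist(lapply(trace_borders(out$mask), function(tr) {
      segs <- place_line_scans(tr, out$mask, spacing_px = 8L,
                               border_width_px = bw)
      vapply(segs, function(s) measure_line_scan(out$image, s)$ratio, 0)
    }))
    expect_gt(length(ratios), 5L)
    median(ratios)
  }
  ## noiseless: exact up to discretization (< 5%)
  expect_equal(recover_median_ratio(0, 11), 3, tolerance = 0.05)
  ## SNR 10 on the cytoplasm level
  expect_equal(recover_median_ratio(10, 12), 3, tolerance = 0.05)
})

test_that("aggregate_ratios reproduces quartiles and group tests", {
  ## single result: median = Q1 = Q3
  one <- aggregate_ratios(2.5, "a")
  expect_equal(one$summary$median, 2.5)
  expect_equal(one$summary$q1, 2.5)
  expect_equal(one$summary$q3, 2.5)

  ## linear-interpolation quartiles on 1..5
  s <- aggregate_ratios(c(1, 2, 3, 4, 5), rep("a", 5))$summary
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$min, 1)
  expect_equal(s$max, 5)

  ## identical groups: rank-sum p = 1
  agg <- aggregate_ratios(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(agg$comparisons$p_value, 1)

  expect_error(aggregate_ratios(numeric(0), character(0)), "group")
})
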