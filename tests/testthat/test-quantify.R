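test_that("z-projection is the per-pixel maximum across planes", {
  one <- const_channel(10)
  expect_identical(project_stack(list(one))$pixels, one$pixels)
  two <- project_stack(list(const_channel(10), const_channel(20)))
  expect_true(all(two$pixels == 20))
  # brute-force per-pixel max oracle on a random 3-plane stack
  set.seed(11)
  planes <- lapply(1:3, function(i)
    mat_channel(matrix(runif(16 * 16, 0, 1000), 16, 16)))
  proj <- project_stack(planes)
  oracle <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16)
    oracle[i, j] <- max(vapply(planes, function(p) p$pixels[i, j],
                               numeric(1)))
  expect_equal(proj$pixels, oracle)
  expect_error(project_stack(list()), "empty")
})

test_that("background correction removes flat fields and ramps, keeps spikes", {
  # constant image maps to zero (up to floating-point roundoff)
  expect_lt(max(correct_background(const_channel(500), 20)$pixels), 1e-6)
  # constant + spike: matches the direct-convolution oracle exactly and
  # retains the spike's prominence
  m <- matrix(100, 40, 40)
  m[20, 20] <- 5000
  img <- mat_channel(m, pixel_size_um = 1)
  out <- correct_background(img, 10)
  oracle <- pmax(m - brute_lowpass(m, 10), 0)
  expect_equal(out$pixels, oracle, tolerance = 1e-12)
  expect_gt(out$pixels[20, 20], 0.95 * (5000 - 100))
  expect_lt(mean(out$pixels[-c(20 * 40 + 20)]), 5)
  expect_lte(mean(out$pixels), mean(img$pixels))
  expect_error(correct_background(img, -1), "> 0")
})

test_that("a ramp no longer biases threshold detection after correction", {
  n <- 128
  ramp <- outer(rep(1, n), seq(0, 4000, length.out = n))
  disc <- disc_matrix(n, 10, value = 20000)
  img <- mat_channel(ramp + disc, pixel_size_um = 1)
  out <- correct_background(img, 40)
  thr <- resolve_threshold(threshold_spec("otsu"), out)
  expect_equal(sum(out$pixels >= thr), sum(disc > 0),
               tolerance = 0.02)
})

test_that("autofluorescence mask thresholds, dilates and subtracts", {
  blank <- const_channel(100, role = "autofluorescence")
  expect_false(any(autofluorescence_mask(blank,
                                         threshold_spec("fixed", 15000))))
  m <- disc_matrix(32, 4, value = 30000) + 100
  af <- mat_channel(m, role = "autofluorescence")
  m0 <- autofluorescence_mask(af, threshold_spec("fixed", 15000), 0)
  m1 <- autofluorescence_mask(af, threshold_spec("fixed", 15000), 1)
  expect_true(all(m0[m == 30100]))
  expect_gte(sum(m1), sum(m0))        # dilation is monotone
  expect_true(all(m1[m0]))
  expect_error(autofluorescence_mask(const_channel(1), threshold_spec("otsu")),
               "autofluorescence")
  expect_error(autofluorescence_mask(af, threshold_spec("fixed", 1e6)),
               "range")
  # subtraction semantics
  sig <- const_channel(1000, n = 32)
  expect_identical(subtract_mask(sig, matrix(FALSE, 32, 32))$pixels,
                   sig$pixels)
  expect_true(all(subtract_mask(sig, matrix(TRUE, 32, 32))$pixels == 0))
  out <- subtract_mask(sig, m1)
  expect_true(all(out$pixels[m1] == 0))
  expect_true(all(out$pixels[!m1] == 1000))
  expect_error(subtract_mask(sig, matrix(TRUE, 4, 4)), "dimensions")
})

test_that("edge enhancement is identity at strength 0 and boosts rims", {
  img <- mat_channel(disc_matrix(64, 12, value = 10000) + 500,
                     pixel_size_um = 1)
  expect_identical(edge_enhance(img, 0)$pixels, img$pixels)
  cst <- const_channel(700)
  expect_equal(edge_enhance(cst, 3)$pixels, cst$pixels, tolerance = 1e-9)
  rim_contrast <- function(strength) {
    out <- edge_enhance(img, strength, edge_sigma_um = 2)$pixels
    d <- sqrt(outer((seq_len(64) - 32.5)^2, (seq_len(64) - 32.5)^2, `+`))
    band <- d >= 10 & d <= 14
    interior <- d < 8
    max(out[band]) - mean(out[interior])
  }
  rc <- vapply(c(0, 1, 2), rim_contrast, numeric(1))
  expect_true(all(diff(rc) > 0))
  expect_error(edge_enhance(img, -0.5), ">= 0")
})

test_that("detection applies size restrictions in physical units", {
  blank <- const_channel(0, n = 32)
  p <- seg_params(signal_threshold = threshold_spec("fixed", 100))
  expect_equal(nrow(detect_objects(blank, p)$objects), 0)
  # 10x10 px square at 0.5 um/px = 25 um^2
  m <- matrix(0, 64, 64); m[20:29, 20:29] <- 1000
  img <- mat_channel(m, pixel_size_um = 0.5)
  p30 <- seg_params(signal_threshold = threshold_spec("fixed", 500),
                    min_area_um2 = 30, edge_strength = 0)
  p20 <- seg_params(signal_threshold = threshold_spec("fixed", 500),
                    min_area_um2 = 20, edge_strength = 0)
  expect_equal(nrow(detect_objects(img, p30)$objects), 0)
  det <- detect_objects(img, p20)
  expect_equal(nrow(det$objects), 1)
  expect_equal(det$objects$area_um2, 25)
  expect_equal(det$objects$centroid_x, 23.5)  # 0-based pixel coords
  expect_equal(det$objects$centroid_y, 23.5)
  expect_equal(det$objects$mean_raw_intensity, 1000)
})

test_that("labeling is 8-connected and raw intensities ignore enhancement", {
  m <- matrix(0, 16, 16)
  m[4, 4] <- 800; m[5, 5] <- 800   # diagonal touch: one object
  img <- mat_channel(m, pixel_size_um = 1)
  p <- seg_params(signal_threshold = threshold_spec("fixed", 500),
                  min_area_um2 = 1, edge_strength = 0)
  expect_equal(nrow(detect_objects(img, p)$objects), 1)
  # enhanced image used for detection, raw image for intensity
  raw <- mat_channel(m / 2, pixel_size_um = 1)
  det <- detect_objects(img, p, raw = raw)
  expect_equal(det$objects$mean_raw_intensity, 400)
})

test_that("roundness separates discs from elongated objects", {
  disc <- mat_channel(disc_matrix(64, 10, 1000), pixel_size_um = 1)
  bar <- matrix(0, 64, 64); bar[31:33, 5:60] <- 1000
  p <- seg_params(signal_threshold = threshold_spec("fixed", 500),
                  min_area_um2 = 1, edge_strength = 0)
  r_disc <- detect_objects(disc, p)$objects$roundness
  r_bar <- detect_objects(mat_channel(bar, pixel_size_um = 1),
                          p)$objects$roundness
  expect_gt(r_disc, 0.9)
  expect_lt(r_bar, 0.5)
  expect_lte(r_disc, 1)
  # a roundness floor drops the bar but keeps the disc
  p_round <- seg_params(signal_threshold = threshold_spec("fixed", 500),
                        min_area_um2 = 1, edge_strength = 0,
                        roundness_range = c(0.6, 1))
  expect_equal(nrow(detect_objects(mat_channel(bar, pixel_size_um = 1),
                                   p_round)$objects), 0)
  expect_equal(nrow(detect_objects(disc, p_round)$objects), 1)
})

test_that("ir-area records match a brute-force summation oracle", {
  expect_equal(measure_ir_area(data.frame(area_um2 = numeric(0)),
                               1000)$ir_area_percent, 0)
  one <- measure_ir_area(data.frame(area_um2 = 50), 1000, "c1", "TeCtx",
                         "ptau")
  expect_equal(one$ir_area_percent, 5)
  set.seed(21)
  areas <- runif(200, 1, 50)
  rec <- measure_ir_area(data.frame(area_um2 = areas), 123456)
  acc <- 0
  for (a in areas) acc <- acc + a
  expect_equal(rec$ir_area_percent, 100 * acc / 123456, tolerance = 1e-9)
  expect_error(measure_ir_area(data.frame(area_um2 = 1), 0), "positive")
})

test_that("the full marker pipeline is deterministic and role-checked", {
  b <- stage_burden_profile("III_IV", tangle = 0.02, thread = 0.01,
                            lipofuscin = 0.01, nucleus = NA)
  sec <- generate_section(quick_params(128L), b, seed = 31)
  r1 <- quantify_marker(sec, seg_params())
  r2 <- quantify_marker(sec, seg_params())
  attr(r1, "objects") <- attr(r1, "labels") <- NULL
  attr(r2, "objects") <- attr(r2, "labels") <- NULL
  expect_identical(r1, r2)
  expect_error(quantify_marker(list(signal = sec$channels$signal),
                               seg_params()),
               "autofluorescence")
  # blank section measures zero
  b0 <- stage_burden_profile("control", tangle = 0, thread = 0,
                             lipofuscin = 0, nucleus = 0)
  sec0 <- generate_section(quick_params(128L), b0, seed = 1)
  expect_equal(quantify_marker(sec0, seg_params())$ir_area_percent, 0)
})

test_that("detected objects never intersect lipofuscin ground truth", {
  b <- stage_burden_profile("V_VI", tangle = 0.03, thread = 0.01,
                            lipofuscin = 0.01, nucleus = NA)
  for (s in 1:3) {
    sec <- generate_section(quick_params(256L), b, seed = s)
    rec <- quantify_marker(sec, seg_params())
    labels <- attr(rec, "labels")
    expect_equal(sum(labels > 0 & sec$ground_truth$masks$lipofuscin), 0)
  }
})

test_that("autofluorescence mask covers the lipofuscin render (Jaccard >= 0.8)", {
  b <- stage_burden_profile("control", lipofuscin = 0.01, nucleus = 0)
  sec <- generate_section(quick_params(256L), b, seed = 17)
  gt <- sec$ground_truth$masks$lipofuscin
  tight <- autofluorescence_mask(sec$channels$autofluorescence,
                                 threshold_spec("fixed", 15000), 0)
  jac <- sum(tight & gt) / sum(tight | gt)
  expect_gte(jac, 0.8)                # threshold alone is a tight match
  dilated <- autofluorescence_mask(sec$channels$autofluorescence,
                                   threshold_spec("fixed", 15000), 1)
  expect_true(all(dilated[gt]))       # dilated mask covers all granules
  expect_true(all(dilated[tight]))
})

test_that("raising threshold or min-area never raises measured area", {
  b <- stage_burden_profile("V_VI", tangle = 0.03, thread = 0.015,
                            lipofuscin = 0.01, nucleus = NA)
  sec <- generate_section(quick_params(256L), b, seed = 23)
  ir <- function(thr, min_area) {
    quantify_marker(sec, seg_params(
      signal_threshold = threshold_spec("fixed", thr),
      min_area_um2 = min_area))$ir_area_percent
  }
  by_thr <- vapply(c(8000, 12000, 16000, 24000), ir, numeric(1),
                   min_area = 5)
  expect_true(all(diff(by_thr) <= 0))
  by_area <- vapply(c(5, 20, 60, 200), function(a) ir(12000, a),
                    numeric(1))
  expect_true(all(diff(by_area) <= 0))
})

test_that("plaque cores are kept and tangles excluded by brightness + size", {
  p <- section_sim_params(image_size_px = c(512L, 512L),
                          tangle_diameter_um = c(12, 20),
                          n_plaques = 5L, n_tangles = 20L, n_threads = 0L,
                          n_lipofuscin = 30L, n_nuclei = 0L)
  b <- stage_burden_profile("V_VI", tangle = NA, thread = 0, plaque = NA,
                            lipofuscin = NA, nucleus = 0)
  sec <- generate_section(p, b, seed = 41)
  expect_equal(nrow(detect_plaque_cores(const_channel(0, role = "thios"))), 0)
  cores <- detect_plaque_cores(sec$channels$thios, plaque_params())
  gt_lab <- tauquant:::label_components_8(sec$ground_truth$masks$plaque)
  expect_equal(nrow(cores), max(gt_lab))
  # no detected core sits on tangle ground truth
  tan <- sec$ground_truth$masks$tangle
  for (i in seq_len(nrow(cores))) {
    cy <- round(cores$centroid_y[i]) + 1L
    cx <- round(cores$centroid_x[i]) + 1L
    expect_false(tan[cy, cx])
  }
  # lowering min_area below the small-object sizes admits more objects
  # (with a permissive threshold so weakly ThioS-positive tangles count)
  counts <- vapply(c(200, 100, 20), function(a) {
    nrow(detect_plaque_cores(sec$channels$thios,
                             plaque_params(min_area_um2 = a,
                                           threshold = threshold_spec("fixed", 7000))))
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})
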