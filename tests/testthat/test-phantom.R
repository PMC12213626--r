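test_that("layer schemas have the required structure", {
  n <- layer_schema("normal")
  d <- layer_schema("degenerative")
  expect_length(n$boundary_names, 9)
  expect_length(n$layer_names, 8)
  expect_length(d$boundary_names, 8)
  expect_length(d$layer_names, 7)
  expect_equal(length(n$layer_names), length(n$boundary_names) - 1)
  expect_equal(length(d$layer_names), length(d$boundary_names) - 1)
})

test_that("make_profile follows the degeneration model", {
  p <- phantom_params()
  m <- degeneration_model()
  prof0 <- make_profile(p, m, 0)
  # baseline reproduces the reference table (ONL via the fitted exponential,
  # so only within the fit residual; other layers exactly)
  expect_equal(unname(prof0$thickness_um["INL"]), 25.76)
  expect_equal(unname(prof0$thickness_um["ONL"]), 63.30, tolerance = 3 / 63.3)
  expect_equal(prof0$schema$name, "normal")
  # closed-form ONL decay
  m2 <- m
  m2$onl_floor_C <- 14; m2$onl_amplitude_A <- 49.3; m2$onl_rate_k <- 0.231
  prof3 <- make_profile(p, m2, 3)
  expect_equal(unname(prof3$thickness_um["ONL"]), 14 + 49.3 * exp(-0.231 * 3),
               tolerance = 1e-12)
  # k = 0: no decay at any day
  m3 <- m
  m3$onl_floor_C <- 0; m3$onl_amplitude_A <- 60; m3$onl_rate_k <- 0
  for (d in c(0, 2, 5)) {
    pr <- make_profile(p, m3, d)
    expect_equal(unname(pr$thickness_um["ONL"]), 60)
  }
  # schema switch at merge_day
  expect_equal(make_profile(p, m, 6)$schema$name, "degenerative")
  expect_true("OR" %in% names(make_profile(p, m, 13)$thickness_um))
  expect_true("IS+OS" %in% names(make_profile(p, m, 3)$thickness_um))
  # unknown override layer errors
  expect_error(make_profile(p, m, 0, overrides = list(BOGUS = 10)),
               "unknown layer")
})

test_that("ground-truth ONL time course reproduces the reference means", {
  p <- phantom_params()
  m <- degeneration_model()
  tab <- si_reference_thickness()
  for (i in seq_len(nrow(tab))) {
    pr <- make_profile(p, m, tab$day[i])
    expect_lt(abs(pr$thickness_um["ONL"] - tab$ONL[i]), 3)
  }
})

test_that("noise-free rendering is exactly geometric within a uniform layer", {
  p <- quiet_params(noise_free = TRUE, background_level = 0,
                    curvature_sag_px = 0, onh_width_px = 0, particle_rate = 0)
  rb <- quick_phantom(0, seed = 1, params = p)
  img <- rb$bscan$pixels
  B <- rb$truth$boundaries
  # rows fully inside the ONL (uniform reflectivity/attenuation band)
  k <- match("ONL/IS+OS", rb$truth$boundary_names)
  top <- ceiling(B[k - 1, 1]) + 3
  bot <- floor(B[k, 1]) - 2
  ratio <- img[(top + 1):bot, 1] / img[top:(bot - 1), 1]
  mu <- unname(rb$truth$layer_attenuation_m1["ONL"])
  expect_equal(ratio, rep(exp(-2 * mu * 1.7e-6), length(ratio)),
               tolerance = 1e-10)
})

test_that("rendered mean intensity matches the reflectivity-attenuation model", {
  # speckle averaged over >= 1e4 pixels agrees with the noise-free image
  p_noisy <- quiet_params(onh_width_px = 0, particle_rate = 0,
                          curvature_sag_px = 0)
  p_clean <- quiet_params(noise_free = TRUE, onh_width_px = 0,
                          particle_rate = 0, curvature_sag_px = 0)
  prof <- make_profile(p_noisy, degeneration_model(), 0)
  noisy <- render_bscan(prof, p_noisy, seed = 11)$bscan$pixels
  clean <- render_bscan(prof, p_clean, seed = 11)$bscan$pixels
  B <- render_bscan(prof, p_clean, seed = 11)$truth$boundaries
  for (lay in c("IPL", "ONL", "choroid")) {
    k <- match(lay, prof$schema$layer_names)
    rows <- (ceiling(B[k, 1]) + 2):(floor(B[k + 1, 1]) - 1)
    expect_gt(length(rows) * 1000, 1e4)
    expect_equal(mean(noisy[rows, ]), mean(clean[rows, ]), tolerance = 0.02)
  }
})

test_that("render contracts: determinism, particle-free vitreous, geometry error", {
  p <- phantom_params()
  m <- degeneration_model()
  prof <- make_profile(p, m, 1)
  a <- render_bscan(prof, p, seed = 99)
  b <- render_bscan(prof, p, seed = 99)
  expect_identical(a$bscan$pixels, b$bscan$pixels)
  expect_identical(a$truth$boundaries, b$truth$boundaries)
  # particle_rate = 0: vitreous contains only background
  p0 <- quiet_params(noise_free = TRUE, particle_rate = 0)
  rb <- quick_phantom(0, seed = 5, params = p0)
  vit_rows <- seq_len(floor(min(rb$truth$boundaries[1, ])) - 1)
  expect_true(all(rb$bscan$pixels[vit_rows, ] == p0$background_level))
  # image too short
  p_short <- phantom_params(image_height_px = 120L)
  expect_error(render_bscan(make_profile(p_short, m, 0), p_short),
               "too short")
})

test_that("phantom truth boundaries are strictly ordered outside the ONH", {
  p <- phantom_params()
  m <- degeneration_model()
  for (day in c(0, 3, 20)) {
    rb <- quick_phantom(day, seed = day + 1, params = p, model = m)
    tru <- as_segmentation(rb$truth)
    d <- diff(rb$truth$boundaries[, tru$valid, drop = FALSE])
    expect_true(all(d > 0))
    # particles lie above the first boundary and within the area range
    pt <- rb$truth$particles
    if (nrow(pt)) {
      expect_true(all(pt$centroid_row <
                        rb$truth$boundaries[1, pt$centroid_col]))
      expect_true(all(pt$area_px >= p$particle_area_px_range[1] &
                        pt$area_px <= p$particle_area_px_range[2]))
    }
  }
})

test_that("simulate_study emits the designed number of images", {
  p <- phantom_params()
  m <- degeneration_model()
  one <- simulate_study(list(n_mice = 1, eyes_per_mouse = 1,
                             bscans_per_eye = 1, timepoints = 0),
                        p, m, seed = 1, keep_images = FALSE)
  expect_length(one$records, 1)
  ss <- simulate_study(list(n_mice = 2, eyes_per_mouse = 2,
                            bscans_per_eye = 2, timepoints = c(0, 6)),
                       p, m, seed = 1, keep_images = FALSE)
  expect_length(ss$records, 2 * 2 * 2 * 2)
  days <- vapply(ss$records, `[[`, 0, "day")
  expect_equal(sum(days == 0), 8)
  # per-eye effects drawn once and held across days
  expect_equal(nrow(ss$eye_effects), 4)
})

test_that("different seeds change speckle but not the stated ground truth", {
  p <- phantom_params()
  m <- degeneration_model(thickness_jitter_sd = 0, loss_noise_um = 0,
                          loss_gamma_um = 0, severity_eac_slope = 0)
  des <- list(n_mice = 1, eyes_per_mouse = 2, bscans_per_eye = 1,
              timepoints = c(0, 3))
  s1 <- simulate_study(des, p, m, seed = 1)
  s2 <- simulate_study(des, p, m, seed = 2)
  expect_false(identical(s1$records[[1]]$bscan$pixels,
                         s2$records[[1]]$bscan$pixels))
  agg <- function(s) aggregate(thickness_um ~ day + layer, s$truth_table, mean)
  expect_equal(agg(s1), agg(s2))
})
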