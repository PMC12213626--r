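# closed-form eAC for a uniform medium sampled at pitch delta:
# I[i] = I0 * r^i with r = exp(-2 mu delta) gives mu_hat = (1-r)/(2 delta r)
geometric_mu_hat <- function(mu, delta_um) {
  r <- exp(-2 * mu * delta_um * 1e-6)
  (1 - r) / (2 * delta_um * 1e-6 * r)
}

geometric_column <- function(mu, delta_um = 1.7, n = 800, i0 = 100) {
  i0 * exp(-2 * mu * delta_um * 1e-6)^(seq_len(n))
}

test_that("linearize handles scales and background", {
  img <- matrix(runif(200, 1, 50), 20, 10)
  bs <- bscan(img)
  # linear input, no background: identity
  expect_equal(linearize(bs)$pixels, img)
  # constant image with its own mean as background -> all zero
  cbs <- bscan(matrix(7, 20, 10))
  expect_true(all(linearize(cbs, background = 7)$pixels == 0))
  # display compression round trip
  lg <- log_compress(bs, a = 55, b = 2)
  back <- log_expand(lg)
  expect_lt(max(abs(back$pixels - img) / img), 1e-6)
  expect_equal(linearize(lg)$pixels, img, tolerance = 1e-9)
  # compressed image without recorded parameters is an error
  lg$log_params <- NULL
  expect_error(linearize(lg), "parameters")
})

test_that("compute_eac matches the geometric-series closed form", {
  mu <- 5000
  img <- matrix(rep(geometric_column(mu), 3), ncol = 3)
  lin <- linearize(bscan(img))
  eac <- compute_eac(lin)
  expected <- geometric_mu_hat(mu, 1.7)
  # the closed form assumes an infinite tail: evaluate at depths that keep
  # >= 300 pixels of remaining tail (truncation term r^300 ~ 1e-3 here)
  vals <- eac$eac[10:400, ]
  expect_true(all(is.finite(vals)))
  expect_lt(max(abs(vals - expected)) / expected, 0.015)
  expect_lt(abs(median(vals) - expected) / expected, 0.001)
  # within 2.5% of the true attenuation (discretization bias only)
  expect_lt(abs(median(vals) - mu) / mu, 0.025)
})

test_that("eAC is exactly scale invariant and masks degenerate tails", {
  img <- matrix(runif(400, 0.1, 10), 40, 10)
  e1 <- compute_eac(linearize(bscan(img)))
  e2 <- compute_eac(linearize(bscan(img * 37.5)))
  expect_equal(e1$eac, e2$eac, tolerance = 1e-12)  # machine precision
  # all-zero A-scan -> fully masked column
  img0 <- img
  img0[, 4] <- 0
  e0 <- compute_eac(linearize(bscan(img0)))
  expect_true(all(is.na(e0$eac[, 4])))
  # single bright pixel at the bottom: everything above it masked except
  # (at most) pixels whose tail is that single value
  one <- matrix(0, 30, 1)
  one[30, 1] <- 5
  eo <- compute_eac(linearize(bscan(one)), tail_floor_frac = 0)
  expect_true(all(is.na(eo$eac[30, 1])))      # no tail below the last pixel
  expect_true(all(eo$eac[1:29, 1] == 0))      # zero intensity above
})

test_that("layer_eac summarizes the uniform phantom correctly", {
  mu <- 5000
  img <- matrix(rep(geometric_column(mu), 40), ncol = 40)
  eac <- compute_eac(linearize(bscan(img)))
  rows <- c(0, 5, 10, 14, 20, 120, 140, 160, 200)  # flat fixture boundaries
  seg <- flat_segmentation(rows, n_ascans = 40)
  roi <- list(side = "left", cols = 3:38)
  le <- layer_eac(eac, seg, "ONL", roi)   # rows 21..120, tails >= 600 px
  expect_gt(le$n_pixels, 1000)
  expect_equal(le$mean_log10_eac, log10(geometric_mu_hat(mu, 1.7)),
               tolerance = 1e-4)
  # empty ROI -> missing value with zero count
  le0 <- layer_eac(eac, seg, "ONL", list(cols = integer(0)))
  expect_true(is.na(le0$mean_log10_eac))
  expect_equal(le0$n_pixels, 0L)
})

test_that("ONL attenuation elevation is visible in eAC at day 1, every seed", {
  p <- quiet_params(particle_rate = 0)
  m <- degeneration_model()
  roi <- list(side = "right", cols = 701:900)
  for (seed in 1:20) {
    prof0 <- make_profile(p, m, 0)
    prof1 <- make_profile(p, m, 1)
    prof1$thickness_um <- prof0$thickness_um  # isolate the optical change
    rb0 <- render_bscan(prof0, p, seed = seed)
    rb1 <- render_bscan(prof1, p, seed = seed + 1000)
    e0 <- layer_eac(compute_eac(linearize(rb0$bscan)),
                    as_segmentation(rb0$truth), "ONL", roi)
    e1 <- layer_eac(compute_eac(linearize(rb1$bscan)),
                    as_segmentation(rb1$truth), "ONL", roi)
    expect_gt(e1$mean_log10_eac, e0$mean_log10_eac)
  }
})

test_that("eAC compensates vessel shadows within 5%", {
  p <- quiet_params(particle_rate = 0, onh_width_px = 0)
  rb <- quick_phantom(0, seed = 4, params = p)
  img <- rb$bscan$pixels
  seg <- as_segmentation(rb$truth)
  # a surface vessel halves all intensity below it over columns 100..180
  shadow_cols <- 100:180
  for (j in shadow_cols) {
    below <- (floor(rb$truth$boundaries[1, j]) + 3):nrow(img)
    img[below, j] <- img[below, j] * 0.5
  }
  eac <- compute_eac(linearize(bscan(img)))
  sh <- layer_eac(eac, seg, "ONL", list(cols = shadow_cols))
  un <- layer_eac(eac, seg, "ONL", list(cols = 300:380))
  expect_lt(abs(sh$mean_log10_eac - un$mean_log10_eac) /
              abs(un$mean_log10_eac), 0.05)
})

test_that("dip_ratio follows its definition", {
  # constant intensity inside IS+OS -> ratio exactly 1
  img <- matrix(50, 200, 12)
  rows <- c(10, 20, 50, 60, 70, 100, 130, 140, 180)
  seg <- flat_segmentation(rows, n_ascans = 12)
  roi <- list(cols = 2:11)
  expect_equal(dip_ratio(linearize(bscan(img)), seg, roi), 1.0)
  # crafted peak 200 / dip 50: IS+OS spans rows 101..130
  img2 <- matrix(80, 200, 12)
  img2[103:106, ] <- 200   # IS peak in the upper half
  img2[118:122, ] <- 50    # hyporeflective dip below the peak
  expect_equal(dip_ratio(linearize(bscan(img2)), seg, roi), 4.0)
  # degenerative schema has no IS+OS -> not applicable
  dseg <- flat_segmentation(c(10, 20, 50, 60, 70, 100, 140, 180),
                            "degenerative", n_ascans = 12)
  expect_error(dip_ratio(linearize(bscan(img)), dseg, roi), "not applicable")
})

test_that("degeneration lowers the Dip ratio (day 3 vs baseline)", {
  p <- quiet_params(particle_rate = 0)
  m <- degeneration_model()
  roi <- list(cols = 701:900)
  worse <- 0
  for (seed in 1:10) {
    prof0 <- make_profile(p, m, 0)
    prof3 <- make_profile(p, m, 3)
    prof3$thickness_um <- prof0$thickness_um  # same geometry, dip filled in
    rb0 <- render_bscan(prof0, p, seed = seed)
    rb3 <- render_bscan(prof3, p, seed = seed + 500)
    d0 <- dip_ratio(linearize(rb0$bscan), as_segmentation(rb0$truth), roi)
    d3 <- dip_ratio(linearize(rb3$bscan), as_segmentation(rb3$truth), roi)
    expect_lt(d3, d0)
  }
})
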