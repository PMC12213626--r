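test_that("boundary cost maps respect polarity", {
  # hard dark->bright transition between rows 12 and 13
  img <- rbind(matrix(0, 12, 8), matrix(100, 10, 8))
  cm <- boundary_cost(img, "dark-to-bright", smoothing_sigma = 0)
  expect_equal(unname(apply(cm$cost, 2, which.min)), rep(12, 8))
  expect_true(all(cm$cost >= 0 & cm$cost <= 1))
  # inverted polarity: no matching edge anywhere -> uniform high cost
  cm_inv <- boundary_cost(img, "bright-to-dark", smoothing_sigma = 0)
  expect_true(all(cm_inv$cost == 1))
  # smoothing does not move the per-column cost minimum off the step
  cm_s <- boundary_cost(img, "dark-to-bright", smoothing_sigma = 2)
  expect_equal(unname(apply(cm_s$cost, 2, which.min)), rep(12, 8))
  # constant image: uniform cost, no error
  expect_true(all(boundary_cost(matrix(5, 10, 4))$cost == 1))
})

test_that("shortest-path DP is exact on crafted grids", {
  # zero-cost row is followed exactly
  cost <- matrix(1, 20, 15)
  cost[12, ] <- 0
  expect_equal(shortest_path_boundary(cost, max_step = 1), rep(12L, 15))
  # the 3x3 grid with the documented optimum (rows 1,2,1; cost 3)
  g3 <- rbind(c(1, 9, 1), c(9, 1, 9), c(1, 9, 1))
  path <- shortest_path_boundary(g3, max_step = 1)
  expect_equal(path, c(1L, 2L, 1L))
  expect_equal(sum(g3[cbind(path, 1:3)]),
               enumerate_min_cost(g3, 1, 3, 1))
  # max_step = 0 reduces to the best single row
  g <- matrix(runif(50), 5, 10)
  p0 <- shortest_path_boundary(g, max_step = 0)
  expect_equal(unique(p0), unname(which.min(rowSums(g))))
  # infeasible band
  expect_error(shortest_path_boundary(g, row_band = c(4, 2)), "infeasible")
})

test_that("DP ties break toward the smaller row", {
  cost <- matrix(1, 6, 4)
  cost[2, ] <- 0
  cost[5, ] <- 0   # equal-cost alternative deeper down
  expect_equal(shortest_path_boundary(cost, max_step = 1), rep(2L, 4))
})

test_that("DP equals exhaustive enumeration on random small grids", {
  set.seed(401)
  for (i in 1:40) {
    nr <- sample(2:6, 1)
    nc <- sample(2:5, 1)
    ms <- sample(0:2, 1)
    cost <- matrix(round(runif(nr * nc), 3), nr, nc)
    path <- shortest_path_boundary(cost, max_step = ms)
    expect_equal(sum(cost[cbind(path, seq_len(nc))]),
                 enumerate_min_cost(cost, 1, nr, ms))
    expect_true(all(abs(diff(path)) <= ms))
  }
})

test_that("noise-free phantoms are segmented to sub-pixel accuracy", {
  p <- quiet_params(noise_free = TRUE, particle_rate = 0)
  rb <- quick_phantom(0, seed = 2, params = p)
  for (v in default_variants()) {
    seg <- segment_bscan(rb$bscan, "normal", v)
    err <- boundary_errors(seg, rb$truth)
    rms <- sqrt(rowMeans(err^2))
    expect_true(all(rms < 0.5), info = v$name)
  }
})

test_that("degenerative schema segmentation returns 8 boundaries", {
  p <- phantom_params()
  rb <- quick_phantom(13, seed = 3, params = p)
  seg <- segment_bscan(rb$bscan, "degenerative")
  expect_equal(nrow(seg$boundaries), 8)
  expect_equal(seg$schema$name, "degenerative")
  # ordering invariant at valid A-scans
  expect_true(all(diff(seg$boundaries[, seg$valid]) > 0))
})

test_that("degenerate images raise a segmentation failure", {
  zero <- bscan(matrix(0, 80, 60))
  expect_error(segment_bscan(zero, "normal"), "segmentation failure")
  flat <- bscan(matrix(7, 80, 60))
  expect_error(segment_bscan(flat, "normal"), "segmentation failure")
  noise <- bscan(matrix(rgamma(80 * 300, 40, 40), 80, 300))
  expect_error(segment_bscan(noise, "normal"), "segmentation failure")
})

test_that("ensemble median follows the per-A-scan median contract", {
  mk <- function(b1) {
    rows <- c(b1, 20, 50, 60, 70, 100, 110, 120, 160)
    flat_segmentation(rows, n_ascans = 6)
  }
  e3 <- ensemble_median(list(mk(10), mk(12), mk(14)))
  expect_equal(unname(e3$boundaries[1, ]), rep(12, 6))
  # idempotence
  same <- ensemble_median(list(mk(10), mk(10), mk(10)))
  expect_equal(same$boundaries, mk(10)$boundaries, ignore_attr = TRUE)
  # even count: mean of the central pair
  e2 <- ensemble_median(list(mk(10), mk(20)))
  expect_equal(unname(e2$boundaries[1, ]), rep(15, 6))
  # valid mask is ANDed
  a <- mk(10); a$valid[2] <- FALSE
  b <- mk(12)
  expect_equal(ensemble_median(list(a, b))$valid,
               c(TRUE, FALSE, rep(TRUE, 4)))
  # mixed schemas rejected
  d <- flat_segmentation(c(10, 20, 50, 60, 70, 100, 110, 160),
                         "degenerative", n_ascans = 6)
  expect_error(ensemble_median(list(mk(10), d)), "mixed")
})

test_that("dice_score matches hand counts and conventions", {
  rows_a <- c(0, 5, 10, 14, 20, 30, 40, 50, 60)   # NFL = rows 1..5 etc.
  a <- flat_segmentation(rows_a, n_ascans = 1)
  expect_equal(dice_score(a, a, "INL", 100), 1.0)
  # INL in a: (10,14] -> 4 px; in b: (11,17] -> 6 px; overlap 12..14 -> 3
  rows_b <- c(0, 5, 11, 17, 20, 30, 40, 50, 60)
  b <- flat_segmentation(rows_b, n_ascans = 1)
  expect_equal(dice_score(a, b, "INL", 100), 2 * 3 / (4 + 6))
  # disjoint masks
  rows_c <- c(0, 5, 30, 34, 40, 50, 60, 70, 80)
  cc <- flat_segmentation(rows_c, n_ascans = 1)
  expect_equal(dice_score(a, cc, "INL", 100), 0)
})

test_that("usage_rate counts selections", {
  expect_equal(unname(usage_rate(rep(c("X", "Y"), c(7, 21)),
                                 c("X", "Y"))["X"]), 0.25)
  expect_equal(unname(usage_rate(rep("A", 5), c("A", "B"))), c(1, 0))
  r <- usage_rate(c("A", "A", "B", "C"), c("A", "B", "C"))
  expect_equal(unname(r), c(0.5, 0.25, 0.25))
  expect_equal(sum(r), 1)
  expect_error(usage_rate(character(0), "A"), "empty")
  expect_error(usage_rate("Z", c("A", "B")), "unknown")
})

test_that("median ensemble shrugs off one corrupted variant", {
  p <- phantom_params()
  rb <- quick_phantom(0, seed = 8, params = p)
  segs <- lapply(default_variants(), function(v)
    segment_bscan(rb$bscan, "normal", v))
  segs[[2]]$boundaries <- segs[[2]]$boundaries + 10  # corrupt one model
  ens <- ensemble_median(segs)
  rms_of <- function(s) sqrt(mean(boundary_errors(s, rb$truth)^2))
  variant_rms <- sort(vapply(segs, rms_of, numeric(1)))
  # "no worse than" up to sub-pixel numerical ties (the +10 px corruption is
  # two orders of magnitude above this slack)
  expect_lte(rms_of(ens), median(variant_rms[1:3]) + 0.02)
})

test_that("boundary recovery under default noise stays within tolerance", {
  # mean absolute error <= 1 px per boundary (choroid/sclera <= 2 px),
  # ensemble segmentation over 20 seeds
  p <- phantom_params()
  m <- degeneration_model()
  err_sum <- NULL
  n <- 0
  for (seed in 1:20) {
    day <- c(0, 1, 3, 6, 13, 20)[(seed %% 6) + 1]
    rb <- quick_phantom(day, seed = seed, params = p, model = m)
    seg <- ensemble_median(lapply(default_variants(), function(v)
      segment_bscan(rb$bscan, rb$truth$schema_name, v)))
    err <- abs(boundary_errors(seg, rb$truth))
    key <- rb$truth$schema_name
    mae <- rowMeans(err)
    names(mae) <- rb$truth$boundary_names
    lim <- ifelse(names(mae) == "choroid/sclera", 2.0, 1.0)
    expect_true(all(mae <= lim),
                info = paste("seed", seed, "day", day, ":",
                             paste(round(mae, 2), collapse = " ")))
  }
})
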