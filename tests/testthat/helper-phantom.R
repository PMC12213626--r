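# shared fixtures: all phantoms are generated in code at test time

# default-geometry phantom parameters, optionally noise-free
quiet_params <- function(noise_free = FALSE, ...) {
  args <- list(...)
  if (noise_free) args$speckle_n_avg <- 0
  do.call(phantom_params, args)
}

# one rendered phantom at a given day (Table-driven model)
quick_phantom <- function(day = 0, seed = 1, params = phantom_params(),
                          model = degeneration_model(), overrides = NULL) {
  render_bscan(make_profile(params, model, day, overrides), params,
               seed = seed)
}

# boundary errors (ensemble or single segmentation vs generator truth),
# restricted to jointly valid A-scans
boundary_errors <- function(seg, truth) {
  tru <- as_segmentation(truth)
  ok <- seg$valid & tru$valid
  seg$boundaries[, ok, drop = FALSE] - tru$boundaries[, ok, drop = FALSE]
}

# exhaustive shortest-path oracle: enumerate every feasible path
# (row per column, |drow| <= max_step) and return the minimal total cost
enumerate_min_cost <- function(cost, rmin, rmax, max_step) {
  nr <- rmax - rmin + 1
  nc <- ncol(cost)
  combos <- as.matrix(expand.grid(rep(list(seq_len(nr)), nc)))
  if (nc > 1) {
    steps <- abs(combos[, -1, drop = FALSE] - combos[, -nc, drop = FALSE])
    combos <- combos[apply(steps <= max_step, 1, all), , drop = FALSE]
  }
  idx <- cbind(as.vector(combos + rmin - 1L), rep(seq_len(nc),
                                                  each = nrow(combos)))
  totals <- rowSums(matrix(cost[idx], nrow(combos), nc))
  min(totals)
}

# brute-force connected-component oracle: iterative label propagation
brute_label <- function(mask, connectivity = 8) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  nbr <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
      if (!mask[i, j]) next
      for (d in seq_len(nrow(nbr))) {
        ni <- i + nbr[d, 1]; nj <- j + nbr[d, 2]
        if (ni < 1 || ni > nrow(mask) || nj < 1 || nj > ncol(mask)) next
        if (mask[ni, nj] && lab[ni, nj] < lab[i, j]) {
          lab[i, j] <- lab[ni, nj]; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

# flat-boundary segmentation fixture (n columns, boundaries in 0-based rows)
flat_segmentation <- function(rows, schema_name = "normal", n_ascans = 10,
                              valid = rep(TRUE, n_ascans)) {
  sch <- layer_schema(schema_name)
  stopifnot(length(rows) == length(sch$boundary_names))
  B <- matrix(rep(rows, n_ascans), length(rows), n_ascans)
  retoct:::new_segmentation(sch, B, valid, "fixture")
}
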