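#' Study run configuration
#'
#' A serializable container for everything a reproducible study run needs:
#' study design, phantom parameter overrides, degeneration-model overrides,
#' segmenter variant table, statistics options and the master seed.  Stored
#' as plain values so the object round-trips losslessly through JSON.
#'
#' @param design list: n_mice, eyes_per_mouse, bscans_per_eye, timepoints.
#' @param seed master RNG seed (integer).
#' @param phantom named list of \code{\link{phantom_params}} overrides.
#' @param model named list of \code{\link{degeneration_model}} overrides
#'   (scalar/vector arguments only).
#' @param variants data.frame with columns name, smoothing_sigma, max_step,
#'   grad_power; defaults to \code{\link{default_variants}}.
#' @param n_boot bootstrap resamples for correlation CIs.
#' @param measures measurements besides thickness to compute per image.
#' @return a \code{run_config}.
#' @export
run_config <- function(design = list(n_mice = 7, eyes_per_mouse = 2,
                                     bscans_per_eye = 4,
                                     timepoints = c(0, 1, 3, 6, 13, 20)),
                       seed = 1, phantom = list(), model = list(),
                       variants = NULL, n_boot = 2000,
                       measures = c("eac", "dip", "particles")) {
  if (is.null(variants)) {
    vs <- default_variants()
    variants <- data.frame(
      name = vapply(vs, `[[`, "", "name"),
      smoothing_sigma = vapply(vs, `[[`, 0, "smoothing_sigma"),
      max_step = vapply(vs, `[[`, 0, "max_step"),
      grad_power = vapply(vs, `[[`, 0, "grad_power"))
  }
  structure(list(design = design, seed = seed, phantom = phantom,
                 model = model, variants = variants, n_boot = n_boot,
                 measures = measures), class = "run_config")
}

#' @rdname run_config
#' @param config a \code{run_config}.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$design <- as.list(obj$design)
  obj$phantom <- as.list(obj$phantom)
  obj$model <- as.list(obj$model)
  structure(obj, class = "run_config")
}

config_variants <- function(config) {
  v <- config$variants
  lapply(seq_len(nrow(v)), function(i)
    segmenter_variant(v$smoothing_sigma[i], v$max_step[i], v$grad_power[i],
                      v$name[i]))
}

#' Analyze one B-scan end to end
#'
#' Segments with every variant, forms the median ensemble, places the two
#' ROIs relative to the detected ONH, and measures per-ROI layer thickness,
#' layer eAC (ONL plus RPE or OR), Dip ratio (normal schema only) and the
#' vitreous particle count.  The "best fit" model selection of an
#' interactive review is emulated by choosing the variant closest (boundary
#' RMS over valid A-scans) to the ensemble.
#'
#' @param bs a \code{bscan}.
#' @param schema_name "normal" or "degenerative".
#' @param variants list of \code{\link{segmenter_variant}}s.
#' @param measures which measurements to compute (thickness is always
#'   computed; dropping unused ones saves time in large simulations).
#' @return list: \code{seg} (ensemble segmentation), \code{rois},
#'   \code{thickness} (data.frame roi_side/layer/value), \code{eac}
#'   (data.frame or NULL), \code{dip} (data.frame or NULL), \code{particles}
#'   (count or NA), \code{selection} (chosen variant name).
#' @export
analyze_bscan <- function(bs, schema_name, variants = default_variants(),
                          measures = c("eac", "dip", "particles")) {
  # particle-robust surface estimate shared by all variants
  pri <- boundary_priors(layer_schema(schema_name))
  min_below <- sum(vapply(pri$gaps_um,
                          function(gg) floor(gg[1] / bs$axial_pitch_um), 0))
  hint <- find_surface(bs$pixels,
                       max(4L, as.integer(nrow(bs$pixels) - min_below)))
  segs <- lapply(variants, function(v)
    segment_bscan(bs, schema_name, v, surface_hint = hint))
  ens <- ensemble_median(segs)
  onh <- locate_onh(ens)
  rois <- select_rois(onh, bs$lateral_pitch_um, ncol(bs$pixels))
  want_eac <- "eac" %in% measures
  want_dip <- "dip" %in% measures && schema_name == "normal"
  want_part <- "particles" %in% measures
  lin <- if (want_eac || want_dip)
    linearize(bs, vitreous_pixel_mask(bs, ens)) else NULL
  eacimg <- if (want_eac) compute_eac(lin) else NULL
  eac_layers <- if (schema_name == "normal") c("ONL", "RPE") else c("ONL", "OR")
  th_rows <- list()
  eac_rows <- list()
  dip_rows <- list()
  for (side in c("left", "right")) {
    roi <- rois[[side]]
    th <- layer_thickness(ens, roi, bs$axial_pitch_um)
    th_rows[[side]] <- data.frame(roi_side = side, layer = names(th),
                                  value = unname(th), row.names = NULL)
    if (want_eac) {
      for (l in eac_layers) {
        le <- layer_eac(eacimg, ens, l, roi)
        eac_rows[[paste(side, l)]] <- data.frame(
          roi_side = side, layer = l, value = le$mean_log10_eac,
          n_pixels = le$n_pixels)
      }
    }
    if (want_dip)
      dip_rows[[side]] <- data.frame(roi_side = side, layer = "IS+OS",
                                     value = dip_ratio(lin, ens, roi))
  }
  particles <- NA_integer_
  if (want_part) {
    # particle count with a threshold from particle-free vitreous statistics
    vpix <- bs$pixels[vitreous_pixel_mask(bs, ens)]
    thr_keep <- vpix[vpix <= median(vpix) + 6 * mad(vpix)]
    pset <- count_particles(vitreous_mask(bs, ens),
                            background_stats = list(mean = mean(thr_keep),
                                                    sd = sd(thr_keep)))
    particles <- pset$count
  }
  rms <- vapply(segs, function(s)
    sqrt(mean((s$boundaries[, ens$valid] - ens$boundaries[, ens$valid])^2)),
    numeric(1))
  list(seg = ens, rois = rois,
       thickness = do.call(rbind, th_rows),
       eac = if (length(eac_rows)) do.call(rbind, eac_rows) else NULL,
       dip = if (length(dip_rows)) do.call(rbind, dip_rows) else NULL,
       particles = particles,
       selection = variants[[which.min(rms)]]$name)
}

#' Run a full simulated study
#'
#' Orchestrates phantom generation, segmentation (all variants plus median
#' ensemble), reflectance/morphometry/vitreous measurement and eye-level
#' aggregation into a long-format study table, plus summary statistics:
#' per-day thickness summary, ONL exponential decay fit, day-1 ONL eAC vs
#' final ONL loss correlation, and paired t-tests against baseline.  Fully
#' seeded; the same config yields byte-identical tables.  Per-image failures
#' are recorded and the run continues.
#'
#' @param config a \code{\link{run_config}}.
#' @param progress print progress lines.
#' @return a \code{study_result}: \code{$table} (StudyTable), \code{$summary}
#'   (per day/layer mean, sd, n), \code{$decay_fit}, \code{$correlation},
#'   \code{$ttests}, \code{$usage}, \code{$failures}, \code{$config}.
#' @export
run_study <- function(config = run_config(), progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  params <- do.call(phantom_params, config$phantom)
  model <- do.call(degeneration_model, config$model)
  variants <- config_variants(config)
  design <- config$design
  rows <- list()
  selections <- character(0)
  failures <- list()
  idx <- 0L
  for (m in seq_len(design$n_mice)) {
    for (e in seq_len(design$eyes_per_mouse)) {
      eye_id <- (m - 1L) * design$eyes_per_mouse + e
      eff <- draw_eye_effect(m, e, eye_id, model, config$seed)
      for (day in design$timepoints) {
        prof <- make_profile(params, eff$model, day)
        jl <- intersect(names(eff$jitter), names(prof$thickness_um))
        prof$thickness_um[jl] <- prof$thickness_um[jl] * eff$jitter[jl]
        th_acc <- list()
        eac_acc <- list()
        dip_acc <- list()
        pc_acc <- numeric(0)
        for (s in seq_len(design$bscans_per_eye)) {
          idx <- idx + 1L
          res <- tryCatch({
            rb <- render_bscan(prof, params, seed = derive_seed(config$seed, idx))
            analyze_bscan(rb$bscan, prof$schema$name, variants,
                          measures = config$measures)
          }, error = function(err) err)
          if (inherits(res, "error")) {
            failures[[length(failures) + 1L]] <- data.frame(
              mouse = m, eye = e, day = day, bscan = s,
              message = conditionMessage(res))
            next
          }
          th_acc[[s]] <- res$thickness
          if (!is.null(res$eac)) eac_acc[[s]] <- res$eac
          if (!is.null(res$dip)) dip_acc[[s]] <- res$dip
          if (!is.na(res$particles)) pc_acc <- c(pc_acc, res$particles)
          selections <- c(selections, res$selection)
        }
        if (!length(th_acc)) next
        # the >= 4 ROI rule applies at the full 4-B-scan design; scaled-down
        # designs require proportionally fewer
        agg <- aggregate_eye(do.call(rbind, th_acc),
                             min_rois = min(4, 2 * design$bscans_per_eye))
        rows[[length(rows) + 1L]] <- data.frame(
          mouse = m, eye = e, day = day, layer = agg$layer,
          metric = "thickness_um", value = agg$mean, n = agg$n_rois)
        if (length(eac_acc)) {
          eacdf <- do.call(rbind, eac_acc)
          for (l in unique(eacdf$layer)) {
            v <- eacdf$value[eacdf$layer == l]
            rows[[length(rows) + 1L]] <- data.frame(
              mouse = m, eye = e, day = day, layer = l, metric = "log10_eac",
              value = mean(v, na.rm = TRUE), n = sum(!is.na(v)))
          }
        }
        if (length(dip_acc)) {
          dv <- do.call(rbind, dip_acc)$value
          rows[[length(rows) + 1L]] <- data.frame(
            mouse = m, eye = e, day = day, layer = "IS+OS",
            metric = "dip_ratio", value = mean(dv, na.rm = TRUE),
            n = sum(!is.na(dv)))
        }
        if (length(pc_acc))
          rows[[length(rows) + 1L]] <- data.frame(
            mouse = m, eye = e, day = day, layer = "vitreous",
            metric = "particle_count", value = mean(pc_acc),
            n = length(pc_acc))
        if (progress)
          message(sprintf("mouse %d eye %d day %g done", m, e, day))
      }
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 summary = summarize_thickness(tab),
                 decay_fit = study_decay_fit(tab),
                 correlation = study_eac_correlation(tab, config$n_boot,
                                                     config$seed),
                 ttests = study_ttests(tab),
                 usage = if (length(selections))
                   usage_rate(selections,
                              vapply(variants, `[[`, "", "name")) else NULL,
                 failures = if (length(failures)) do.call(rbind, failures)
                 else NULL,
                 config = config), class = "study_result")
}

#' Per-day thickness summary (published-table shape)
#'
#' Mean, SD and eye count per day and layer from a long-format study table.
#'
#' @param tab StudyTable data.frame.
#' @param metric metric to summarize.
#' @return data.frame day, layer, mean, sd, n_eyes.
#' @export
summarize_thickness <- function(tab, metric = "thickness_um") {
  d <- tab[tab$metric == metric & !is.na(tab$value), ]
  if (!nrow(d)) return(NULL)
  sp <- split(d, list(d$day, d$layer), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g) data.frame(
    day = g$day[1], layer = g$layer[1], mean = mean(g$value),
    sd = if (nrow(g) > 1) sd(g$value) else NA_real_, n_eyes = nrow(g))))
  rownames(out) <- NULL
  out[order(out$day, out$layer), ]
}

# group-mean ONL decay fit across days (needs >= 4 timepoints)
study_decay_fit <- function(tab) {
  s <- summarize_thickness(tab)
  if (is.null(s)) return(NULL)
  s <- s[s$layer == "ONL", ]
  if (nrow(s) < 4 || length(unique(s$day)) < 3) return(NULL)
  fit_exp_decay(s$day, s$mean)
}

# day-1 ONL eAC vs final (last-day) ONL loss, per eye
study_eac_correlation <- function(tab, n_boot = 2000, seed = 1) {
  days <- sort(unique(tab$day))
  last <- max(days)
  if (!(1 %in% days) || !(0 %in% days) || last <= 1) return(NULL)
  key <- function(d) paste(d$mouse, d$eye)
  eac1 <- tab[tab$day == 1 & tab$metric == "log10_eac" & tab$layer == "ONL", ]
  th0 <- tab[tab$day == 0 & tab$metric == "thickness_um" & tab$layer == "ONL", ]
  thl <- tab[tab$day == last & tab$metric == "thickness_um" & tab$layer == "ONL", ]
  k <- intersect(intersect(key(eac1), key(th0)), key(thl))
  if (length(k) < 3) return(NULL)
  x <- eac1$value[match(k, key(eac1))]
  y <- th0$value[match(k, key(th0))] - thl$value[match(k, key(thl))]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) return(NULL)
  linfit_r2(x[ok], y[ok], n_boot = n_boot, seed = seed)
}

# paired t-tests of each layer/metric vs baseline, per post-injection day
study_ttests <- function(tab) {
  days <- setdiff(sort(unique(tab$day)), 0)
  if (!length(days) || !(0 %in% tab$day)) return(NULL)
  out <- list()
  key <- function(d) paste(d$mouse, d$eye)
  for (metric in unique(tab$metric)) {
    for (layer in unique(tab$layer[tab$metric == metric])) {
      base <- tab[tab$day == 0 & tab$metric == metric & tab$layer == layer, ]
      if (!nrow(base)) next
      for (day in days) {
        cur <- tab[tab$day == day & tab$metric == metric & tab$layer == layer, ]
        k <- intersect(key(base), key(cur))
        if (length(k) < 2) next
        b <- base$value[match(k, key(base))]
        a <- cur$value[match(k, key(cur))]
        ok <- is.finite(a) & is.finite(b)
        if (sum(ok) < 2) next
        tt <- paired_t(b[ok], a[ok])
        out[[length(out) + 1L]] <- data.frame(
          metric = metric, layer = layer, day = day, n = sum(ok),
          t_stat = tt$t_stat, df = tt$df, p = tt$p_two_sided, flag = tt$flag)
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d table rows, %d eyes x %d timepoints\n",
              nrow(x$table),
              x$config$design$n_mice * x$config$design$eyes_per_mouse,
              length(x$config$design$timepoints)))
  if (!is.null(x$decay_fit)) print(x$decay_fit)
  if (!is.null(x$failures))
    cat("  ", nrow(x$failures), "image(s) failed\n")
  invisible(x)
}
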