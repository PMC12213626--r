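#' Published group-mean retinal layer thicknesses for the SI time course
#'
#' Group-mean layer thicknesses (micrometers) of sodium-iodate treated mouse
#' retina at baseline and 1, 3, 6, 13 and 20 days post injection, as used to
#' parameterize the phantom generator: inner layers swell transiently
#' (peaking around day 3), the ONL decays roughly exponentially, and the
#' outer retina (OR = IS+OS plus RPE) thins.  OR is reported at all days;
#' IS+OS and RPE exist separately only while unmerged (days < 6).
#'
#' @return data.frame with columns \code{day, NFL, IPL, INL, OPL, ONL, OR}.
#' @export
si_reference_thickness <- function() {
  data.frame(
    day = c(0, 1, 3, 6, 13, 20),
    NFL = c(14.63, 15.77, 16.21, 16.08, 15.01, 15.06),
    IPL = c(51.25, 52.62, 50.22, 47.53, 43.89, 43.19),
    INL = c(25.76, 27.54, 33.35, 32.72, 24.99, 22.52),
    OPL = c(15.99, 16.67, 21.67, 17.27, 15.44, 13.94),
    ONL = c(63.30, 53.63, 38.08, 31.60, 22.07, 16.81),
    OR  = c(57.83, 47.56, 46.86, 27.32, 16.36, 13.07)
  )
}

#' Phantom geometry, optics and noise parameters
#'
#' Parameters of the synthetic B-scan generator.  Geometry follows the
#' acquisition protocol being emulated: 1.7 um per pixel axially and a
#' 1.4 mm lateral field sampled by 1000 A-scans (1.4 um per A-scan).
#' Reflectivities are linear-scale backscatter amplitudes (arbitrary
#' units); attenuation coefficients are in 1/m.  Speckle is fully
#' developed (exponential) multiplicative noise; averaging of
#' \code{speckle_n_avg} repeated frames (default 40, matching the
#' acquisition protocol) is emulated by a single Gamma(n, n) multiplier.
#' \code{speckle_n_avg = 0} disables noise entirely.
#'
#' @param axial_pitch_um micrometers per pixel, axial (depth) direction.
#' @param lateral_pitch_um micrometers per A-scan.
#' @param image_height_px image height in pixels.
#' @param n_ascans number of A-scans (image width).
#' @param layer_reflectivity named vector of per-layer mean linear
#'   backscatter; must cover both schemas plus "vitreous" and "sclera".
#' @param layer_attenuation_m1 named vector of per-layer attenuation (1/m).
#' @param isos_profile reflectivity of the IS peak, the hyporeflective dip
#'   between IS and OS, and the OS band (inner structure of the IS+OS
#'   layer), plus their depth fractions.
#' @param background_level additive noise floor (linear units).
#' @param speckle_n_avg number of averaged speckle frames (0 = noise-free).
#' @param top_offset_px depth of the vitreoretinal boundary at image center.
#' @param curvature_sag_px parabolic sag of the retina across the field.
#' @param onh_center_col,onh_width_px optic-nerve-head gap position and
#'   width (columns); width 0 disables the ONH.
#' @param particle_rate expected number of vitreous particles (Poisson).
#'   NULL (default) follows the degeneration model's per-day series; a
#'   number overrides it at every day (0 disables particles).
#' @param particle_area_px_range min/max particle area in pixels.
#' @param particle_reflectivity linear intensity of particle pixels.
#' @return A \code{phantom_params} object (list).
#' @export
phantom_params <- function(axial_pitch_um = 1.7,
                           lateral_pitch_um = 1.4,
                           image_height_px = 360L,
                           n_ascans = 1000L,
                           layer_reflectivity = c(
                             vitreous = 0, NFL = 80, IPL = 55, INL = 25,
                             OPL = 60, ONL = 20, `IS+OS` = 85, RPE = 150,
                             OR = 110, choroid = 45, sclera = 22),
                           layer_attenuation_m1 = c(
                             vitreous = 0, NFL = 2000, IPL = 1500, INL = 800,
                             OPL = 1500, ONL = 600, `IS+OS` = 2500,
                             RPE = 4500, OR = 3000, choroid = 2500,
                             sclera = 1500),
                           isos_profile = list(refl = c(peak = 95, dip = 35,
                                                        os = 75),
                                               fractions = c(0.35, 0.30, 0.35)),
                           background_level = 3,
                           speckle_n_avg = 40,
                           top_offset_px = 50,
                           curvature_sag_px = 12,
                           onh_center_col = NULL,
                           onh_width_px = 90L,
                           particle_rate = NULL,
                           particle_area_px_range = c(8, 60),
                           particle_reflectivity = 160) {
  if (axial_pitch_um <= 0 || lateral_pitch_um <= 0)
    stop("pixel pitches must be > 0")
  if (is.null(onh_center_col)) onh_center_col <- round(n_ascans / 2)
  if (onh_center_col < 1 || onh_center_col > n_ascans)
    stop("onh_center_col outside the image")
  if (any(layer_attenuation_m1 < 0)) stop("attenuation must be >= 0")
  if (particle_area_px_range[1] > particle_area_px_range[2])
    stop("invalid particle_area_px_range")
  structure(list(
    axial_pitch_um = axial_pitch_um, lateral_pitch_um = lateral_pitch_um,
    image_height_px = as.integer(image_height_px),
    n_ascans = as.integer(n_ascans),
    layer_reflectivity = layer_reflectivity,
    layer_attenuation_m1 = layer_attenuation_m1,
    isos_profile = isos_profile,
    background_level = background_level, speckle_n_avg = speckle_n_avg,
    top_offset_px = top_offset_px, curvature_sag_px = curvature_sag_px,
    onh_center_col = onh_center_col, onh_width_px = as.integer(onh_width_px),
    particle_rate = particle_rate,
    particle_area_px_range = particle_area_px_range,
    particle_reflectivity = particle_reflectivity), class = "phantom_params")
}

#' Longitudinal degeneration model driving the phantom
#'
#' Encodes the ground-truth time course: ONL thickness follows
#' \code{T(t) = C + A * exp(-k t)} with \code{(C, A, k)} obtained by least
#' squares from the reference thickness table (so the generated truth
#' reproduces the published means within 3 um at every captured timepoint);
#' the other retinal layers are piecewise-linear through the table; the RPE
#' swells by \code{rpe_swelling_um} at early post-injection days; IS+OS and
#' RPE merge into a single OR band at \code{merge_day}; the choroid thins
#' monotonically; vitreous particle load peaks at day 1 and returns to
#' baseline by day 13.
#'
#' Per-eye severity coupling: a latent standard-normal severity \code{z}
#' (drawn once per eye by \code{\link{simulate_study}}) raises the ONL
#' attenuation at day >= 1 by \code{severity_eac_slope * z} above the mean
#' elevation \code{eac_onl_elevation}, and shifts the final ONL loss by
#' \code{loss_gamma_um * z} plus independent noise of SD
#' \code{loss_noise_um}.  With equal gamma and noise SD the designed
#' truth-level R-squared between day-1 ONL attenuation and day-20 ONL loss
#' is 0.5.
#'
#' @param thickness_table reference thickness table
#'   (default \code{\link{si_reference_thickness}()}).
#' @param rpe_baseline_um baseline RPE thickness.
#' @param rpe_swelling_um added RPE thickness at days in [1, merge_day).
#' @param merge_day first day at which IS+OS and RPE are merged (OR schema).
#' @param choroid_series_um named choroid thickness by day.
#' @param particle_series expected vitreous particle count by day.
#' @param dip_series reflectivity of the IS/OS dip by day (rises with
#'   degeneration, lowering the Dip ratio).
#' @param eac_onl_elevation mean multiplier on ONL attenuation at day >= 1.
#' @param rpe_eac_factor multiplier on RPE attenuation at day >= 1
#'   (reflectance loss of injured RPE).
#' @param severity_eac_slope,loss_gamma_um,loss_noise_um severity coupling
#'   (see Details).
#' @param thickness_jitter_sd SD of the per-eye multiplicative thickness
#'   jitter (layers other than ONL).
#' @return A \code{degeneration_model} object.
#' @export
degeneration_model <- function(thickness_table = si_reference_thickness(),
                               rpe_baseline_um = 10,
                               rpe_swelling_um = 0.5,
                               merge_day = 6,
                               choroid_series_um = c(`0` = 88.6, `1` = 83,
                                                     `3` = 77, `6` = 71,
                                                     `13` = 65, `20` = 61),
                               particle_series = c(`0` = 3, `1` = 40, `3` = 28,
                                                   `6` = 16, `13` = 3.5,
                                                   `20` = 3),
                               dip_series = c(`0` = 35, `1` = 38, `3` = 55,
                                              `6` = 55, `13` = 55, `20` = 55),
                               eac_onl_elevation = 1.2,
                               rpe_eac_factor = 0.8,
                               severity_eac_slope = 0.15,
                               loss_gamma_um = 6,
                               loss_noise_um = 6,
                               thickness_jitter_sd = 0.02) {
  stopifnot(is.data.frame(thickness_table),
            all(c("day", "NFL", "IPL", "INL", "OPL", "ONL", "OR") %in%
                  names(thickness_table)))
  if (!merge_day %in% thickness_table$day)
    stop("merge_day must be one of the captured timepoints")
  ch <- unname(choroid_series_um)
  if (any(diff(ch) > 1e-9))
    stop("choroid series must be non-increasing after baseline")
  fit <- fit_exp_decay(thickness_table$day, thickness_table$ONL)
  structure(list(
    thickness_table = thickness_table,
    onl_floor_C = fit$floor_C, onl_amplitude_A = fit$amplitude_A,
    onl_rate_k = fit$rate_k,
    rpe_baseline_um = rpe_baseline_um, rpe_swelling_um = rpe_swelling_um,
    merge_day = merge_day,
    choroid_series_um = choroid_series_um,
    particle_series = particle_series,
    dip_series = dip_series,
    eac_onl_elevation = eac_onl_elevation,
    rpe_eac_factor = rpe_eac_factor,
    severity_eac_slope = severity_eac_slope,
    loss_gamma_um = loss_gamma_um, loss_noise_um = loss_noise_um,
    thickness_jitter_sd = thickness_jitter_sd), class = "degeneration_model")
}

# linear interpolation of a day-indexed named series, constant beyond ends
interp_series <- function(series, day) {
  d <- as.numeric(names(series))
  stats::approx(d, unname(series), xout = day, rule = 2)$y
}

#' Per-layer thickness/optics profile for a given post-injection day
#'
#' Evaluates the degeneration model at \code{day}: picks the schema (normal
#' before \code{merge_day}, degenerative from it on), interpolates layer
#' thicknesses, evaluates the ONL exponential decay, and assembles per-layer
#' reflectivity and attenuation (ONL attenuation elevated and RPE
#' attenuation reduced at day >= 1).
#'
#' @param params \code{\link{phantom_params}}.
#' @param model \code{\link{degeneration_model}}.
#' @param day days post injection (>= 0).
#' @param overrides optional named list of thickness overrides (um); names
#'   must be layers of the day's schema.
#' @return A \code{layer_profile}: schema, named thickness/reflectivity/
#'   attenuation vectors, IS+OS inner profile, particle rate.
#' @export
make_profile <- function(params, model, day, overrides = NULL) {
  stopifnot(inherits(params, "phantom_params"),
            inherits(model, "degeneration_model"), day >= 0)
  schema <- schema_for_day(day, model$merge_day)
  tab <- model$thickness_table
  itp <- function(col) stats::approx(tab$day, tab[[col]], xout = day,
                                     rule = 2)$y
  onl <- model$onl_floor_C + model$onl_amplitude_A * exp(-model$onl_rate_k * day)
  rpe <- model$rpe_baseline_um +
    if (day >= 1 && day < model$merge_day) model$rpe_swelling_um else 0
  th <- c(NFL = itp("NFL"), IPL = itp("IPL"), INL = itp("INL"),
          OPL = itp("OPL"), ONL = onl)
  if (schema$name == "normal") {
    th <- c(th, `IS+OS` = itp("OR") - rpe, RPE = rpe)
  } else {
    th <- c(th, OR = itp("OR"))
  }
  th <- c(th, choroid = interp_series(model$choroid_series_um, day))
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(th))
    if (length(bad))
      stop("unknown layer in thickness overrides: ",
           paste(bad, collapse = ", "))
    th[names(overrides)] <- unlist(overrides)
  }
  if (any(th <= 0)) stop("layer thicknesses must be > 0")
  refl <- params$layer_reflectivity[schema$layer_names]
  mu <- params$layer_attenuation_m1[schema$layer_names]
  if (anyNA(refl) || anyNA(mu))
    stop("reflectivity/attenuation missing for some schema layers")
  if (day >= 1) {
    # reflectance change = scattering change: backscatter and attenuation
    # move together (this is what the eAC estimator is sensitive to)
    mu["ONL"] <- mu["ONL"] * model$eac_onl_elevation
    refl["ONL"] <- refl["ONL"] * model$eac_onl_elevation
    if ("RPE" %in% names(mu)) {
      mu["RPE"] <- mu["RPE"] * model$rpe_eac_factor
      refl["RPE"] <- refl["RPE"] * model$rpe_eac_factor
    }
  }
  isos <- params$isos_profile
  isos$refl["dip"] <- interp_series(model$dip_series, day)
  rate <- if (!is.null(params$particle_rate)) params$particle_rate else
    interp_series(model$particle_series, day)
  structure(list(day = day, schema = schema, thickness_um = th,
                 reflectivity = refl, attenuation_m1 = mu,
                 isos_profile = isos, particle_rate = rate),
            class = "layer_profile")
}

# per-column ground-truth boundaries (0-based rows), n_boundaries x n_ascans
truth_boundaries <- function(profile, params) {
  nb <- length(profile$schema$boundary_names)
  nc <- params$n_ascans
  x <- seq_len(nc)
  ctr <- (nc + 1) / 2
  b0 <- params$top_offset_px +
    params$curvature_sag_px * ((x - ctr) / (nc / 2))^2
  th_px <- profile$thickness_um / params$axial_pitch_um
  B <- matrix(0, nb, nc)
  B[1, ] <- b0
  for (k in seq_along(th_px)) B[k + 1, ] <- B[k, ] + th_px[k]
  # ONH: retinal boundaries converge onto the retina/choroid boundary in a
  # wedge around onh_center_col; choroid boundaries are unaffected
  if (params$onh_width_px > 0) {
    half <- params$onh_width_px / 2
    inonh <- abs(x - params$onh_center_col) < half
    if (any(inonh)) {
      f <- abs(x[inonh] - params$onh_center_col) / half
      base <- B[nb - 1, inonh]
      for (k in seq_len(nb - 2))
        B[k, inonh] <- base - (base - B[k, inonh]) * f
    }
  }
  B
}

#' Render a synthetic B-scan from a layer profile
#'
#' Produces a linear-intensity B-scan whose expected value in layer L at
#' depth z is \code{reflectivity_L * exp(-2 * mu_cum(z))} plus an additive
#' background, with Gamma multiplicative speckle on both terms (see
#' \code{\link{phantom_params}}).  Ground truth (sub-pixel boundaries,
#' per-layer attenuation, particle list) is returned alongside.
#'
#' @param profile from \code{\link{make_profile}}.
#' @param params \code{\link{phantom_params}}.
#' @param seed optional RNG seed for reproducible rendering.
#' @return list with elements \code{bscan} (a \code{\link{bscan}}) and
#'   \code{truth} (a \code{phantom_truth}).
#' @export
render_bscan <- function(profile, params, seed = NULL) {
  stopifnot(inherits(profile, "layer_profile"),
            inherits(params, "phantom_params"))
  if (!is.null(seed)) set.seed(seed)
  nr <- params$image_height_px
  nc <- params$n_ascans
  B <- truth_boundaries(profile, params)
  if (max(B) > nr - 8)
    stop("image too short for the requested layers (need > ",
         ceiling(max(B)) + 8, " rows)")
  # expand schema layers into render bands (IS+OS gets inner structure);
  # band boundary stack: image top, b1..b_nb, image bottom
  layers <- profile$schema$layer_names
  stack <- list(rep(0, nc))
  band_refl <- c(params$layer_reflectivity["vitreous"])
  band_mu <- c(params$layer_attenuation_m1["vitreous"])
  for (k in seq_along(layers)) {
    lay <- layers[k]
    t_k <- B[k, ]; b_k <- B[k + 1, ]
    if (lay == "IS+OS") {
      fr <- params$isos_profile$fractions
      rp <- profile$isos_profile$refl
      mu_l <- profile$attenuation_m1[lay]
      stack <- c(stack, list(t_k, t_k + fr[1] * (b_k - t_k),
                             t_k + (fr[1] + fr[2]) * (b_k - t_k)))
      band_refl <- c(band_refl, rp["peak"], rp["dip"], rp["os"])
      band_mu <- c(band_mu, mu_l, mu_l, mu_l)
    } else {
      stack <- c(stack, list(t_k))
      band_refl <- c(band_refl, profile$reflectivity[lay])
      band_mu <- c(band_mu, profile$attenuation_m1[lay])
    }
  }
  stack <- c(stack, list(B[nrow(B), ]))
  band_refl <- c(band_refl, params$layer_reflectivity["sclera"])
  band_mu <- c(band_mu, params$layer_attenuation_m1["sclera"])
  bounds <- do.call(rbind, c(stack, list(rep(nr, nc))))
  signal <- .render_layers(bounds, unname(band_refl), unname(band_mu),
                           nr, params$axial_pitch_um)
  # vitreous particles: hyper-reflective blobs above the first boundary,
  # laterally concentrated near the ONH
  particles <- data.frame(centroid_row = numeric(0), centroid_col = numeric(0),
                          area_px = integer(0))
  n_part <- if (profile$particle_rate > 0) rpois(1, profile$particle_rate) else 0L
  if (n_part > 0) {
    # placement uses the wedge-free surface so particles never end up in the
    # ONH pit; placements overlapping an earlier particle are re-drawn so
    # that components never merge (truth count == countable blobs)
    x <- seq_len(nc)
    ctr <- (nc + 1) / 2
    b0_flat <- params$top_offset_px +
      params$curvature_sag_px * ((x - ctr) / (nc / 2))^2
    placed <- matrix(numeric(0), 0, 3)  # row, col, radius
    for (i in seq_len(n_part)) {
      for (try in 1:20) {
        col <- round(rnorm(1, params$onh_center_col, 0.12 * nc))
        col <- min(max(col, 5), nc - 4)
        area <- round(runif(1, params$particle_area_px_range[1] + 2,
                            params$particle_area_px_range[2] - 8))
        r <- sqrt(area / pi)
        rmax <- floor(b0_flat[col]) - ceiling(r) - 4
        rmin <- ceiling(r) + 3
        if (rmax <= rmin) break
        row <- round(runif(1, rmin, rmax))
        clear <- !nrow(placed) ||
          all(sqrt((placed[, 1] - row)^2 + (placed[, 2] - col)^2) >
                placed[, 3] + r + 3)
        if (clear) {
          dd <- ceiling(r)
          off <- expand.grid(dr = -dd:dd, dc = -dd:dd)
          off <- off[off$dr^2 + off$dc^2 <= r^2, , drop = FALSE]
          pr <- row + off$dr
          pc <- col + off$dc
          ok <- pr >= 1 & pr <= nr & pc >= 1 & pc <= nc
          signal[cbind(pr[ok], pc[ok])] <-
            signal[cbind(pr[ok], pc[ok])] + params$particle_reflectivity
          placed <- rbind(placed, c(row, col, r))
          particles <- rbind(particles,
                             data.frame(centroid_row = row,
                                        centroid_col = col,
                                        area_px = sum(ok)))
          break
        }
      }
    }
  }
  n_avg <- params$speckle_n_avg
  if (is.finite(n_avg) && n_avg > 0) {
    g1 <- matrix(rgamma(nr * nc, shape = n_avg, rate = n_avg), nr, nc)
    g2 <- matrix(rgamma(nr * nc, shape = n_avg, rate = n_avg), nr, nc)
    img <- signal * g1 + params$background_level * g2
  } else {
    img <- signal + params$background_level
  }
  truth <- structure(list(
    schema_name = profile$schema$name,
    boundaries = B,
    boundary_names = profile$schema$boundary_names,
    layer_names = profile$schema$layer_names,
    thickness_um = profile$thickness_um,
    layer_attenuation_m1 = profile$attenuation_m1,
    particles = particles,
    onh_center_col = if (params$onh_width_px > 0) params$onh_center_col else NA,
    onh_width_px = params$onh_width_px,
    day = profile$day), class = "phantom_truth")
  list(bscan = bscan(img, axial_pitch_um = params$axial_pitch_um,
                     lateral_pitch_um = params$lateral_pitch_um),
       truth = truth)
}

#' Convert phantom ground truth to a Segmentation
#'
#' Useful as an oracle segmentation: boundaries are the generator's
#' sub-pixel truth; columns inside the ONH wedge are marked invalid.
#'
#' @param truth a \code{phantom_truth}.
#' @return a \code{segmentation} object with \code{source_model = "truth"}.
#' @export
as_segmentation <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  nc <- ncol(truth$boundaries)
  valid <- rep(TRUE, nc)
  if (!is.na(truth$onh_center_col) && truth$onh_width_px > 0) {
    x <- seq_len(nc)
    valid[abs(x - truth$onh_center_col) < truth$onh_width_px / 2] <- FALSE
  }
  new_segmentation(layer_schema(truth$schema_name), truth$boundaries,
                   valid, "truth")
}

# per-eye random effects: thickness jitter plus a latent severity z that
# couples day-1 ONL attenuation elevation to day-20 ONL loss (shared-cause
# design; truth-level R^2 = gamma^2 / (gamma^2 + noise^2))
draw_eye_effect <- function(m, e, eye_id, model, seed) {
  set.seed(derive_seed(seed, 1000000L + eye_id))
  z <- rnorm(1)
  eps <- rnorm(1)
  jit <- 1 + rnorm(5, 0, model$thickness_jitter_sd)
  names(jit) <- c("NFL", "IPL", "INL", "OPL", "choroid")
  eac_elev <- model$eac_onl_elevation + model$severity_eac_slope * z
  k <- model$onl_rate_k
  t0 <- model$onl_floor_C + model$onl_amplitude_A  # baseline ONL
  l0 <- model$onl_amplitude_A * (1 - exp(-20 * k)) # mean day-20 loss
  loss <- l0 + model$loss_gamma_um * z + model$loss_noise_um * eps
  loss <- min(max(loss, 0.3 * t0), 0.95 * t0)
  c_i <- t0 - loss / (1 - exp(-20 * k))
  model_i <- model
  model_i$onl_floor_C <- c_i
  model_i$onl_amplitude_A <- t0 - c_i
  model_i$eac_onl_elevation <- eac_elev
  list(model = model_i, jitter = jit,
       row = data.frame(mouse = m, eye = e, severity_z = z,
                        eac_elevation = eac_elev, design_loss_um = loss,
                        onl_floor_C = c_i, onl_amplitude_A = t0 - c_i))
}

# deterministic sub-seed derivation (stays below 2^31)
derive_seed <- function(seed, idx) {
  as.integer((as.numeric(seed %% 100000L) * 20011 + as.numeric(idx) * 7919) %%
               2147483629) + 1L
}

#' Simulate a longitudinal phantom study
#'
#' Generates B-scans and ground truth for a full study design.  Per-eye
#' random effects (small multiplicative thickness jitter, a latent severity
#' that couples day-1 ONL attenuation elevation to day-20 ONL loss) are
#' drawn once per eye and held across days, so longitudinal correlation
#' structure exists in the truth.
#'
#' @param design list with \code{n_mice}, \code{eyes_per_mouse},
#'   \code{bscans_per_eye}, \code{timepoints} (days).
#' @param params \code{\link{phantom_params}}.
#' @param model \code{\link{degeneration_model}}.
#' @param seed integer master seed.
#' @param keep_images keep rendered B-scans in the result (memory permitting);
#'   if FALSE only ground truth and metadata are kept.
#' @return A \code{study_set}: \code{$records} (one element per image with
#'   mouse/eye/day/scan, truth, and optionally the bscan), \code{$eye_effects}
#'   (per-eye latent draws), \code{$truth_table} (long-format ground-truth
#'   thicknesses), and \code{$design}.
#' @export
simulate_study <- function(design, params = phantom_params(),
                           model = degeneration_model(), seed = 1,
                           keep_images = TRUE) {
  stopifnot(design$n_mice >= 1, design$eyes_per_mouse >= 1,
            design$bscans_per_eye >= 1, length(design$timepoints) >= 1)
  records <- list()
  truth_rows <- list()
  eff_rows <- list()
  idx <- 0L
  for (m in seq_len(design$n_mice)) {
    for (e in seq_len(design$eyes_per_mouse)) {
      eye_id <- (m - 1L) * design$eyes_per_mouse + e
      eff <- draw_eye_effect(m, e, eye_id, model, seed)
      model_i <- eff$model
      jit <- eff$jitter
      eff_rows[[eye_id]] <- eff$row
      for (day in design$timepoints) {
        prof <- make_profile(params, model_i, day)
        jl <- intersect(names(jit), names(prof$thickness_um))
        prof$thickness_um[jl] <- prof$thickness_um[jl] * jit[jl]
        for (s in seq_len(design$bscans_per_eye)) {
          idx <- idx + 1L
          rb <- render_bscan(prof, params, seed = derive_seed(seed, idx))
          rec <- list(mouse = m, eye = e, day = day, bscan_index = s,
                      truth = rb$truth)
          if (keep_images) rec$bscan <- rb$bscan
          records[[idx]] <- rec
          truth_rows[[idx]] <- data.frame(
            mouse = m, eye = e, day = day, bscan = s,
            layer = names(rb$truth$thickness_um),
            thickness_um = unname(rb$truth$thickness_um),
            row.names = NULL)
        }
      }
    }
  }
  structure(list(design = design, records = records,
                 eye_effects = do.call(rbind, eff_rows),
                 truth_table = do.call(rbind, truth_rows)),
            class = "study_set")
}
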