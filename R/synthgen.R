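#' Arterial input function specification
#'
#' A gamma-variate bolus `A * (t - t0)^alpha * exp(-(t - t0) / beta)`
#' (normalised so that `amplitude` is the peak activity) with an optional
#' recirculation shoulder: after the bolus peak, a fraction of the peak
#' activity rises with time constant `recirc_tau` towards a plateau,
#' emulating the persistent blood-pool signal of a freely diffusible tracer.
#' The defaults place the peak at `t0 + alpha * beta` = 26 s, within the
#' first minute as arterial curves from a central-aorta VOI show.
#'
#' @param amplitude peak activity, Bq/mL (0 yields an identically zero
#'   curve).
#' @param onset bolus arrival time t0, seconds.
#' @param shape gamma shape alpha (> 0).
#' @param scale gamma scale beta, seconds (> 0).
#' @param recirc_fraction plateau height of the recirculation shoulder as a
#'   fraction of the peak (0 disables it).
#' @param recirc_tau recirculation time constant, seconds.
#' @return A list of class `aif_spec`.
#' @export
aif_spec <- function(amplitude = 45000, onset = 8, shape = 3, scale = 6,
                     recirc_fraction = 0.12, recirc_tau = 60) {
  if (amplitude < 0 || shape <= 0 || scale <= 0 || onset < 0)
    stop("amplitude must be >= 0, shape and scale positive, onset >= 0")
  if (recirc_fraction < 0 || recirc_tau <= 0)
    stop("invalid recirculation shoulder")
  structure(list(amplitude = amplitude, onset = onset, shape = shape,
                 scale = scale, recirc_fraction = recirc_fraction,
                 recirc_tau = recirc_tau),
            class = "aif_spec")
}

# gamma-variate evaluated at arbitrary (possibly fractional) times
eval_aif <- function(spec, t) {
  s <- pmax(t - spec$onset, 0)
  g <- ifelse(s > 0, s^spec$shape * exp(-s / spec$scale), 0)
  peak <- (spec$shape * spec$scale)^spec$shape * exp(-spec$shape)
  main <- spec$amplitude * g / peak
  if (spec$recirc_fraction > 0) {
    t_peak <- spec$onset + spec$shape * spec$scale
    sh <- spec$recirc_fraction * spec$amplitude *
      (1 - exp(-pmax(t - t_peak, 0) / spec$recirc_tau))
    main <- main + sh
  }
  main
}

#' Generate an arterial input function on the 1-s grid
#'
#' @param spec an [aif_spec()].
#' @param t_max final second; default 280.
#' @return A [sampled_curve()] labelled `"aorta"`.
#' @export
generate_aif <- function(spec, t_max = 280L) {
  stopifnot(inherits(spec, "aif_spec"))
  sampled_curve(eval_aif(spec, seq_len(t_max)), "aorta")
}

#' Synthetic subject specification
#'
#' Ground truth for one simulated patient: the arterial input, the true
#' liver model parameters, the dispersion compartment generating the
#' measured portal-vein curve, the spleen's one-tissue parameters, the frame
#' noise model, and the seed. Defaults put the liver at the cohort-mean
#' operating point of the measured-portal-input model (f_A = 0.299,
#' f_P = 0.930 mL/min/mL, k = 1.603 /min, V_B = 0.095, delays 18 and 23 s),
#' the portal dispersion at rate 1.2 /min with a 2 s arrival delay, and the
#' spleen at f = 1, k = 1.1 /min, V_B = 0.1, delay 22 s.
#'
#' Frame noise is multiplicative Gaussian scaled by frame duration:
#' `value * (1 + fraction * z / sqrt(duration / 5 s))` with z standard
#' normal, so longer frames are less noisy, a simple stand-in for count
#' statistics.
#'
#' @param aif an [aif_spec()].
#' @param params true liver parameters (any `hbf_params` model).
#' @param pv_rate,pv_delay dispersion rate (mL/min/mL) and integer delay (s)
#'   of the compartment generating the portal-vein curve.
#' @param spleen_params a [params_1tcm()] for the spleen.
#' @param noise_fraction multiplicative noise fraction at the 5-s reference
#'   frame duration (0 = noise-free).
#' @param noise_frame_scaling scale noise by `1/sqrt(duration/5)`.
#' @param seed integer master seed for the subject's noise stream.
#' @param schedule acquisition [frame_schedule()].
#' @return A list of class `subject_spec`.
#' @export
subject_spec <- function(aif = aif_spec(),
                         params = params_new_dual_input(
                           f_A = 0.299, f_P = 0.930, k = 1.603,
                           V_B = 0.095, dt1 = 18L, dt2 = 23L),
                         pv_rate = 1.2, pv_delay = 2L,
                         spleen_params = params_1tcm(
                           f = 1.0, k = 1.1, V_B = 0.1, dt1 = 22L),
                         noise_fraction = 0.05,
                         noise_frame_scaling = TRUE,
                         seed = 1L,
                         schedule = default_frame_schedule()) {
  stopifnot(inherits(aif, "aif_spec"), inherits(params, "hbf_params"),
            inherits(spleen_params, "params_1tcm"),
            inherits(schedule, "frame_schedule"))
  if (noise_fraction < 0) stop("noise_fraction must be >= 0")
  structure(list(aif = aif, params = params,
                 pv_rate = check_pos(pv_rate, "pv_rate"),
                 pv_delay = check_delay(pv_delay, "pv_delay"),
                 spleen_params = spleen_params,
                 noise_fraction = noise_fraction,
                 noise_frame_scaling = isTRUE(noise_frame_scaling),
                 seed = as.integer(seed), schedule = schedule),
            class = "subject_spec")
}

#' Generate a synthetic subject
#'
#' Builds the clean 1-s curves (aorta; portal vein via the dispersion
#' compartment; liver tissue and liver PET via the spec's model and its
#' blood-volume mixing; spleen via its one-tissue model), frame-averages
#' them onto the schedule, and applies the frame noise under the spec's
#' seed. Regenerating from the same spec reproduces the noisy TACs
#' bit-identically.
#'
#' For the notional-portal models (`taniguchi`, `rijzewijk`) the exported
#' portal-vein TAC is the model's own dispersed compartment; for the
#' measured-portal-input model it is the curve generated from
#' `pv_rate`/`pv_delay`, which also drives the liver.
#'
#' @param spec a [subject_spec()].
#' @param t_max grid length in seconds.
#' @return A list of class `synthetic_subject` with elements `spec`,
#'   `curves` (clean [sampled_curve()]s: `aorta`, `pv`, `tissue`, `pet`,
#'   `spleen`), `clean_tacs` and `tacs` (named lists of [frame_tac()]s:
#'   `aorta`, `portal_vein`, `liver`, `spleen`).
#' @export
generate_subject <- function(spec, t_max = 280L) {
  stopifnot(inherits(spec, "subject_spec"))
  aorta <- generate_aif(spec$aif, t_max)
  pv <- simulate_pv_compartment(spec$pv_rate, spec$pv_delay, aorta)
  sim <- model_pet_curve(spec$params, aorta, pv)
  pv_out <- if (!is.null(sim$pv)) sim$pv else pv
  spleen_sim <- model_pet_curve(spec$spleen_params, aorta)

  clean <- list(
    aorta = frame_average(aorta, spec$schedule),
    portal_vein = frame_average(
      sampled_curve(pv_out$values, "portal_vein"), spec$schedule),
    liver = frame_average(
      sampled_curve(sim$pet$values, "liver"), spec$schedule),
    spleen = frame_average(
      sampled_curve(spleen_sim$pet$values, "spleen"), spec$schedule))

  dur <- frame_durations(spec$schedule)
  scale <- if (spec$noise_frame_scaling) 1 / sqrt(dur / 5) else rep(1, length(dur))
  noisy <- withr::with_seed(spec$seed, {
    lapply(clean, function(tac) {
      z <- stats::rnorm(length(tac$values))
      frame_tac(tac$schedule,
                tac$values * (1 + spec$noise_fraction * scale * z),
                tac$label, allow_negative = TRUE)
    })
  })

  structure(list(spec = spec,
                 curves = list(aorta = aorta,
                               pv = sampled_curve(pv_out$values,
                                                  "portal_vein"),
                               tissue = sim$tissue, pet = sim$pet,
                               spleen = sampled_curve(spleen_sim$pet$values,
                                                      "spleen")),
                 clean_tacs = clean, tacs = noisy),
            class = "synthetic_subject")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("<synthetic_subject: model '%s', noise %.1f%%, seed %d>\n",
              x$spec$params$model, 100 * x$spec$noise_fraction, x$spec$seed))
  invisible(x)
}

#' Phantom layout
#'
#' Places four non-overlapping boxes (aorta, portal vein, liver, spleen) in
#' a small voxel grid. The portal-vein box can carry a cold rim (its
#' single-voxel outer shell at reduced intensity) emulating partial-volume
#' dilution around a thin vessel, and an optional spurious disjoint blob for
#' exercising the largest-component filter.
#'
#' @param dim grid size in voxels.
#' @param voxel_size voxel edge lengths, mm.
#' @param pv_rim_intensity rim intensity as a fraction of the true value
#'   (NULL disables the rim).
#' @param voxel_noise per-voxel multiplicative Gaussian noise fraction.
#' @param spurious_pv add a small disjoint portal-vein blob.
#' @return A list of class `phantom_layout` with per-VOI box index ranges.
#' @export
phantom_layout <- function(dim = c(40L, 40L, 20L), voxel_size = c(4, 4, 4),
                           pv_rim_intensity = 0.5, voxel_noise = 0.02,
                           spurious_pv = FALSE) {
  boxes <- list(
    aorta = list(x = 3:8, y = 3:8, z = 5:12),
    # 6x6x6: the one-voxel shell is 152/216 = 70% of the box
    portal_vein = list(x = 14:19, y = 3:8, z = 6:11),
    liver = list(x = 12:30, y = 14:32, z = 4:16),
    spleen = list(x = 33:38, y = 3:10, z = 5:12))
  lay <- structure(list(dim = as.integer(dim), voxel_size = voxel_size,
                        boxes = boxes, pv_rim_intensity = pv_rim_intensity,
                        voxel_noise = voxel_noise,
                        spurious_pv = isTRUE(spurious_pv)),
                   class = "phantom_layout")
  validate_layout(lay)
  lay
}

validate_layout <- function(lay) {
  occ <- array(0L, lay$dim)
  for (b in lay$boxes) {
    if (max(b$x) > lay$dim[1] || max(b$y) > lay$dim[2] ||
        max(b$z) > lay$dim[3] || min(unlist(b)) < 1)
      stop("box outside the grid")
    occ[b$x, b$y, b$z] <- occ[b$x, b$y, b$z] + 1L
  }
  if (any(occ > 1L)) stop("overlapping boxes in the phantom layout")
  invisible(lay)
}

box_mask <- function(b, dims) {
  m <- array(FALSE, dims)
  m[b$x, b$y, b$z] <- TRUE
  m
}

# one-voxel outer shell of a box
box_rim <- function(b, dims) {
  outer <- box_mask(b, dims)
  inner <- array(FALSE, dims)
  if (length(b$x) > 2 && length(b$y) > 2 && length(b$z) > 2)
    inner[b$x[-c(1, length(b$x))], b$y[-c(1, length(b$y))],
          b$z[-c(1, length(b$z))]] <- TRUE
  outer & !inner
}

#' Generate a 4D phantom image and its masks
#'
#' Fills each VOI box with that VOI's clean per-frame value, applies
#' per-voxel multiplicative noise, scales the portal-vein rim down by
#' `pv_rim_intensity`, and returns the 4D PET array, the per-VOI masks and
#' the geometry. With the rim present, the upper-percentile portal TAC is
#' demonstrably closer to the true portal curve than the plain mean.
#'
#' @param subject a [generate_subject()] result.
#' @param layout a [phantom_layout()].
#' @return A list with `pet` (4D array), `masks` (named [voi_mask()] list),
#'   `geometry`, and `schedule`.
#' @export
generate_phantom_image <- function(subject, layout = phantom_layout()) {
  stopifnot(inherits(subject, "synthetic_subject"),
            inherits(layout, "phantom_layout"))
  validate_layout(layout)
  sched <- subject$spec$schedule
  nf <- n_frames(sched)
  dims <- layout$dim
  geom <- image_geometry(dims, layout$voxel_size)
  pet <- array(0, c(dims, nf))
  masks <- list()
  nvox3 <- prod(dims)

  withr::with_seed(subject$spec$seed + 1L, {
    for (lab in names(layout$boxes)) {
      b <- layout$boxes[[lab]]
      m <- box_mask(b, dims)
      idx <- which(m)
      vals <- subject$clean_tacs[[lab]]$values
      rim_scale <- rep(1, length(idx))
      if (lab == "portal_vein" && !is.null(layout$pv_rim_intensity)) {
        rim <- box_rim(b, dims)
        rim_scale[rim[idx]] <- layout$pv_rim_intensity
      }
      for (fr in seq_len(nf)) {
        noise <- 1 + layout$voxel_noise * stats::rnorm(length(idx))
        pet[(fr - 1L) * nvox3 + idx] <- vals[fr] * rim_scale * noise
      }
      masks[[lab]] <- m
    }
    if (layout$spurious_pv) {
      spur <- list(x = 25:27, y = 3:5, z = 2:4)
      sm <- box_mask(spur, dims)
      sidx <- which(sm)
      for (fr in seq_len(nf))
        pet[(fr - 1L) * nvox3 + sidx] <-
          subject$clean_tacs$portal_vein$values[fr] * 0.2 *
          (1 + layout$voxel_noise * stats::rnorm(length(sidx)))
      masks$portal_vein <- masks$portal_vein | sm
    }
  })
  masks <- lapply(stats::setNames(names(masks), names(masks)), function(lab)
    voi_mask(masks[[lab]], geom, lab))
  list(pet = pet, masks = masks, geometry = geom, schedule = sched)
}

#' Generate a synthetic cohort
#'
#' Draws `n` subjects whose true continuous parameters are jittered around a
#' base specification's values (log-normal jitter with the given coefficient
#' of variation), with fresh per-subject seeds derived from the master seed.
#'
#' @param n number of subjects.
#' @param seed master seed.
#' @param base a [subject_spec()] providing the central parameters.
#' @param cv coefficient of variation of the log-normal parameter jitter
#'   (0 = all subjects identical up to noise realisation).
#' @return A list of [subject_spec()] objects.
#' @export
cohort_specs <- function(n, seed = 1L, base = subject_spec(), cv = 0.3) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      p <- base$params
      jit <- function(x) x * exp(stats::rnorm(1, 0, cv))
      p2 <- switch(p$model,
        "new_dual_input" = params_new_dual_input(
          jit(p$f_A), jit(p$f_P), jit(p$k),
          min(max(jit(p$V_B), 0.01), 0.5), p$dt1, p$dt2),
        "1tcm" = params_1tcm(jit(p$f), jit(p$k),
                             min(max(jit(p$V_B), 0.01), 0.5), p$dt1),
        stop("cohort_specs supports 1tcm and new_dual_input bases"))
      spec <- base
      spec$params <- p2
      spec$seed <- as.integer(seed + i)
      spec
    })
  })
}
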