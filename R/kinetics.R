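#' Kinetic model parameter sets
#'
#' Constructors for the parameter vectors of the four liver models. Flows
#' (`f`, `f_A`, `f_P`, `f_p`) are in mL/min/mL, the washout constant `k` in
#' /min, the blood volume fraction `V_B` and the portosystemic shunting
#' fraction `E` are unitless in \[0, 1\], and the delays `dt1`, `dt2` are
#' integer seconds in \[0, 65\].
#'
#' Model identities:
#' \describe{
#'   \item{`1tcm`}{one-tissue compartment model with a single arterial input,
#'     delayed by `dt1`.}
#'   \item{`taniguchi`}{dual-input model whose portal input is a notional
#'     dispersed compartment driven by the delayed aorta curve; the liver
#'     receives the doubly delayed artery and the `dt2`-delayed portal
#'     compartment; `dt1` is calibrated on the spleen.}
#'   \item{`rijzewijk`}{the same dual-input structure but with an undelayed
#'     arterial term and a single fitted delay `dt1` on the portal
#'     compartment's input.}
#'   \item{`new_dual_input`}{dual-input model whose portal input is a
#'     measured image-derived curve; one differential equation with two
#'     delayed inputs.}
#' }
#'
#' @param f,f_A,f_P,f_p flow rate constants, mL/min/mL.
#' @param k washout rate constant, /min.
#' @param E portosystemic shunting fraction in \[0, 1\].
#' @param V_B blood volume fraction in \[0, 1\].
#' @param dt1,dt2 integer delays, seconds, in \[0, 65\].
#' @return A classed list with a `model` field; class `hbf_params`.
#' @name model_params
NULL

check_delay <- function(d, name) {
  if (length(d) != 1L || !is.finite(d) || d != round(d) || d < 0 || d > 65)
    stop(name, " must be an integer in [0, 65]")
  as.integer(d)
}

check_pos <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0)
    stop(name, " must be a positive number")
  as.numeric(x)
}

# rate constants: zero is admitted as the degenerate limit (no inflow /
# no washout); fitting keeps them strictly positive via the transforms
check_rate <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0)
    stop(name, " must be a non-negative number")
  as.numeric(x)
}

check_frac <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop(name, " must lie in [0, 1]")
  as.numeric(x)
}

#' @rdname model_params
#' @export
params_1tcm <- function(f, k, V_B, dt1 = 0L) {
  structure(list(model = "1tcm",
                 f = check_rate(f, "f"), k = check_rate(k, "k"),
                 V_B = check_frac(V_B, "V_B"),
                 dt1 = check_delay(dt1, "dt1")),
            class = c("params_1tcm", "hbf_params"))
}

#' @rdname model_params
#' @export
params_taniguchi <- function(f_A, f_p, E, k, V_B, dt1 = 0L, dt2 = 0L) {
  structure(list(model = "taniguchi",
                 f_A = check_rate(f_A, "f_A"), f_p = check_rate(f_p, "f_p"),
                 E = check_frac(E, "E"), k = check_rate(k, "k"),
                 V_B = check_frac(V_B, "V_B"),
                 dt1 = check_delay(dt1, "dt1"),
                 dt2 = check_delay(dt2, "dt2")),
            class = c("params_taniguchi", "hbf_params"))
}

#' @rdname model_params
#' @export
params_rijzewijk <- function(f_A, f_p, E, k, V_B, dt1 = 0L) {
  structure(list(model = "rijzewijk",
                 f_A = check_rate(f_A, "f_A"), f_p = check_rate(f_p, "f_p"),
                 E = check_frac(E, "E"), k = check_rate(k, "k"),
                 V_B = check_frac(V_B, "V_B"),
                 dt1 = check_delay(dt1, "dt1")),
            class = c("params_rijzewijk", "hbf_params"))
}

#' @rdname model_params
#' @export
params_new_dual_input <- function(f_A, f_P, k, V_B, dt1 = 0L, dt2 = 0L) {
  structure(list(model = "new_dual_input",
                 f_A = check_rate(f_A, "f_A"), f_P = check_rate(f_P, "f_P"),
                 k = check_rate(k, "k"), V_B = check_frac(V_B, "V_B"),
                 dt1 = check_delay(dt1, "dt1"),
                 dt2 = check_delay(dt2, "dt2")),
            class = c("params_new_dual_input", "hbf_params"))
}

#' @export
print.hbf_params <- function(x, ...) {
  vals <- unlist(x[setdiff(names(x), "model")])
  cat(sprintf("<%s params: %s>\n", x$model,
              paste(names(vals), signif(vals, 4), sep = "=", collapse = ", ")))
  invisible(x)
}

model_ids <- c("1tcm", "taniguchi", "rijzewijk", "new_dual_input")

#' Number of fitted parameters per model
#'
#' 4 for the one-tissue model, 7 for the spleen-calibrated dual-input model,
#' 6 for the single-delay dual-input variant, 6 for the measured-portal-input
#' model (delays count as parameters).
#'
#' @param model one of `"1tcm"`, `"taniguchi"`, `"rijzewijk"`,
#'   `"new_dual_input"`.
#' @export
model_n_params <- function(model) {
  model <- match.arg(model, model_ids)
  switch(model, "1tcm" = 4L, "taniguchi" = 7L, "rijzewijk" = 6L,
         "new_dual_input" = 6L)
}

# Discrete forward step shared by every model:
#   C(i) = u(i) + (1 - k_s) * C(i - 1),  C(0) = 0,
# i.e. an explicit Euler step of dC/dt = u(t) - k_s C(t) on the 1-s grid,
# run by the compiled kernel.
recursive_uptake <- function(u, k_per_s) {
  if (k_per_s >= 1)
    warning("per-second washout >= 1: the recursion is unstable")
  euler_recursion(u, 1 - k_per_s)
}

# Per-second rate from a per-minute rate constant. The recursion applies
# rates per 1-s step while parameters are reported per minute; `per_step`
# skips the conversion for exact-replication studies on per-step rates.
rate_per_s <- function(rate_per_min, per_step = FALSE) {
  if (per_step) rate_per_min else rate_per_min / 60
}

# Stability warning for the public simulation surface: per-second rates at
# or above 1 flip the sign of the recursion's carry-over and blow up.
warn_unstable <- function(q, per_step) {
  div <- if (per_step) 1 else 60
  rates <- unlist(q[intersect(names(q), c("k", "f_p"))])
  if (any(rates / div >= 1))
    warning("per-second rate >= 1: the recursion is unstable")
  invisible(q)
}

# Vector-level forward simulation shared by the public simulate functions
# and the fitting objective (which is why it does not warn itself). `q` is a
# plain named list of constrained parameter values plus integer delays;
# returns numeric vectors.
sim_values <- function(model, q, aif_v, pv_v = NULL, per_step = FALSE) {
  div <- if (per_step) 1 else 60
  ks <- q$k / div
  if (model == "1tcm") {
    tis <- euler_recursion((q$f / div) * lag_values(aif_v, q$dt1 + 1L),
                           1 - ks)
    pvv <- NULL
    blood <- aif_v
  } else if (model == "taniguchi") {
    fps <- q$f_p / div
    pvv <- euler_recursion(fps * lag_values(aif_v, q$dt1 + 1L), 1 - fps)
    u <- (q$f_A / div) * lag_values(aif_v, q$dt1 + q$dt2 + 1L) +
      q$E * fps * lag_values(pvv, q$dt2 + 1L)
    tis <- euler_recursion(u, 1 - ks)
    w <- c(q$f_A, q$E * q$f_p)
    if (sum(w) <= 0) stop("degenerate parameters: zero total flow weight")
    blood <- (w[1] * aif_v + w[2] * pvv) / sum(w)
  } else if (model == "rijzewijk") {
    fps <- q$f_p / div
    pvv <- euler_recursion(fps * lag_values(aif_v, q$dt1 + 1L), 1 - fps)
    u <- (q$f_A / div) * lag_values(aif_v, 1L) +
      q$E * fps * lag_values(pvv, 1L)
    tis <- euler_recursion(u, 1 - ks)
    w <- c(q$f_A, q$E * q$f_p)
    if (sum(w) <= 0) stop("degenerate parameters: zero total flow weight")
    blood <- (w[1] * aif_v + w[2] * pvv) / sum(w)
  } else {
    if (is.null(pv_v)) stop("new_dual_input requires a measured portal curve")
    pvv <- pv_v
    u <- (q$f_A / div) * lag_values(aif_v, q$dt1 + 1L) +
      (q$f_P / div) * lag_values(pv_v, q$dt2 + 1L)
    tis <- euler_recursion(u, 1 - ks)
    w <- c(q$f_A, q$f_P)
    if (sum(w) <= 0) stop("degenerate parameters: zero total flow weight")
    blood <- (w[1] * aif_v + w[2] * pv_v) / sum(w)
  }
  list(tissue = tis, pv = pvv,
       pet = (1 - q$V_B) * tis + q$V_B * blood)
}

#' Simulate the one-tissue compartment model
#'
#' Runs the discrete recursion
#' `C_T(i) = f_s * C_A(i - dt1 - 1) + (1 - k_s) * C_T(i - 1)` for
#' i = 1..T with per-second rates `f_s = f/60`, `k_s = k/60` and
#' `C_T(0) = 0`. The one-sample input lag is part of the model definition.
#'
#' @param params a [params_1tcm()].
#' @param aif arterial input, a [sampled_curve()] on the 1-s grid.
#' @param per_step use the parameter values directly as per-step rates
#'   instead of dividing by 60.
#' @return Tissue curve `C_T` as a [sampled_curve()].
#' @export
simulate_1tcm <- function(params, aif, per_step = FALSE) {
  stopifnot(inherits(params, "params_1tcm"), inherits(aif, "sampled_curve"))
  warn_unstable(params, per_step)
  sim <- sim_values("1tcm", params, aif$values, per_step = per_step)
  sampled_curve(sim$tissue, "model")
}

#' Simulate the dispersed portal-vein compartment
#'
#' The notional portal compartment of the dual-input models:
#' `dC_PV/dt = f_p C_A(t - dt1) - f_p C_PV(t)`, discretised on the 1-s grid.
#' The output is a delayed, dispersed, unit-DC-gain copy of the arterial
#' input.
#'
#' @param f_p dispersion rate constant, mL/min/mL.
#' @param dt1 integer delay, seconds.
#' @param aif arterial input, a [sampled_curve()].
#' @inheritParams simulate_1tcm
#' @return Portal curve `C_PV` as a [sampled_curve()].
#' @export
simulate_pv_compartment <- function(f_p, dt1, aif, per_step = FALSE) {
  stopifnot(inherits(aif, "sampled_curve"))
  f_p <- check_pos(f_p, "f_p")
  dt1 <- check_delay(dt1, "dt1")
  fps <- rate_per_s(f_p, per_step)
  u <- fps * lag_values(aif$values, dt1 + 1L)
  sampled_curve(recursive_uptake(u, fps), "portal_vein")
}

#' Simulate the spleen-calibrated dual-input model
#'
#' Two coupled recursions: the dispersed portal compartment driven by the
#' `dt1`-delayed aorta, and a liver compartment receiving the doubly delayed
#' artery plus the `dt2`-delayed, `E`-scaled portal compartment:
#' `dC_T/dt = f_A C_A(t - dt1 - dt2) + E f_p C_PV(t - dt2) - k C_T(t)`.
#'
#' @param params a [params_taniguchi()].
#' @inheritParams simulate_1tcm
#' @return A list with [sampled_curve()] elements `tissue` and `pv`.
#' @export
simulate_taniguchi <- function(params, aif, per_step = FALSE) {
  stopifnot(inherits(params, "params_taniguchi"),
            inherits(aif, "sampled_curve"))
  warn_unstable(params, per_step)
  sim <- sim_values("taniguchi", params, aif$values, per_step = per_step)
  list(tissue = sampled_curve(sim$tissue, "model"),
       pv = sampled_curve(sim$pv, "portal_vein"))
}

#' Simulate the single-delay dual-input model
#'
#' As [simulate_taniguchi()] but with the arterial liver term undelayed and
#' the sole delay `dt1` on the portal compartment's input:
#' `dC_T/dt = f_A C_A(t) + E f_p C_PV(t) - k C_T(t)`.
#'
#' @param params a [params_rijzewijk()].
#' @inheritParams simulate_1tcm
#' @return A list with [sampled_curve()] elements `tissue` and `pv`.
#' @export
simulate_rijzewijk <- function(params, aif, per_step = FALSE) {
  stopifnot(inherits(params, "params_rijzewijk"),
            inherits(aif, "sampled_curve"))
  warn_unstable(params, per_step)
  sim <- sim_values("rijzewijk", params, aif$values, per_step = per_step)
  list(tissue = sampled_curve(sim$tissue, "model"),
       pv = sampled_curve(sim$pv, "portal_vein"))
}

#' Simulate the measured-portal-input dual-input model
#'
#' One differential equation with two measured, independently delayed inputs:
#' `dC_T/dt = f_A C_A(t - dt1) + f_P C_PV(t - dt2) - k C_T(t)`, where `C_PV`
#' is an image-derived portal-vein curve rather than a notional compartment.
#'
#' @param params a [params_new_dual_input()].
#' @param pv measured portal-vein input, a [sampled_curve()] on the same
#'   grid as `aif`.
#' @inheritParams simulate_1tcm
#' @return Tissue curve `C_T` as a [sampled_curve()].
#' @export
simulate_new_model <- function(params, aif, pv, per_step = FALSE) {
  stopifnot(inherits(params, "params_new_dual_input"),
            inherits(aif, "sampled_curve"), inherits(pv, "sampled_curve"))
  if (length(aif$values) != length(pv$values))
    stop("aif and pv must be on the same grid")
  warn_unstable(params, per_step)
  sim <- sim_values("new_dual_input", params, aif$values, pv$values,
                    per_step = per_step)
  sampled_curve(sim$tissue, "model")
}

#' Mix tissue and blood signal into the model PET curve
#'
#' `C_PET = (1 - V_B) * C_T + V_B * blood`, pointwise. The blood curve is the
#' arterial input for the one-tissue model and the flow-weighted mean of the
#' (undelayed) arterial and portal curves for the dual-input models; see
#' [model_blood_curve()].
#'
#' @param tissue tissue curve `C_T`, a [sampled_curve()].
#' @param blood blood curve, a [sampled_curve()] on the same grid.
#' @param V_B blood volume fraction in \[0, 1\].
#' @return `C_PET` as a [sampled_curve()].
#' @export
blend_blood <- function(tissue, blood, V_B) {
  stopifnot(inherits(tissue, "sampled_curve"),
            inherits(blood, "sampled_curve"))
  V_B <- check_frac(V_B, "V_B")
  if (length(tissue$values) != length(blood$values))
    stop("tissue and blood curves must be aligned")
  sampled_curve((1 - V_B) * tissue$values + V_B * blood$values, "model")
}

#' Model-specific blood curve for the blood-volume term
#'
#' The one-tissue model uses the arterial curve; the dual-input variants use
#' the flow-weighted mean `(f_A C_A + E f_p C_PV) / (f_A + E f_p)`; the
#' measured-portal-input model uses `(f_A C_A + f_P C_PV) / (f_A + f_P)`.
#' All blood terms use the undelayed curves.
#'
#' @param params an `hbf_params` object.
#' @param aif arterial [sampled_curve()].
#' @param pv portal [sampled_curve()] (the simulated compartment for the
#'   notional-portal models, the measured curve for the others); ignored for
#'   the one-tissue model.
#' @return Blood curve as a [sampled_curve()].
#' @export
model_blood_curve <- function(params, aif, pv = NULL) {
  stopifnot(inherits(params, "hbf_params"))
  if (params$model == "1tcm") return(sampled_curve(aif$values, "model"))
  if (is.null(pv)) stop("dual-input blood curve needs a portal curve")
  w <- switch(params$model,
              taniguchi = ,
              rijzewijk = c(params$f_A, params$E * params$f_p),
              new_dual_input = c(params$f_A, params$f_P))
  if (sum(w) <= 0) stop("degenerate parameters: zero total flow weight")
  sampled_curve((w[1] * aif$values + w[2] * pv$values) / sum(w), "model")
}

#' Full forward model: tissue, portal and PET curves
#'
#' Dispatches on the parameter class, simulates the tissue (and, for the
#' notional-portal models, the portal) curve, and applies the blood-volume
#' mixing to produce the curve that is compared with the measured liver TAC.
#'
#' @param params an `hbf_params` object of any of the four models.
#' @param aif arterial input, a [sampled_curve()].
#' @param pv measured portal input (required for `new_dual_input`, ignored
#'   for `1tcm`, unused for the notional-portal models which simulate their
#'   own).
#' @inheritParams simulate_1tcm
#' @return A list with elements `tissue`, `pv` (NULL for `1tcm`), and `pet`.
#' @export
model_pet_curve <- function(params, aif, pv = NULL, per_step = FALSE) {
  stopifnot(inherits(params, "hbf_params"), inherits(aif, "sampled_curve"))
  if (!is.null(pv) && length(aif$values) != length(pv$values))
    stop("aif and pv must be on the same grid")
  warn_unstable(params, per_step)
  sim <- sim_values(params$model, params, aif$values,
                    if (!is.null(pv)) pv$values, per_step = per_step)
  list(tissue = sampled_curve(sim$tissue, "model"),
       pv = if (!is.null(sim$pv)) sampled_curve(sim$pv, "portal_vein"),
       pet = sampled_curve(sim$pet, "model"))
}

#' Derived haemodynamic quantities
#'
#' Total hepatic blood flow `f = f_A + f_P` (with `f_P = E * f_p` for the
#' notional-portal models), the water partition coefficient `V_T = f / k`,
#' and the portal fraction `f_P / f`. For the one-tissue model the portal
#' fraction is undefined and reported as `NA`.
#'
#' @param params an `hbf_params` object.
#' @return A list with `f_total` (mL/min/mL), `V_T` (unitless) and
#'   `portal_fraction` (unitless, `NA` for `1tcm`).
#' @export
derive_quantities <- function(params) {
  stopifnot(inherits(params, "hbf_params"))
  if (params$k == 0) stop("k = 0: partition coefficient undefined")
  fp <- switch(params$model,
               "1tcm" = NA_real_,
               "taniguchi" = ,
               "rijzewijk" = params$E * params$f_p,
               "new_dual_input" = params$f_P)
  f_total <- switch(params$model,
                    "1tcm" = params$f,
                    params$f_A + fp)
  list(f_total = f_total,
       V_T = f_total / params$k,
       portal_fraction = if (is.na(fp)) NA_real_ else fp / f_total)
}
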