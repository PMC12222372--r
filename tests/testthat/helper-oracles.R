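# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct loops, closed forms, exhaustive
# enumeration, and a fine-step ODE integrator.

# Analytic gamma-variate input, normalised so `amplitude` is the peak, with
# the same optional recirculation shoulder as the generator spec. Evaluable
# at arbitrary real times, which the ODE oracle needs.
oracle_aif_fun <- function(amplitude = 45000, onset = 8, shape = 3,
                           scale = 6, recirc_fraction = 0, recirc_tau = 60) {
  function(t) {
    s <- pmax(t - onset, 0)
    g <- ifelse(s > 0, s^shape * exp(-s / scale), 0)
    out <- amplitude * g / ((shape * scale)^shape * exp(-shape))
    if (recirc_fraction > 0) {
      tp <- onset + shape * scale
      out <- out + recirc_fraction * amplitude *
        (1 - exp(-pmax(t - tp, 0) / recirc_tau))
    }
    out
  }
}

# Fine-step integration (deSolve, stiff-safe lsoda) of the continuous-time
# model equations with per-second rates, sampled on the integer grid.
# `model` selects the stated ODE system; delays are applied to the input
# function arguments exactly as the equations state them.
ode_oracle <- function(model, p, aif_fun, pv_fun = NULL, t_max = 280) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  times <- seq(0, t_max, by = 1)
  rhs <- switch(model,
    "1tcm" = function(t, y, parms) {
      list((p$f / 60) * aif_fun(t - p$dt1) - (p$k / 60) * y[1])
    },
    "taniguchi" = function(t, y, parms) {
      dpv <- (p$f_p / 60) * (aif_fun(t - p$dt1) - y[1])
      # delayed PV term: the PV state has a closed dependence on the input
      # only through its own ODE, so the delayed value is obtained by
      # integrating a shadow copy lagged in its driving time
      stop("handled separately")
    },
    "rijzewijk" = function(t, y, parms) {
      dpv <- (p$f_p / 60) * (aif_fun(t - p$dt1) - y[1])
      dct <- (p$f_A / 60) * aif_fun(t) +
        p$E * (p$f_p / 60) * y[1] - (p$k / 60) * y[2]
      list(c(dpv, dct))
    },
    "new_dual_input" = function(t, y, parms) {
      list((p$f_A / 60) * aif_fun(t - p$dt1) +
             (p$f_P / 60) * pv_fun(t - p$dt2) - (p$k / 60) * y[1])
    })
  if (model == "taniguchi") {
    # integrate the PV compartment once, then feed its interpolant, delayed
    # by dt2, into the liver equation
    pv_sol <- deSolve::ode(y = 0, times = seq(0, t_max, by = 0.05),
                           func = function(t, y, parms)
                             list((p$f_p / 60) * (aif_fun(t - p$dt1) - y[1])),
                           parms = NULL, method = "lsoda")
    pvf <- stats::approxfun(pv_sol[, 1], pv_sol[, 2], rule = 2, yleft = 0)
    sol <- deSolve::ode(y = 0, times = times,
                        func = function(t, y, parms)
                          list((p$f_A / 60) * aif_fun(t - p$dt1 - p$dt2) +
                                 p$E * (p$f_p / 60) *
                                 pvf(max(t - p$dt2, 0)) -
                                 (p$k / 60) * y[1]),
                        parms = NULL, method = "lsoda")
    return(list(tissue = sol[-1, 2],
                pv = pvf(pmax(times[-1], 0))))
  }
  n_state <- if (model == "rijzewijk") 2 else 1
  sol <- deSolve::ode(y = numeric(n_state), times = times, func = rhs,
                      parms = NULL, method = "lsoda")
  if (model == "rijzewijk")
    list(pv = sol[-1, 2], tissue = sol[-1, 3])
  else list(tissue = sol[-1, 2])
}

rel_l2 <- function(x, ref) sqrt(sum((x - ref)^2) / sum(ref^2))

# Two-point piecewise-linear interpolation evaluated second by second, with
# anchors at (0, 0) and the frame midpoints, constant beyond the last anchor.
interp_oracle <- function(mids, vals, t_max = 280) {
  xs <- c(0, mids)
  ys <- c(0, vals)
  sapply(seq_len(t_max), function(t) {
    if (t >= max(xs)) return(ys[length(ys)])
    i <- max(which(xs <= t))
    ys[i] + (ys[i + 1] - ys[i]) * (t - xs[i]) / (xs[i + 1] - xs[i])
  })
}

# Exact one-sided signed-rank p-value by enumeration over all sign
# assignments (tie-free, zero-free differences only).
signed_rank_exact_oracle <- function(a, b, alternative = "greater") {
  d <- a - b
  stopifnot(all(d != 0), !any(duplicated(abs(d))))
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  switch(alternative,
         greater = mean(v_all >= v_obs),
         less = mean(v_all <= v_obs))
}

# Exact two-sided Mann-Whitney p-value by enumeration over all group
# assignments of the pooled ranks (tie-free data only).
mwu_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!any(duplicated(pooled)))
  m <- length(a)
  r <- rank(pooled)
  u_from <- function(idx) sum(r[idx]) - m * (m + 1) / 2
  u_obs <- u_from(seq_len(m))
  combos <- utils::combn(length(pooled), m)
  u_all <- apply(combos, 2, u_from)
  mu <- m * length(b) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# BFS flood fill over the 26-neighbourhood; returns the membership labels.
bfs_components_oracle <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  cur <- 0L
  idx_all <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx_all))) {
    v <- idx_all[r, ]
    if (lab[v[1], v[2], v[3]] > 0L) next
    cur <- cur + 1L
    queue <- list(v)
    lab[v[1], v[2], v[3]] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (j in seq_len(nrow(nb))) {
        q <- p + nb[j, ]
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- cur
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# random physiological parameter draw helpers (fixed ranges shared by the
# discretisation and recovery tests)
draw_phys_1tcm <- function(delay_max = 40L) {
  params_1tcm(f = runif(1, 0.1, 3), k = runif(1, 0.1, 3),
              V_B = runif(1, 0.02, 0.3), dt1 = sample(0:delay_max, 1))
}

draw_phys_new <- function(delay_max = 40L) {
  params_new_dual_input(f_A = runif(1, 0.1, 1), f_P = runif(1, 0.3, 2),
                        k = runif(1, 0.3, 2.5), V_B = runif(1, 0.02, 0.3),
                        dt1 = sample(0:delay_max, 1),
                        dt2 = sample(0:delay_max, 1))
}

draw_phys_taniguchi <- function(delay_max = 40L) {
  params_taniguchi(f_A = runif(1, 0.1, 1), f_p = runif(1, 0.5, 2),
                   E = runif(1, 0.5, 0.95), k = runif(1, 0.3, 2.5),
                   V_B = runif(1, 0.02, 0.3),
                   dt1 = sample(0:delay_max, 1),
                   dt2 = sample(0:delay_max, 1))
}

draw_phys_rijzewijk <- function(delay_max = 40L) {
  params_rijzewijk(f_A = runif(1, 0.1, 1), f_p = runif(1, 0.5, 2),
                   E = runif(1, 0.5, 0.95), k = runif(1, 0.3, 2.5),
                   V_B = runif(1, 0.02, 0.3),
                   dt1 = sample(0:delay_max, 1))
}
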