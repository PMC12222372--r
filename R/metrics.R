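#' Frame-level fit metrics: MRE, MSE, AIC
#'
#' Evaluates a fitted model curve against the measured TAC on the original
#' acquisition frames (24 in the default protocol):
#' \itemize{
#'   \item MRE = mean over frames of |measured - fitted| / measured;
#'   \item MSE = mean over frames of (measured - fitted)^2 with both curves
#'     in kBq/mL;
#'   \item AIC = n_frames * ln(max(MSE, mse_floor)) + 2 N, with N the total
#'     number of model parameters including delays.
#' }
#' The fitted 1-s curve is frame-averaged onto the schedule by default (the
#' measured value is itself a frame mean); `frame_eval = "midpoint"` samples
#' it at frame midpoints instead. Frames whose measured value is below `eps`
#' in absolute value are excluded from the MRE with the divisor reduced
#' accordingly (a warning is emitted).
#'
#' @param fitted fitted model curve on the 1-s grid, a [sampled_curve()].
#' @param measured measured TAC, a [frame_tac()] in Bq/mL.
#' @param n_params total number of model parameters N.
#' @param mse_floor AIC floor on the MSE, (kBq/mL)^2.
#' @param frame_eval `"average"` (default) or `"midpoint"`.
#' @param eps absolute activity below which a frame is dropped from the MRE,
#'   Bq/mL.
#' @return A list of class `fit_metrics`: `mre`, `mse`, `aic`, `n_params`,
#'   `n_frames`, `n_frames_mre` (frames retained in the MRE sum).
#' @export
compute_metrics <- function(fitted, measured, n_params,
                            mse_floor = 1e-12,
                            frame_eval = c("average", "midpoint"),
                            eps = 1e-6) {
  stopifnot(inherits(fitted, "sampled_curve"), inherits(measured, "frame_tac"))
  frame_eval <- match.arg(frame_eval)
  nf <- n_frames(measured$schedule)
  fit_frames <- if (frame_eval == "average")
    frame_average(fitted, measured$schedule)$values
  else fitted$values[round(frame_midpoints(measured$schedule))]
  m <- measured$values

  keep <- abs(m) >= eps
  if (!all(keep))
    warning(sum(!keep), " frame(s) with near-zero measured activity ",
            "excluded from the MRE")
  if (!any(keep)) stop("no frames usable for the MRE")
  mre <- mean(abs(m[keep] - fit_frames[keep]) / m[keep])

  d_kbq <- (m - fit_frames) / 1000
  mse <- mean(d_kbq^2)
  aic <- nf * log(max(mse, mse_floor)) + 2 * n_params

  structure(list(mre = mre, mse = mse, aic = aic,
                 n_params = as.integer(n_params), n_frames = nf,
                 n_frames_mre = sum(keep)),
            class = "fit_metrics")
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("<fit_metrics: MRE = %.4f, MSE = %.4g (kBq/mL)^2, AIC = %.2f (N = %d, frames = %d)>\n",
              x$mre, x$mse, x$aic, x$n_params, x$n_frames))
  invisible(x)
}

#' One-sided Wilcoxon signed-rank test for paired error terms
#'
#' Tests whether the paired values in `a` systematically exceed those in `b`
#' (alternative `"greater"`, the default, as used when asking whether one
#' model's errors are larger than another's). Zero differences are dropped
#' and ties mid-ranked; the exact distribution is used for up to 25 non-zero
#' pairs and the continuity-corrected normal approximation beyond that.
#'
#' @param a,b equal-length paired numeric vectors.
#' @param alternative `"greater"`, `"less"`, or `"two.sided"`.
#' @return A list with `statistic` (V) and `p_value`.
#' @export
wilcoxon_signed_rank <- function(a, b, alternative = "greater") {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 5) stop("need at least 5 pairs")
  d <- a - b
  n_eff <- sum(d != 0)
  if (n_eff == 0) {
    warning("all differences are zero")
    return(list(statistic = 0, p_value = 1))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, alternative = alternative,
                       exact = n_eff <= 25, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Mann-Whitney U test for two independent groups
#'
#' Two-sided by default, as used for sex-based comparisons of flow
#' estimates. Exact for small tie-free samples, otherwise the tie-corrected
#' normal approximation.
#'
#' @param a,b independent samples, each of length >= 3.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return A list with `statistic` (U) and `p_value`.
#' @export
mann_whitney_u <- function(a, b, alternative = "two.sided") {
  if (length(a) < 3 || length(b) < 3) stop("each group needs >= 3 values")
  ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Pearson correlation with t-based test
#'
#' Pearson's r with the two-sided test from
#' t = r sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom, as used for
#' associations between flow estimates and age, weight, or BMI.
#'
#' @param x,y numeric vectors of equal length >= 3 with finite values.
#' @return A list with `r` and `p_value`.
#' @export
pearson_with_t_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need paired vectors of length >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p_value = ht$p.value)
}

#' Cohort-level summary of fitted models
#'
#' Summarises a per-subject, per-model table of fit results the way cohort
#' tables are reported: mean +/- SD (sample SD, n - 1 denominator) of each
#' parameter and derived quantity per model, medians of MRE/MSE/AIC per
#' model, and the matrix of pairwise one-sided Wilcoxon signed-rank
#' p-values asking whether the row model's error exceeds the column
#' model's.
#'
#' @param table a data frame / tibble with columns `subject`, `model`,
#'   numeric parameter / derived-quantity columns, and (optionally) `mre`,
#'   `mse`, `aic`.
#' @return A list with tibbles `params` (mean, sd per model and variable),
#'   `errors` (medians per model), and `comparisons` (long tibble of
#'   pairwise one-sided p-values per metric, rows where both models have
#'   complete pairs).
#' @export
cohort_summary <- function(table) {
  stopifnot(is.data.frame(table), all(c("subject", "model") %in% names(table)))
  tbl <- tibble::as_tibble(table)
  metric_cols <- intersect(c("mre", "mse", "aic"), names(tbl))
  value_cols <- setdiff(names(tbl)[vapply(tbl, is.numeric, logical(1))],
                        c("subject", metric_cols))

  params <- tbl |>
    tidyr_longer(value_cols) |>
    dplyr::group_by(.data$model, .data$variable) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value, na.rm = TRUE),
                     n = sum(!is.na(.data$value)), .groups = "drop")

  errors <- NULL
  comparisons <- NULL
  if (length(metric_cols) > 0) {
    errors <- tbl |>
      dplyr::group_by(.data$model) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(metric_cols),
                                     ~ stats::median(.x, na.rm = TRUE)),
                       .groups = "drop")
    models <- unique(tbl$model)
    rows <- list()
    for (ma in models) for (mb in setdiff(models, ma)) {
      a <- tbl[tbl$model == ma, c("subject", metric_cols)]
      b <- tbl[tbl$model == mb, c("subject", metric_cols)]
      common <- intersect(a$subject, b$subject)
      if (length(common) < 5) next
      for (mc in metric_cols) {
        av <- a[[mc]][match(common, a$subject)]
        bv <- b[[mc]][match(common, b$subject)]
        p <- wilcoxon_signed_rank(av, bv, "greater")$p_value
        rows[[length(rows) + 1L]] <-
          tibble::tibble(model_a = ma, model_b = mb, metric = mc,
                         p_greater = p)
      }
    }
    comparisons <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(model_a = character(), model_b = character(),
                     metric = character(), p_greater = numeric())
  }
  list(params = params, errors = errors, comparisons = comparisons)
}

# minimal long-format pivot (avoids importing tidyr for one reshape)
tidyr_longer <- function(tbl, cols) {
  pieces <- lapply(cols, function(cn) {
    tibble::tibble(model = tbl$model, variable = cn, value = tbl[[cn]])
  })
  dplyr::bind_rows(pieces)
}
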