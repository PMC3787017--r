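# Constrained variable-slope sigmoid dose-response fitting. The model is the
# two-parameter Hill curve on log10 dose with floor and ceiling hard-fixed
# at 0 and 100 percent inhibition:
#
#   E(d) = 100 / (1 + 10^(hill * (log_ed50 - log10(d))))
#
# Per-animal points (not dose means) enter the unweighted least-squares loss.

#' Predicted percent inhibition from the constrained sigmoid
#'
#' Variable-slope sigmoid with minimum and maximum constrained to 0 and 100:
#' \deqn{E(d) = 100 / (1 + 10^{h (\log_{10}ED_{50} - \log_{10} d)})}
#' At `dose = ED50` the prediction is exactly 50.
#'
#' @param dose Dose(s) in mg/kg, strictly positive. Vectorized.
#' @param log_ed50 log10 of the ED50 (log10 mg/kg).
#' @param hill Hill slope, > 0.
#' @return Predicted percent inhibition in (0, 100).
#' @examples
#' predict_inhibition(10, log_ed50 = 0, hill = 1)  # 90.909...
#' @export
predict_inhibition <- function(dose, log_ed50, hill) {
  if (!is.numeric(dose) || any(is.na(dose)) || any(dose <= 0)) {
    stop_input("`dose` must be strictly positive")
  }
  assert_number(log_ed50)
  assert_number(hill)
  if (hill <= 0) stop_input("`hill` must be > 0")
  100 / (1 + 10^(hill * (log_ed50 - log10(dose))))
}

#' Construct an ED50 estimate from printed values
#'
#' Minimal container for an ED50 with its 95% confidence interval, e.g. when
#' entering values read off a publication rather than refitting raw data.
#' [fit_ed50()] results inherit from this class, so the two are
#' interchangeable in the synergy functions.
#'
#' @param ed50 ED50 in mg/kg, > 0.
#' @param lower,upper 95% CI bounds in mg/kg (optional; `NA` if unknown).
#' @param label Drug label.
#' @return An object of class `ed50_estimate`.
#' @examples
#' morphine <- ed50_estimate(2.3, 2.0, 2.5, label = "morphine")
#' @export
ed50_estimate <- function(ed50, lower = NA_real_, upper = NA_real_,
                          label = "drug") {
  assert_number(ed50)
  if (ed50 <= 0) stop_input("`ed50` must be > 0")
  if (!is.na(lower) && !is.na(upper)) {
    if (!(lower < ed50 && ed50 < upper)) {
      stop_input("CI must bracket the ED50: lower < ed50 < upper")
    }
  }
  structure(
    list(drug_label = label, ed50 = ed50, log_ed50 = log10(ed50),
         ci95 = c(lower = lower, upper = upper)),
    class = "ed50_estimate"
  )
}

has_ci <- function(x) {
  !is.null(x$ci95) && all(is.finite(x$ci95))
}

#' @export
print.ed50_estimate <- function(x, ...) {
  ci <- if (has_ci(x)) {
    sprintf(" (95%% CI: %.3g-%.3g)", x$ci95[["lower"]], x$ci95[["upper"]])
  } else {
    " (CI unavailable)"
  }
  cat(sprintf("%s: ED50 = %.3g mg/kg%s\n", x$drug_label, x$ed50, ci))
  invisible(x)
}

#' Fit the constrained sigmoid and estimate the ED50
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the two-parameter
#' constrained sigmoid over `(log_ed50, hill)` on per-animal
#' percent-inhibition points. The 95% CI is computed on `log_ed50` from the
#' asymptotic covariance with a t critical value on `n - 2` degrees of
#' freedom, then back-transformed to mg/kg, which makes it asymmetric on the
#' linear scale (the convention of standard dose-response software).
#'
#' Initialization places `log_ed50` at the dose whose mean response is
#' nearest 50% with `hill = 1`; the Hill slope is bounded to \[0.1, 10\] to
#' prevent degenerate step-function fits on sparse designs.
#'
#' @param dose Per-animal doses in mg/kg (> 0); at least 3 distinct doses.
#' @param pct_inhibition Per-animal percent inhibition (may be negative or
#'   exceed 100; the curve, not the data, is constrained).
#' @param drug_label Label carried into the result.
#' @param conf_level Confidence level for the ED50 interval.
#' @return An object of classes `dose_response_fit` and `ed50_estimate` with
#'   elements `drug_label`, `log_ed50`, `ed50`, `hill`, `ci95` (mg/kg),
#'   `se_log_ed50`, `n_points`, `converged`, `residual_sd` and the raw data.
#' @examples
#' d <- rep(c(0.3, 1, 3, 10), each = 4)
#' y <- predict_inhibition(d, log_ed50 = log10(2.3), hill = 1.5)
#' fit_ed50(d, y, drug_label = "noise-free")
#' @export
fit_ed50 <- function(dose, pct_inhibition, drug_label = "drug",
                     conf_level = 0.95) {
  if (length(dose) != length(pct_inhibition)) {
    stop_input("`dose` and `pct_inhibition` must have equal length")
  }
  if (!is.numeric(dose) || any(is.na(dose)) || any(dose <= 0)) {
    stop_input("doses must be strictly positive")
  }
  if (anyNA(pct_inhibition)) stop_input("`pct_inhibition` must not contain NA")
  if (length(unique(dose)) < 3L) {
    stop_input("design error: need >= 3 distinct positive doses")
  }

  # canonical row order so the fit is bit-identical under input permutation
  ord <- order(dose, pct_inhibition)
  dose <- dose[ord]
  pct_inhibition <- pct_inhibition[ord]

  logd <- log10(dose)
  y <- as.numeric(pct_inhibition)
  n <- length(y)

  # deterministic start: log-dose whose group mean response is nearest 50%
  dose_means <- tapply(y, logd, mean)
  start_log <- as.numeric(names(dose_means))[which.min(abs(dose_means - 50))]
  lower <- c(log_ed50 = min(logd) - 3, hill = 0.1)
  upper <- c(log_ed50 = max(logd) + 3, hill = 10)

  dat <- data.frame(logd = logd, y = y)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      y ~ 100 / (1 + 10^(hill * (log_ed50 - logd))),
      data = dat,
      start = list(log_ed50 = start_log, hill = 1),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )),
    error = function(e) NULL
  )

  res <- structure(
    list(
      drug_label = drug_label,
      log_ed50 = NA_real_, ed50 = NA_real_, hill = NA_real_,
      ci95 = c(lower = NA_real_, upper = NA_real_),
      se_log_ed50 = NA_real_, n_points = n,
      converged = FALSE, residual_sd = NA_real_,
      conf_level = conf_level,
      data = data.frame(dose = dose, pct_inhibition = y)
    ),
    class = c("dose_response_fit", "ed50_estimate")
  )
  if (is.null(fit)) return(res)

  cf <- stats::coef(fit)
  res$log_ed50 <- unname(cf[["log_ed50"]])
  res$ed50 <- 10^res$log_ed50
  res$hill <- unname(cf[["hill"]])
  res$converged <- isTRUE(fit$convInfo$isConv)
  df_res <- n - 2L
  res$residual_sd <- sqrt(sum(stats::resid(fit)^2) / df_res)

  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["log_ed50"]],
                 error = function(e) NA_real_)
  if (res$converged && is.finite(se) && df_res > 0L) {
    res$se_log_ed50 <- se
    tcrit <- stats::qt(0.5 + conf_level / 2, df_res)
    ci_log <- res$log_ed50 + c(-1, 1) * tcrit * se
    res$ci95 <- c(lower = 10^ci_log[1], upper = 10^ci_log[2])
  }
  res
}

#' Fit one arm of a percent-inhibition table
#'
#' Convenience wrapper: selects the rows of one treatment arm from a
#' [percent_inhibition_table()] and fits [fit_ed50()] on its total mixture
#' dose (component doses summed), the Loewe-consistent axis for
#' combination arms.
#'
#' @param pct_table Output of [percent_inhibition_table()].
#' @param arm Arm label to fit.
#' @param drug_label Label for the result; defaults to the arm.
#' @inheritParams fit_ed50
#' @return A `dose_response_fit`.
#' @export
fit_arm <- function(pct_table, arm, drug_label = arm, conf_level = 0.95) {
  assert_columns(pct_table, c("arm", "total_dose_mg_kg", "pct_inhibition"),
                 "percent-inhibition table")
  d <- pct_table[pct_table$arm == arm & pct_table$total_dose_mg_kg > 0, ]
  if (nrow(d) == 0L) stop_input(sprintf("no dosed animals in arm '%s'", arm))
  fit_ed50(d$total_dose_mg_kg, d$pct_inhibition,
           drug_label = drug_label, conf_level = conf_level)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> %s\n", x$drug_label))
  if (!x$converged) cat("  [fit did not converge]\n")
  ci <- if (has_ci(x)) {
    sprintf("95%% CI: %.3g-%.3g", x$ci95[["lower"]], x$ci95[["upper"]])
  } else {
    "CI unavailable"
  }
  cat(sprintf("  ED50 = %.3g mg/kg (%s), Hill slope = %.3g\n",
              x$ed50, ci, x$hill))
  cat(sprintf("  n = %d animal points, residual SD = %.3g%%\n",
              x$n_points, x$residual_sd))
  invisible(x)
}

#' Plot a fitted dose-response curve
#'
#' Per-animal points with the fitted constrained sigmoid on a log10 dose
#' axis.
#'
#' @param x A `dose_response_fit`.
#' @param ... Passed to [plot()].
#' @export
plot.dose_response_fit <- function(x, ...) {
  d <- x$data
  plot(d$dose, d$pct_inhibition, log = "x",
       xlab = "dose (mg/kg)", ylab = "% inhibition of flinching",
       main = x$drug_label, ...)
  if (is.finite(x$ed50)) {
    grid_d <- 10^seq(log10(min(d$dose)) - 0.5, log10(max(d$dose)) + 0.5,
                     length.out = 200)
    graphics::lines(grid_d, predict_inhibition(grid_d, x$log_ed50, x$hill))
    graphics::abline(v = x$ed50, lty = 2)
  }
  invisible(x)
}
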