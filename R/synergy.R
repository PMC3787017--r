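# Fixed-dose and fixed-ratio (isobolographic) synergy evaluation under the
# Loewe additivity null model. The theoretical additive ED50 of an A:B
# mixture is the fractional-multiplier combination of the component ED50s,
# and synergy is declared when the observed combination ED50's 95% CI falls
# entirely below the additive point's 95% CI.

#' Fractional multiplier for a fixed-ratio mixture
#'
#' Weight converting the mixture ratio and component potency ratio into the
#' additive ED50 under Loewe additivity:
#' \deqn{F = r / (r + ED_{50,A} / ED_{50,B})}
#' where `r` is parts of drug A per part of drug B. `F` runs from 0 (pure
#' drug B) to 1 (pure drug A) and is monotone in the ratio.
#'
#' @param ratio Parts of drug A per part of drug B, >= 0 (`Inf` allowed for
#'   the pure-A limit).
#' @param ed50_a,ed50_b Component ED50s in mg/kg, > 0.
#' @return The fractional multiplier in \[0, 1\].
#' @examples
#' fractional_multiplier(3, 27.8, 2.3)  # 0.19886...
#' @export
fractional_multiplier <- function(ratio, ed50_a, ed50_b) {
  if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) || ratio < 0) {
    stop_input("`ratio` must be a single number >= 0")
  }
  assert_number(ed50_a)
  assert_number(ed50_b)
  if (ed50_a <= 0 || ed50_b <= 0) stop_input("ED50s must be > 0")
  if (is.infinite(ratio)) return(1)
  ratio / (ratio + ed50_a / ed50_b)
}

#' Theoretical additive ED50 of a fixed-ratio combination
#'
#' Loewe-additive ED50 of the mixture, expressed on the total mixture dose
#' axis: `z_add = f * ed50_a + (1 - f) * ed50_b`. It is always bracketed by
#' the two component ED50s.
#'
#' @param f Fractional multiplier in \[0, 1\] (see
#'   [fractional_multiplier()]).
#' @param ed50_a,ed50_b Component ED50s in mg/kg, > 0.
#' @return Additive ED50 in mg/kg (total mixture dose).
#' @examples
#' f <- fractional_multiplier(3, 27.8, 2.3)
#' additive_ed50(f, 27.8, 2.3)  # 7.4 mg/kg to one decimal
#' @export
additive_ed50 <- function(f, ed50_a, ed50_b) {
  assert_number(f)
  if (f < 0 || f > 1) stop_input("`f` must lie in [0, 1]")
  assert_number(ed50_a)
  assert_number(ed50_b)
  if (ed50_a <= 0 || ed50_b <= 0) stop_input("ED50s must be > 0")
  f * ed50_a + (1 - f) * ed50_b
}

# SE on the linear scale recovered from a 95% CI: mean of the two half-widths
# divided by 1.96. Returns NA when the CI is absent.
se_from_ci95 <- function(est) {
  if (!has_ci(est)) return(NA_real_)
  mean(c(est$ci95[["upper"]] - est$ed50, est$ed50 - est$ci95[["lower"]])) / 1.96
}

#' 95% CI for the theoretical additive ED50
#'
#' Delta-method variance combination. Each component SE is recovered from
#' its 95% CI half-width on the linear scale (mean of the upper and lower
#' half-widths when the interval is asymmetric); then
#' `Var(z_add) = f^2 Var(A) + (1 - f)^2 Var(B)` and the interval is
#' `z_add +/- 1.96 * SE`.
#'
#' @param f Fractional multiplier in \[0, 1\].
#' @param fit_a,fit_b [ed50_estimate()] or `dose_response_fit` objects for
#'   the two components, carrying 95% CIs.
#' @return Named numeric `c(lower, upper)` in mg/kg, or `c(NA, NA)` when a
#'   component CI is missing.
#' @export
additive_ed50_ci <- function(f, fit_a, fit_b) {
  se_a <- se_from_ci95(fit_a)
  se_b <- se_from_ci95(fit_b)
  if (!is.finite(se_a) || !is.finite(se_b)) {
    return(c(lower = NA_real_, upper = NA_real_))
  }
  z_add <- additive_ed50(f, fit_a$ed50, fit_b$ed50)
  se <- sqrt(f^2 * se_a^2 + (1 - f)^2 * se_b^2)
  c(lower = z_add - 1.96 * se, upper = z_add + 1.96 * se)
}

#' Categorical isobolographic verdict from two confidence intervals
#'
#' Synergistic when the observed combination ED50's CI lies entirely below
#' the additive point's CI; antagonistic when entirely above; additive
#' otherwise (touching bounds count as overlap); indeterminate when either
#' CI is absent.
#'
#' @param z_obs_ci,z_add_ci Length-2 numeric `(lower, upper)` intervals in
#'   mg/kg for the observed and theoretical additive ED50.
#' @return One of `"synergistic"`, `"additive"`, `"antagonistic"`,
#'   `"indeterminate"`.
#' @export
isobologram_verdict <- function(z_obs_ci, z_add_ci) {
  if (length(z_obs_ci) != 2L || length(z_add_ci) != 2L) {
    stop_input("CIs must be length-2 (lower, upper)")
  }
  if (anyNA(z_obs_ci) || anyNA(z_add_ci) ||
      !all(is.finite(z_obs_ci)) || !all(is.finite(z_add_ci))) {
    return("indeterminate")
  }
  if (z_obs_ci[2] < z_add_ci[1]) return("synergistic")
  if (z_obs_ci[1] > z_add_ci[2]) return("antagonistic")
  "additive"
}

#' Full isobolographic analysis of a fixed-ratio combination
#'
#' Combines the single-drug fits, the mixture ratio, and the observed
#' combination fit (on the total mixture dose axis) into a verdict. Also
#' reports the interaction index `z_obs / z_add` as a continuous effect
#' size (< 1 synergy, 1 additivity, > 1 antagonism).
#'
#' @param fit_a,fit_b Single-drug [ed50_estimate()]/`dose_response_fit`
#'   objects (A is the drug in the numerator of the ratio).
#' @param fit_obs Fit of the combination arm on total mixture dose.
#' @param ratio Parts of A per part of B, > 0.
#' @return An object of class `isobologram_result`: `drug_a`, `drug_b`,
#'   `ratio`, `f`, `z_add`, `z_add_ci`, `z_obs`, `z_obs_ci`,
#'   `interaction_index`, `verdict`.
#' @examples
#' atx <- ed50_estimate(27.8, 22, 36, label = "atomoxetine")
#' mor <- ed50_estimate(2.3, 2.0, 2.5, label = "morphine")
#' obs <- ed50_estimate(2.4, 2.0, 3.0, label = "3:1 mixture")
#' isobologram(atx, mor, obs, ratio = 3)
#' @export
isobologram <- function(fit_a, fit_b, fit_obs, ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) || ratio <= 0) {
    stop_input("`ratio` must be a single number > 0")
  }
  f <- fractional_multiplier(ratio, fit_a$ed50, fit_b$ed50)
  z_add <- additive_ed50(f, fit_a$ed50, fit_b$ed50)
  z_add_ci <- additive_ed50_ci(f, fit_a, fit_b)
  z_obs <- fit_obs$ed50
  z_obs_ci <- if (has_ci(fit_obs)) {
    c(lower = fit_obs$ci95[["lower"]], upper = fit_obs$ci95[["upper"]])
  } else {
    c(lower = NA_real_, upper = NA_real_)
  }
  converged_obs <- is.null(fit_obs$converged) || isTRUE(fit_obs$converged)
  verdict <- if (!converged_obs) {
    "indeterminate"
  } else {
    isobologram_verdict(z_obs_ci, z_add_ci)
  }
  structure(
    list(
      drug_a = fit_a$drug_label, drug_b = fit_b$drug_label,
      ratio = ratio, f = f,
      z_add = z_add, z_add_ci = z_add_ci,
      z_obs = z_obs, z_obs_ci = z_obs_ci,
      interaction_index = z_obs / z_add,
      verdict = verdict
    ),
    class = "isobologram_result"
  )
}

#' @export
print.isobologram_result <- function(x, ...) {
  fmt_ci <- function(ci) {
    if (anyNA(ci)) "CI unavailable" else sprintf("%.3g-%.3g", ci[1], ci[2])
  }
  cat(sprintf("<isobologram_result> %s:%s at ratio %g:1\n",
              x$drug_a, x$drug_b, x$ratio))
  cat(sprintf("  F = %.4g\n", x$f))
  cat(sprintf("  additive ED50 = %.3g mg/kg (95%% CI: %s)\n",
              x$z_add, fmt_ci(x$z_add_ci)))
  cat(sprintf("  observed ED50 = %.3g mg/kg (95%% CI: %s)\n",
              x$z_obs, fmt_ci(x$z_obs_ci)))
  cat(sprintf("  interaction index = %.3g; verdict: %s\n",
              x$interaction_index, x$verdict))
  invisible(x)
}

#' Fixed-dose design: CI-based shift test between two dose-response fits
#'
#' A shift in ED50 with non-overlapping 95% confidence intervals is deemed
#' significant: `significant_leftward` when the adjunct fit's CI lies
#' entirely below the stand-alone fit's CI, `significant_rightward` for the
#' mirror case, `no_shift` otherwise, and `indeterminate` when a CI is
#' missing.
#'
#' @param fit_alone Fit of the drug dosed alone.
#' @param fit_with_adjunct Fit of the same drug in the presence of a fixed
#'   dose of the adjunct compound.
#' @return One of `"significant_leftward"`, `"significant_rightward"`,
#'   `"no_shift"`, `"indeterminate"`.
#' @examples
#' alone <- ed50_estimate(2.3, 2.0, 2.5, label = "morphine")
#' plus_atx <- ed50_estimate(0.6, 0.4, 0.8, label = "+atomoxetine 10")
#' fixed_dose_shift(alone, plus_atx)
#' @export
fixed_dose_shift <- function(fit_alone, fit_with_adjunct) {
  if (!has_ci(fit_alone) || !has_ci(fit_with_adjunct)) {
    return("indeterminate")
  }
  a <- fit_alone$ci95
  b <- fit_with_adjunct$ci95
  if (b[["upper"]] < a[["lower"]]) return("significant_leftward")
  if (b[["lower"]] > a[["upper"]]) return("significant_rightward")
  "no_shift"
}
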