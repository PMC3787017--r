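# In vitro transporter pharmacology: compound potency profiles, fold
# selectivity between NET and SERT, and total-to-unbound concentration
# conversion. Potencies are kept on the -log10 molar scale (pIC50/pKi)
# throughout; nothing here converts to nM.

#' Create an in vitro compound profile
#'
#' Bundles the uptake-inhibition potencies (pIC50) and, optionally, apparent
#' binding affinities (pKi) of one monoamine reuptake inhibitor at the
#' norepinephrine (NET) and serotonin (SERT) transporters, together with its
#' unbound fractions in plasma and brain homogenate.
#'
#' @param name Compound name.
#' @param pic50_sert,pic50_net Uptake-inhibition potencies, \eqn{-\log_{10}}
#'   molar. Must lie in \[3, 12\] (i.e. IC50 between 1 mM and 1 pM).
#' @param pki_sert,pki_net Optional apparent binding affinities, same scale
#'   and bounds.
#' @param fu_plasma,fu_brain Optional unbound fractions in rat plasma and
#'   brain homogenate, each in (0, 1].
#'
#' @return An object of class `compound_profile` (a named list).
#' @examples
#' atomoxetine <- compound_profile(
#'   "atomoxetine",
#'   pic50_sert = 7.1, pic50_net = 8.6,
#'   fu_plasma = 0.18, fu_brain = 0.021
#' )
#' selectivity_fold(atomoxetine$pic50_net, atomoxetine$pic50_sert)
#' @export
compound_profile <- function(name, pic50_sert, pic50_net,
                             pki_sert = NA_real_, pki_net = NA_real_,
                             fu_plasma = NA_real_, fu_brain = NA_real_) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_input("`name` must be a non-empty string")
  }
  check_potency <- function(x, nm) {
    if (is.na(x)) return(invisible(NULL))
    assert_number(x, nm)
    if (x < 3 || x > 12) {
      stop_input(sprintf("`%s` must lie in [3, 12] (-log10 M), got %g", nm, x))
    }
  }
  check_potency(pic50_sert, "pic50_sert")
  check_potency(pic50_net, "pic50_net")
  check_potency(pki_sert, "pki_sert")
  check_potency(pki_net, "pki_net")
  if (!is.na(fu_plasma)) assert_fraction(fu_plasma, "fu_plasma")
  if (!is.na(fu_brain)) assert_fraction(fu_brain, "fu_brain")
  structure(
    list(
      name = name,
      pic50_sert = pic50_sert, pic50_net = pic50_net,
      pki_sert = pki_sert, pki_net = pki_net,
      fu_plasma = fu_plasma, fu_brain = fu_brain
    ),
    class = "compound_profile"
  )
}

#' @export
print.compound_profile <- function(x, ...) {
  cat(sprintf("<compound_profile> %s\n", x$name))
  cat(sprintf("  pIC50  SERT %.2g  NET %.2g\n", x$pic50_sert, x$pic50_net))
  if (!is.na(x$pki_sert) || !is.na(x$pki_net)) {
    cat(sprintf("  pKi    SERT %.2g  NET %.2g\n", x$pki_sert, x$pki_net))
  }
  if (!is.na(x$fu_plasma) || !is.na(x$fu_brain)) {
    cat(sprintf("  fu     plasma %.3g  brain %.3g\n", x$fu_plasma, x$fu_brain))
  }
  sel <- selectivity_fold(x$pic50_net, x$pic50_sert)
  cat(sprintf("  selectivity: %g-fold %s\n", sel$fold, sel$preferred))
  invisible(x)
}

# Round a positive number to one significant figure, half away from zero on
# the leading digit (so 31.6 -> 30, 35 -> 40, 19953 -> 20000).
round_one_sig <- function(x) {
  stopifnot(all(is.finite(x)), all(x > 0))
  e <- floor(log10(x))
  m <- floor(x / 10^e + 0.5)
  carry <- m == 10
  m[carry] <- 1
  e[carry] <- e[carry] + 1
  m * 10^e
}

#' Transporter fold selectivity from pIC50 values
#'
#' Computes how many fold more potent a compound is at its preferred
#' transporter: \eqn{10^{|pIC50_{NET} - pIC50_{SERT}|}}, rounded to one
#' significant figure (half away from zero on the leading digit). The
#' preferred transporter is the one with the larger pIC50; equal potencies
#' give fold 1 and preference `"none"`.
#'
#' @param pic50_net,pic50_sert Potencies at NET and SERT, \eqn{-\log_{10}}
#'   molar. Vectors are recycled to a common length.
#'
#' @return A data frame with columns `fold` (numeric, >= 1) and `preferred`
#'   (`"NET"`, `"SERT"` or `"none"`), one row per input pair.
#' @examples
#' # esreboxetine: 20,000-fold NET-selective
#' selectivity_fold(9.6, 5.3)
#' # fluoxetine: 50-fold SERT-selective
#' selectivity_fold(6.1, 7.8)
#' @export
selectivity_fold <- function(pic50_net, pic50_sert) {
  if (!is.numeric(pic50_net) || !is.numeric(pic50_sert) ||
      anyNA(pic50_net) || anyNA(pic50_sert) ||
      !all(is.finite(pic50_net)) || !all(is.finite(pic50_sert))) {
    stop_input("`pic50_net` and `pic50_sert` must be finite numeric values")
  }
  n <- max(length(pic50_net), length(pic50_sert))
  net <- rep_len(pic50_net, n)
  sert <- rep_len(pic50_sert, n)
  delta <- net - sert
  fold <- ifelse(delta == 0, 1, round_one_sig(10^abs(delta)))
  preferred <- ifelse(delta > 0, "NET", ifelse(delta < 0, "SERT", "none"))
  data.frame(fold = fold, preferred = preferred)
}

#' Unbound (free) drug concentration
#'
#' Converts a total plasma or brain concentration to the unbound
#' concentration using the in vitro unbound fraction measured by equilibrium
#' dialysis: `unbound = total * fu`.
#'
#' @param total Total concentration (ng/mL plasma or ng/g brain); must be
#'   non-negative. Vectorized.
#' @param fu Unbound fraction, in (0, 1].
#'
#' @return Unbound concentration in the same units as `total`.
#' @examples
#' unbound_concentration(100, 0.25)
#' @export
unbound_concentration <- function(total, fu) {
  if (!is.numeric(total) || anyNA(total) || any(total < 0)) {
    stop_input("`total` must be non-negative numeric")
  }
  assert_fraction(fu, "fu")
  total * fu
}

#' Read compound profiles from CSV
#'
#' Expects columns `name, pic50_sert, pic50_net, pki_sert, pki_net,
#' fu_plasma, fu_brain`; optional values may be blank.
#'
#' @param path Path to the CSV file.
#' @return A list of [compound_profile()] objects, named by compound.
#' @export
read_compound_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("name", "pic50_sert", "pic50_net"), "compound CSV")
  opt <- function(col, i) {
    if (col %in% names(df) && !is.na(df[[col]][i])) df[[col]][i] else NA_real_
  }
  profiles <- lapply(seq_len(nrow(df)), function(i) {
    compound_profile(
      name = df$name[i],
      pic50_sert = df$pic50_sert[i], pic50_net = df$pic50_net[i],
      pki_sert = opt("pki_sert", i), pki_net = opt("pki_net", i),
      fu_plasma = opt("fu_plasma", i), fu_brain = opt("fu_brain", i)
    )
  })
  names(profiles) <- df$name
  profiles
}
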