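# Synthetic-data generators with known ground truth. Per-animal phase-2A
# flinch totals are drawn negative-binomial (overdispersed Poisson; animal-
# to-animal variability in this assay is large) around group means that
# follow the constrained sigmoid, and radioligand time courses are straight
# lines whose slopes carry multiplicative lognormal noise. Everything is
# deterministic under a fixed seed and round-trips through the behavior and
# occupancy modules unchanged.

#' Configuration for the synthetic-data generators
#'
#' @param seed Integer RNG seed; the generators call [set.seed()] with it.
#' @param true_ed50 Ground-truth ED50 in mg/kg (alternative to
#'   `true_log_ed50`; exactly one must be given).
#' @param true_log_ed50 Ground-truth log10 ED50.
#' @param true_hill Ground-truth Hill slope, default 1.5 (typical steepness
#'   of formalin-test dose-response curves).
#' @param vehicle_mean_flinches Mean phase-2A flinch total of vehicle
#'   animals, default 150.
#' @param dispersion Negative-binomial size parameter, default 10 (smaller
#'   is more overdispersed; 10 gives group SEMs of the magnitude seen in
#'   formalin-test figures at n = 8).
#' @param n_per_group Animals per dose group (and per vehicle group),
#'   default 8.
#' @param doses Dose levels in mg/kg; default a 4-point geometric series
#'   around the true ED50 (`true_ed50 * c(0.125, 0.5, 2, 8)`), spanning
#'   about 4% to 96% predicted inhibition at the default Hill slope.
#' @param interaction_index Multiplier applied to the Loewe-additive ED50
#'   when generating combination arms; 1 = exactly additive, < 1 synergy.
#' @param occupancy_noise_cv Coefficient of variation of the multiplicative
#'   slope noise in binding time courses, default 0.1.
#' @param drug Drug label used in arm annotations.
#' @param session Session label (one generated experiment = one session).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             true_ed50 = NULL, true_log_ed50 = NULL,
                             true_hill = 1.5,
                             vehicle_mean_flinches = 150,
                             dispersion = 10,
                             n_per_group = 8L,
                             doses = NULL,
                             interaction_index = 1,
                             occupancy_noise_cv = 0.1,
                             drug = "drugA",
                             session = "S1") {
  if (is.null(true_log_ed50)) {
    if (is.null(true_ed50)) stop_input("give `true_ed50` or `true_log_ed50`")
    assert_number(true_ed50)
    if (true_ed50 <= 0) stop_input("`true_ed50` must be > 0")
    true_log_ed50 <- log10(true_ed50)
  }
  assert_number(true_log_ed50)
  true_ed50 <- 10^true_log_ed50
  assert_number(true_hill)
  if (true_hill <= 0) stop_input("`true_hill` must be > 0")
  if (vehicle_mean_flinches < 1) stop_input("`vehicle_mean_flinches` must be >= 1")
  if (dispersion <= 0) stop_input("`dispersion` must be > 0")
  if (n_per_group < 1) stop_input("`n_per_group` must be >= 1")
  if (interaction_index <= 0) stop_input("`interaction_index` must be > 0")
  if (occupancy_noise_cv < 0) stop_input("`occupancy_noise_cv` must be >= 0")
  if (is.null(doses)) doses <- true_ed50 * c(0.125, 0.5, 2, 8)
  if (any(doses <= 0)) stop_input("`doses` must be > 0")
  structure(
    list(
      seed = as.integer(seed),
      true_ed50 = true_ed50, true_log_ed50 = true_log_ed50,
      true_hill = true_hill,
      vehicle_mean_flinches = vehicle_mean_flinches,
      dispersion = dispersion,
      n_per_group = as.integer(n_per_group),
      doses = doses,
      interaction_index = interaction_index,
      occupancy_noise_cv = occupancy_noise_cv,
      drug = drug, session = session
    ),
    class = "generator_config"
  )
}

# Negative-binomial flinch totals for one group. The group mean is the
# vehicle mean scaled by (1 - E/100); E near 100 gives counts near zero.
rnb_flinches <- function(n, expected_inhibition, config) {
  mu <- config$vehicle_mean_flinches * (1 - expected_inhibition / 100)
  mu <- max(mu, 1e-9)
  stats::rnbinom(n, size = config$dispersion, mu = mu)
}

flinch_rows <- function(ids, arm, drug1, dose1, drug2, dose2, flinches,
                        session) {
  data.frame(
    session = session, animal_id = ids, arm = arm,
    drug1 = drug1, dose1_mg_kg = dose1,
    drug2 = drug2, dose2_mg_kg = dose2,
    bin_start_min = 15, bin_end_min = 40,
    flinches = as.integer(flinches),
    stringsAsFactors = FALSE
  )
}

#' Generate a single-drug formalin experiment
#'
#' One session with a vehicle group and one group per dose level. Each
#' animal contributes a single phase-2A bin (15-40 min) whose flinch total
#' is negative-binomial around the sigmoid-predicted group mean.
#'
#' @param config A [generator_config()].
#' @return A [flinch_data()] dataset (arms: `"vehicle"` and the configured
#'   drug label).
#' @examples
#' cfg <- generator_config(seed = 42, true_ed50 = 2.3, doses = c(0.3, 1, 3, 10))
#' dat <- gen_single_drug(cfg)
#' head(percent_inhibition_table(dat))
#' @export
gen_single_drug <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_per_group
  veh <- flinch_rows(
    sprintf("veh_%02d", seq_len(n)), "vehicle", "vehicle", 0,
    NA_character_, NA_real_,
    rnb_flinches(n, 0, config), config$session
  )
  groups <- lapply(seq_along(config$doses), function(j) {
    d <- config$doses[j]
    e <- predict_inhibition(d, config$true_log_ed50, config$true_hill)
    flinch_rows(
      sprintf("%s_d%d_%02d", config$drug, j, seq_len(n)),
      config$drug, config$drug, d, NA_character_, NA_real_,
      rnb_flinches(n, e, config), config$session
    )
  })
  flinch_data(do.call(rbind, c(list(veh), groups)))
}

#' Generate a fixed-ratio combination experiment
#'
#' One session containing a shared vehicle group, full dose-response groups
#' for each drug alone (at each config's own doses and true parameters),
#' and a fixed-ratio combination arm dosed on total mixture dose. The
#' combination's true total-dose ED50 is
#' `interaction_index * additive_ed50(f, ED50_A, ED50_B)` with `f` from the
#' mixture ratio, so `interaction_index = 1` generates exact Loewe
#' additivity; its Hill slope is the mean of the two component slopes
#' unless `combo_hill` is given.
#'
#' @param config_a,config_b [generator_config()]s for drugs A and B (A is
#'   the numerator of the ratio). `config_a` supplies the seed, session,
#'   vehicle mean, dispersion and per-group n.
#' @param ratio Parts of A per part of B, > 0.
#' @param interaction_index Deviation from additivity (default
#'   `config_a$interaction_index`).
#' @param combo_hill Hill slope of the combination curve.
#' @param combo_doses Total-dose levels for the combination arm; default a
#'   geometric series around the additive prediction
#'   (`z_add * c(0.125, 0.5, 2, 8)`), i.e. the design an experimenter
#'   blind to the interaction would choose.
#' @return A [flinch_data()] dataset with arms `"vehicle"`, the two drug
#'   labels, and `"<A>+<B>"` for the combination.
#' @export
gen_fixed_ratio <- function(config_a, config_b, ratio,
                            interaction_index = NULL,
                            combo_hill = NULL, combo_doses = NULL) {
  stopifnot(inherits(config_a, "generator_config"),
            inherits(config_b, "generator_config"))
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0) {
    stop_input("`ratio` must be a single number > 0")
  }
  interaction_index <- interaction_index %||% config_a$interaction_index
  if (interaction_index <= 0) stop_input("`interaction_index` must be > 0")
  combo_hill <- combo_hill %||% mean(c(config_a$true_hill, config_b$true_hill))

  ed50_a <- config_a$true_ed50
  ed50_b <- config_b$true_ed50
  f <- fractional_multiplier(ratio, ed50_a, ed50_b)
  z_add <- additive_ed50(f, ed50_a, ed50_b)
  z_true <- interaction_index * z_add
  if (is.null(combo_doses)) combo_doses <- z_add * c(0.125, 0.5, 2, 8)

  set.seed(config_a$seed)
  n <- config_a$n_per_group
  session <- config_a$session
  base <- config_a  # vehicle mean & dispersion shared across the session

  veh <- flinch_rows(
    sprintf("veh_%02d", seq_len(n)), "vehicle", "vehicle", 0,
    NA_character_, NA_real_,
    rnb_flinches(n, 0, base), session
  )
  single <- function(cfg, tag) {
    do.call(rbind, lapply(seq_along(cfg$doses), function(j) {
      d <- cfg$doses[j]
      e <- predict_inhibition(d, cfg$true_log_ed50, cfg$true_hill)
      flinch_rows(
        sprintf("%s_d%d_%02d", tag, j, seq_len(n)),
        cfg$drug, cfg$drug, d, NA_character_, NA_real_,
        rnb_flinches(n, e, base), session
      )
    }))
  }
  arm_a <- single(config_a, "A")
  arm_b <- single(config_b, "B")

  combo_label <- paste0(config_a$drug, "+", config_b$drug)
  combo <- do.call(rbind, lapply(seq_along(combo_doses), function(j) {
    total <- combo_doses[j]
    dose_a <- total * ratio / (1 + ratio)
    dose_b <- total / (1 + ratio)
    e <- predict_inhibition(total, log10(z_true), combo_hill)
    flinch_rows(
      sprintf("AB_d%d_%02d", j, seq_len(n)),
      combo_label, config_a$drug, dose_a, config_b$drug, dose_b,
      rnb_flinches(n, e, base), session
    )
  }))
  flinch_data(rbind(veh, arm_a, arm_b, combo))
}

#' Generate radioligand binding time courses with known occupancy
#'
#' Vehicle animals bind at base rate `v0`; an animal with true occupancy
#' theta binds at `v0 * (1 - theta/100)`. Every animal's slope carries
#' multiplicative lognormal noise with mean 1 and coefficient of variation
#' `config$occupancy_noise_cv`; signals are read at 0, 1, 2 and 3 minutes
#' on a straight line over a constant assay background.
#'
#' @param config A [generator_config()] (supplies seed, per-group n and
#'   noise CV).
#' @param true_occupancy_by_arm Named numeric vector of true occupancies
#'   (percent, <= 100), one per treatment arm. A `"vehicle"` arm at 0% is
#'   added automatically if absent.
#' @param transporter `"NET"` or `"SERT"`.
#' @param v0 Vehicle initial rate, signal/min.
#' @param baseline Time-zero background signal.
#' @return A [binding_data()] dataset.
#' @examples
#' cfg <- generator_config(seed = 7, true_ed50 = 1)
#' b <- gen_binding(cfg, c(esreboxetine_10 = 82), transporter = "NET")
#' summarize_occupancy(occupancy_table(b))
#' @export
gen_binding <- function(config, true_occupancy_by_arm,
                        transporter = "NET", v0 = 50, baseline = 5) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(names(true_occupancy_by_arm)) ||
      any(!nzchar(names(true_occupancy_by_arm)))) {
    stop_input("`true_occupancy_by_arm` must be a named vector")
  }
  if (any(true_occupancy_by_arm > 100)) {
    stop_input("occupancies must be <= 100")
  }
  if (!"vehicle" %in% names(true_occupancy_by_arm)) {
    true_occupancy_by_arm <- c(vehicle = 0, true_occupancy_by_arm)
  }
  set.seed(config$seed)
  n <- config$n_per_group
  cv <- config$occupancy_noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  times <- 0:3
  rows <- lapply(names(true_occupancy_by_arm), function(arm) {
    theta <- true_occupancy_by_arm[[arm]]
    noise <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    slopes <- pmax(v0 * (1 - theta / 100), 0) * noise
    do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(
        session = config$session,
        animal_id = sprintf("%s_%02d", arm, i),
        arm = arm, transporter = transporter,
        time_min = times,
        signal = baseline + slopes[i] * times,
        stringsAsFactors = FALSE
      )
    }))
  })
  binding_data(do.call(rbind, rows))
}
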