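# Ex vivo transporter occupancy from radioligand binding time courses.
# Occupancy in a dosed animal is inferred from the slowing of the initial
# binding rate of the transporter-selective radioligand relative to the
# average rate in concurrently run vehicle animals:
#
#   occupancy% = 100 * (1 - v_i / mean(v_vehicle))

#' Construct a validated binding dataset
#'
#' Holds radioligand binding time courses measured in cortical homogenates:
#' one bound-signal reading per time point per animal and transporter. The
#' assay reads association over the first 3 minutes, where binding is
#' approximately linear in time (initial-rate regime).
#'
#' @param df A data frame with columns `session`, `animal_id`, `arm`,
#'   `transporter` (`"NET"` or `"SERT"`), `time_min`, `signal`.
#' @return The data frame with class `binding_data` prepended.
#' @export
binding_data <- function(df) {
  req <- c("session", "animal_id", "arm", "transporter", "time_min", "signal")
  assert_columns(df, req, "binding dataset")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(df$transporter %in% c("NET", "SERT"))) {
    stop_input("`transporter` must be 'NET' or 'SERT'")
  }
  if (any(is.na(df$signal)) || any(df$signal < 0)) {
    stop_input("`signal` must be non-negative")
  }
  if (any(is.na(df$time_min)) || any(df$time_min < 0)) {
    stop_input("`time_min` must be >= 0")
  }
  key <- interaction(df$session, df$animal_id, df$transporter, drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k)
    t <- df$time_min[idx]
    if (length(t) < 2L) {
      stop_input(sprintf(
        "animal '%s' (%s) has fewer than 2 time points",
        df$animal_id[idx[1]], df$transporter[idx[1]]
      ))
    }
    if (anyDuplicated(t)) {
      stop_input(sprintf(
        "animal '%s' (%s) has duplicated time points",
        df$animal_id[idx[1]], df$transporter[idx[1]]
      ))
    }
  }
  class(df) <- c("binding_data", "data.frame")
  df
}

#' Initial binding rate from a time course
#'
#' Slope of the ordinary least-squares line through (time, signal) points,
#' with a free intercept (a nonzero time-zero background is plausible in
#' homogenate filtration assays); set `origin = TRUE` to force the line
#' through the origin. Negative slopes, which can only arise from noise in
#' an association assay, are floored at 0 with a warning.
#'
#' @param time_min Times in minutes (>= 2 distinct values).
#' @param signal Bound-radioligand signal, arbitrary units.
#' @param origin Force the regression through the origin?
#' @return Initial rate v_i in signal units per minute, >= 0.
#' @examples
#' initial_rate(0:3, c(0, 9, 21, 30))  # 10.2
#' @export
initial_rate <- function(time_min, signal, origin = FALSE) {
  if (length(time_min) < 2L || length(time_min) != length(signal)) {
    stop_input("need >= 2 (time, signal) points of equal length")
  }
  fit <- if (origin) {
    stats::lm(signal ~ 0 + time_min)
  } else {
    stats::lm(signal ~ time_min)
  }
  v <- unname(stats::coef(fit)[["time_min"]])
  if (v < 0) {
    warning("negative initial rate floored at 0", call. = FALSE)
    v <- 0
  }
  v
}

#' Percent transporter occupancy from initial rates
#'
#' Vehicle-normalized occupancy: `100 * (1 - v_i / mean(vehicle_rates))`.
#' Equals 0 when the animal's rate matches the vehicle average and 100 when
#' binding is completely blocked. Values may be negative from noise and are
#' not clipped. The archival form `100 * (1 - v_i) / mean(vehicle_rates)`,
#' which is not scale-invariant, is available behind `literal = TRUE` for
#' fidelity to older report sheets.
#'
#' @param v_i Initial rate(s) of dosed animals, signal/min. Vectorized.
#' @param vehicle_rates Initial rates of the vehicle animals (non-empty,
#'   positive mean).
#' @param literal Use the literal non-normalized form (not recommended).
#' @return Percent occupancy (<= 100, possibly negative).
#' @export
occupancy_percent <- function(v_i, vehicle_rates, literal = FALSE) {
  if (!is.numeric(v_i) || anyNA(v_i) || any(v_i < 0)) {
    stop_input("`v_i` must be non-negative numeric")
  }
  if (!is.numeric(vehicle_rates) || length(vehicle_rates) == 0L ||
      anyNA(vehicle_rates)) {
    stop_input("`vehicle_rates` must be a non-empty numeric vector")
  }
  vbar <- mean(vehicle_rates)
  if (vbar <= 0) stop_input("vehicle mean rate must be > 0")
  if (literal) {
    return(100 * (1 - v_i) / vbar)
  }
  100 * (1 - v_i / vbar)
}

#' Per-animal occupancy table for a binding dataset
#'
#' Computes each animal's initial rate and its percent occupancy relative
#' to the vehicle animals of the same transporter. Normalization is per
#' session by default, mirroring the concurrent-vehicle normalization of
#' the behavioral readout; set `per_session = FALSE` to pool vehicle
#' animals across sessions.
#'
#' @param data A [binding_data()] object.
#' @param vehicle_arm Label of the vehicle arm.
#' @param per_session Normalize within session (default) or pooled.
#' @param origin Passed to [initial_rate()].
#' @return A data frame with one row per animal x transporter: `session`,
#'   `animal_id`, `arm`, `transporter`, `v_i`, `occupancy_pct`.
#' @export
occupancy_table <- function(data, vehicle_arm = "vehicle",
                            per_session = TRUE, origin = FALSE) {
  data <- binding_data(data)
  key <- interaction(data$session, data$animal_id, data$transporter,
                     drop = TRUE)
  rates <- do.call(rbind, lapply(split(seq_len(nrow(data)), key), function(idx) {
    d <- data[idx, , drop = FALSE]
    data.frame(
      session = d$session[1], animal_id = d$animal_id[1], arm = d$arm[1],
      transporter = d$transporter[1],
      v_i = initial_rate(d$time_min, d$signal, origin = origin),
      stringsAsFactors = FALSE
    )
  }))
  grp <- if (per_session) {
    interaction(rates$session, rates$transporter, drop = TRUE)
  } else {
    factor(rates$transporter)
  }
  out <- do.call(rbind, lapply(split(rates, grp), function(d) {
    veh <- d$v_i[d$arm == vehicle_arm]
    if (length(veh) == 0L) {
      stop_input(sprintf(
        "no '%s' animals for transporter %s%s: cannot normalize",
        vehicle_arm, d$transporter[1],
        if (per_session) sprintf(" in session '%s'", d$session[1]) else ""
      ))
    }
    d$occupancy_pct <- occupancy_percent(d$v_i, veh)
    d
  }))
  rownames(out) <- NULL
  out
}

#' Mean and SEM occupancy per arm and transporter
#'
#' @param occ Output of [occupancy_table()].
#' @return A data frame with `arm`, `transporter`, `n`, `mean_occupancy_pct`,
#'   `sem_occupancy_pct` (SEM `NA` when n = 1).
#' @export
summarize_occupancy <- function(occ) {
  assert_columns(occ, c("arm", "transporter", "occupancy_pct"),
                 "occupancy table")
  grp <- interaction(occ$arm, occ$transporter, drop = TRUE)
  out <- do.call(rbind, lapply(split(occ, grp), function(d) {
    s <- summarize_arm(d$occupancy_pct)
    data.frame(
      arm = d$arm[1], transporter = d$transporter[1], n = s$n,
      mean_occupancy_pct = s$mean_pct, sem_occupancy_pct = s$sem_pct,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
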