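# Behavioral scoring for the formalin test: time-binned flinch counts per
# animal are reduced to phase-2A totals (15-40 min post-formalin), normalized
# against the concurrent vehicle group, and summarized per treatment arm.

#' Construct a validated flinch dataset
#'
#' A flinch dataset holds per-animal, time-binned flinch counts from the rat
#' formalin test, with treatment arm and dose annotations. Combination arms
#' carry a second drug/dose column pair. Each row is one time bin for one
#' animal; bins for a single animal must be non-overlapping.
#'
#' @param df A data frame with columns `session`, `animal_id`, `arm`,
#'   `drug1`, `dose1_mg_kg`, `bin_start_min`, `bin_end_min`, `flinches`, and
#'   optionally `drug2`, `dose2_mg_kg` for combination arms.
#'
#' @return The data frame, validated, with class `flinch_data` prepended.
#' @export
flinch_data <- function(df) {
  req <- c("session", "animal_id", "arm", "drug1", "dose1_mg_kg",
           "bin_start_min", "bin_end_min", "flinches")
  assert_columns(df, req, "flinch dataset")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"drug2" %in% names(df)) df$drug2 <- NA_character_
  if (!"dose2_mg_kg" %in% names(df)) df$dose2_mg_kg <- NA_real_
  # stable column types (all-NA CSV columns come back logical otherwise)
  for (col in c("session", "animal_id", "arm", "drug1", "drug2")) {
    df[[col]] <- as.character(df[[col]])
  }
  for (col in c("dose1_mg_kg", "dose2_mg_kg", "bin_start_min",
                "bin_end_min")) {
    df[[col]] <- as.numeric(df[[col]])
  }

  bad_row <- function(i, msg) {
    stop_input(sprintf("flinch dataset row %d: %s", i, msg))
  }
  for (i in seq_len(nrow(df))) {
    fl <- df$flinches[i]
    if (is.na(fl) || fl < 0 || fl != round(fl)) {
      bad_row(i, sprintf("`flinches` must be a non-negative integer, got %s", fl))
    }
    if (is.na(df$bin_start_min[i]) || is.na(df$bin_end_min[i]) ||
        df$bin_start_min[i] >= df$bin_end_min[i]) {
      bad_row(i, "requires bin_start_min < bin_end_min")
    }
    d1 <- df$dose1_mg_kg[i]
    if (is.na(d1) || d1 < 0) bad_row(i, "`dose1_mg_kg` must be >= 0")
  }
  # non-overlapping bins within each animal
  key <- interaction(df$session, df$animal_id, drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k)
    o <- idx[order(df$bin_start_min[idx])]
    if (length(o) > 1L) {
      starts <- df$bin_start_min[o]
      ends <- df$bin_end_min[o]
      ov <- which(starts[-1] < ends[-length(ends)])
      if (length(ov) > 0L) {
        stop_input(sprintf(
          "flinch dataset row %d: overlapping time bins for animal '%s'",
          o[ov[1] + 1L], df$animal_id[o[1]]
        ))
      }
    }
  }
  class(df) <- c("flinch_data", "data.frame")
  df
}

#' Phase-2A flinch total for one animal
#'
#' Sums flinch counts over the bins intersecting the phase-2A window,
#' apportioning partial bins proportionally to their overlap with the
#' window. The window is half-open, `[start, end)`, so counts at a shared
#' bin edge are never double-counted; the default window is the 15-40 min
#' post-formalin antinociceptive period.
#'
#' @param bin_start,bin_end Bin boundaries (min post-formalin), one pair per
#'   bin.
#' @param flinches Flinch count per bin.
#' @param window Length-2 numeric, the scoring window in minutes.
#'
#' @return The (possibly fractional) flinch total over the window.
#' @examples
#' phase2a_total(c(0, 15, 40), c(15, 40, 60), c(200, 80, 10))  # 80
#' phase2a_total(c(10, 20), c(20, 40), c(50, 60))              # 85
#' @export
phase2a_total <- function(bin_start, bin_end, flinches, window = c(15, 40)) {
  if (length(window) != 2L || !is.numeric(window) || window[1] >= window[2]) {
    stop_input("`window` must be c(start, end) with start < end")
  }
  if (length(bin_start) != length(bin_end) ||
      length(bin_start) != length(flinches)) {
    stop_input("`bin_start`, `bin_end`, `flinches` must have equal length")
  }
  overlap <- pmax(0, pmin(bin_end, window[2]) - pmax(bin_start, window[1]))
  if (all(overlap == 0)) {
    stop_input(sprintf(
      "no bins intersect the [%g, %g) window: missing data", window[1], window[2]
    ))
  }
  if (sum(overlap) < diff(window) - 1e-9) {
    warning(sprintf(
      "bins cover only %g of the %g min window; total is a partial count",
      sum(overlap), diff(window)
    ), call. = FALSE)
  }
  sum(flinches * overlap / (bin_end - bin_start))
}

#' Per-animal phase-2A totals for a whole dataset
#'
#' @param data A [flinch_data()] object.
#' @inheritParams phase2a_total
#' @return A data frame with one row per animal: `session`, `animal_id`,
#'   `arm`, drug/dose annotations, `total_dose_mg_kg` (sum of component
#'   doses) and `total_flinches`.
#' @export
phase2a_totals <- function(data, window = c(15, 40)) {
  data <- flinch_data(data)
  key <- interaction(data$session, data$animal_id, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(data)), key), function(idx) {
    d <- data[idx, , drop = FALSE]
    dose2 <- d$dose2_mg_kg[1]
    data.frame(
      session = d$session[1], animal_id = d$animal_id[1], arm = d$arm[1],
      drug1 = d$drug1[1], dose1_mg_kg = d$dose1_mg_kg[1],
      drug2 = d$drug2[1], dose2_mg_kg = dose2,
      total_dose_mg_kg = d$dose1_mg_kg[1] + ifelse(is.na(dose2), 0, dose2),
      total_flinches = phase2a_total(
        d$bin_start_min, d$bin_end_min, d$flinches, window
      ),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percent inhibition of flinching
#'
#' Vehicle-normalized antinociceptive effect:
#' `100 * (vehicle_mean - treatment_total) / vehicle_mean`. Values may be
#' negative (hyperalgesia relative to vehicle) and are deliberately not
#' clipped; the dose-response model, not the data, carries the 0-100
#' constraint.
#'
#' @param treatment_total Phase-2A flinch total(s) for treated animals
#'   (vectorized), each >= 0.
#' @param vehicle_mean Mean phase-2A total of the concurrent vehicle group;
#'   must be > 0.
#' @return Percent inhibition (may be negative, not clipped).
#' @export
percent_inhibition <- function(treatment_total, vehicle_mean) {
  assert_number(vehicle_mean)
  if (vehicle_mean <= 0) {
    stop_input("`vehicle_mean` must be > 0: normalization undefined")
  }
  if (!is.numeric(treatment_total) || any(is.na(treatment_total)) ||
      any(treatment_total < 0)) {
    stop_input("`treatment_total` must be non-negative numeric")
  }
  100 * (vehicle_mean - treatment_total) / vehicle_mean
}

#' Per-animal percent-inhibition table
#'
#' Reduces a flinch dataset to one row per animal with its phase-2A total
#' and percent inhibition relative to the concurrently tested vehicle group.
#' Normalization is per session: each treatment animal is compared to the
#' mean phase-2A total of the vehicle animals of its own session.
#'
#' @param data A [flinch_data()] object.
#' @param window Scoring window in minutes, default the phase-2A 15-40 min.
#' @param vehicle_arm Label of the vehicle arm, default `"vehicle"`.
#' @return The [phase2a_totals()] data frame with extra columns
#'   `vehicle_mean` and `pct_inhibition`. Vehicle animals are retained
#'   (their expected percent inhibition is 0).
#' @export
percent_inhibition_table <- function(data, window = c(15, 40),
                                     vehicle_arm = "vehicle") {
  totals <- phase2a_totals(data, window)
  out <- lapply(split(totals, totals$session), function(d) {
    veh <- d$total_flinches[d$arm == vehicle_arm]
    if (length(veh) == 0L) {
      stop_input(sprintf(
        "session '%s' has no '%s' arm: cannot normalize", d$session[1], vehicle_arm
      ))
    }
    vm <- mean(veh)
    d$vehicle_mean <- vm
    d$pct_inhibition <- percent_inhibition(d$total_flinches, vm)
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mean and SEM of per-animal percent inhibition
#'
#' @param pct Numeric vector of per-animal percent-inhibition values (one
#'   arm), length >= 1.
#' @return A list with `n`, `mean_pct` and `sem_pct`; `sem_pct` is `NA` for a
#'   single animal (a one-animal SEM is undefined, not zero).
#' @export
summarize_arm <- function(pct) {
  if (!is.numeric(pct) || length(pct) == 0L || anyNA(pct)) {
    stop_input("`pct` must be a non-empty numeric vector without NA")
  }
  n <- length(pct)
  sem <- if (n > 1L) stats::sd(pct) / sqrt(n) else NA_real_
  list(n = n, mean_pct = mean(pct), sem_pct = sem)
}

#' Group summaries for every arm of a percent-inhibition table
#'
#' @param pct_table Output of [percent_inhibition_table()].
#' @return A data frame with one row per arm: `arm`, `n`,
#'   `mean_pct_inhibition`, `sem_pct_inhibition`.
#' @export
summarize_arms <- function(pct_table) {
  assert_columns(pct_table, c("arm", "pct_inhibition"), "percent-inhibition table")
  rows <- lapply(split(pct_table, pct_table$arm), function(d) {
    s <- summarize_arm(d$pct_inhibition)
    data.frame(
      arm = d$arm[1], n = s$n,
      mean_pct_inhibition = s$mean_pct,
      sem_pct_inhibition = s$sem_pct,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
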