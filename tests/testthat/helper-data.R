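# Small in-code fixtures shared across test files.

# A minimal two-session flinch dataset: one vehicle + one treated animal per
# session, one exact phase-2A bin each.
make_small_flinch <- function() {
  flinch_data(data.frame(
    session = c("S1", "S1", "S1", "S2", "S2"),
    animal_id = c("v1", "v2", "t1", "v1", "t1"),
    arm = c("vehicle", "vehicle", "drugX", "vehicle", "drugX"),
    drug1 = c("vehicle", "vehicle", "drugX", "vehicle", "drugX"),
    dose1_mg_kg = c(0, 0, 3, 0, 3),
    bin_start_min = 15, bin_end_min = 40,
    flinches = c(100L, 120L, 55L, 200L, 100L),
    stringsAsFactors = FALSE
  ))
}

# Paper-entered ED50 estimates used by the synergy worked examples.
atx_alone <- function() ed50_estimate(27.8, 22, 36, label = "atomoxetine")
mor_alone <- function() ed50_estimate(2.3, 2.0, 2.5, label = "morphine")
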