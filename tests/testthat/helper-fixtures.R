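# shared fixtures, built once per test run

the_bundle <- make_fixture_bundle("DR-like", 1)

zero_lifetable <- make_lifetable("zero")
flat_survival <- make_stage_survival(1)

# parameters with every disease transition switched off
null_params <- nh_params(list(
  adenoma_onset = 0, lr_to_hr = 0, hr_to_preclin = 0,
  local_to_regional = 0, regional_to_distant = 0,
  detect_local = 0, detect_regional = 0, detect_distant = 0))

# quick constructor for a hand-built trace (economics tests)
hand_trace <- function(events, persons, n = nrow(persons),
                       entry_age = 20, horizon_age = 100) {
  structure(list(events = events, persons = persons,
                 occupancy = NULL,
                 config = cohort_config(n, entry_age, horizon_age, seed = 1),
                 strategy = NULL),
            class = "crc_trace")
}

empty_events <- tibble::tibble(person = integer(), age_months = integer(),
                               event = character(), detail = character())

person_row <- function(person = 1L, death_age_months = NA, dx_age_months = NA,
                       dx_stage = NA_character_, death_type = "alive") {
  tibble::tibble(person = person, final_state = "Healthy",
                 death_age_months = death_age_months,
                 death_type = death_type,
                 dx_age_months = dx_age_months, dx_stage = dx_stage)
}
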