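#' Disease states of the natural-history model
#'
#' The model follows the adenoma-carcinoma sequence: individuals enter free of
#' adenomas, may develop a low-risk (<10 mm) adenoma, which may progress to a
#' high-risk (>=10 mm) adenoma and then to preclinical (undiagnosed) invasive
#' cancer. Preclinical cancer progresses in stage (local, regional, distant)
#' and may surface clinically through symptoms, with the chance of symptomatic
#' detection rising with stage. Death from other causes is possible from every
#' living state; cancer-specific death only from diagnosed (clinical) states.
#'
#' `crc_states()` returns the canonical state labels in model order; the
#' integer codes 0-10 in this order are used throughout the package and in the
#' compiled simulation core.
#'
#' @return Character vector of the 11 state labels.
#' @export
crc_states <- function() {
  c("Healthy", "AdenomaLR", "AdenomaHR",
    "PreclinLocal", "PreclinRegional", "PreclinDistant",
    "ClinLocal", "ClinRegional", "ClinDistant",
    "DeathCRC", "DeathOther")
}

# integer codes used by the compiled core (0-based)
.state_code <- function(label) match(label, crc_states()) - 1L

.STAGES <- c("local", "regional", "distant")

#' Natural-history parameter names
#'
#' The eight age-banded monthly transition probabilities the calibration
#' fits and the simulation consumes.
#'
#' @return Character vector of parameter names.
#' @export
nh_param_names <- function() {
  c("adenoma_onset", "lr_to_hr", "hr_to_preclin",
    "local_to_regional", "regional_to_distant",
    "detect_local", "detect_regional", "detect_distant")
}

# event codes emitted by the compiled core
.EVENT_LEVELS <- c(
  "adenoma_onset",       # 1  Healthy -> AdenomaLR
  "adenoma_progression", # 2  AdenomaLR -> AdenomaHR
  "preclin_onset",       # 3  AdenomaHR -> PreclinLocal
  "stage_transition",    # 4  preclinical local->regional / regional->distant
  "symptomatic_dx",      # 5  preclinical -> clinical via symptoms
  "screen_dx",           # 6  preclinical -> clinical via screening
  "test_performed",      # 7
  "complication",        # 8
  "polypectomy",         # 9  adenoma removed at colonoscopy
  "death_crc",           # 10
  "death_other",         # 11
  "positive_test"        # 12 positive first-line (non-colonoscopy) test
)

.MODALITIES <- c("colonoscopy", "sigmoidoscopy", "fit", "fobt")
.REASONS <- c("screening", "followup", "surveillance", "diagnostic")

# detail code for test/complication events: modality*10 + reason (0-based)
.decode_detail <- function(event, detail) {
  out <- rep(NA_character_, length(event))
  is_test <- event %in% c("test_performed", "complication")
  out[is_test] <- paste(.MODALITIES[detail[is_test] %/% 10 + 1],
                        .REASONS[detail[is_test] %% 10 + 1], sep = "_")
  is_stage <- event %in% c("symptomatic_dx", "screen_dx", "stage_transition")
  out[is_stage] <- .STAGES[detail[is_stage]]
  is_poly <- event == "polypectomy"
  out[is_poly] <- c("LR", "HR")[detail[is_poly]]
  is_pos <- event == "positive_test"
  out[is_pos] <- .MODALITIES[detail[is_pos] + 1]
  out
}
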