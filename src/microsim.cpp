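// Per-person monthly-cycle microsimulation of the colorectal-cancer
// adenoma-carcinoma natural history with an optional screening overlay.
//
// Randomness is counter-based: every draw is a pure function of
// (master seed, person, cycle, channel). This gives exact common random
// numbers across strategy arms: the disease-transition draw of a given
// person-cycle is identical no matter how many screening draws the arm
// consumes, so an arm whose policy never changes anyone's state (e.g.
// adherence 0) reproduces the natural-history trace bit for bit.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x ^= x >> 30; x *= 0xBF58476D1CE4E5B9ULL;
  x ^= x >> 27; x *= 0x94D049BB133111EBULL;
  x ^= x >> 31;
  return x;
}

// uniform in [0,1), stateless
static inline double urand(uint64_t seed, uint64_t person, uint64_t cycle,
                           uint64_t channel) {
  uint64_t k = mix64(seed ^ (person * 0xA24BAED4963EE407ULL));
  k = mix64(k ^ (cycle * 0x9FB21C651E98DF25ULL) ^
            (channel * 0xD6E8FEB86659FD93ULL));
  return (k >> 11) * (1.0 / 9007199254740992.0);
}

// states
enum { HEALTHY = 0, AD_LR, AD_HR, PRE_LOC, PRE_REG, PRE_DIST,
       CLIN_LOC, CLIN_REG, CLIN_DIST, DEATH_CRC, DEATH_OTHER };
// parameter columns of p_disease
enum { P_ONSET = 0, P_LR2HR, P_HR2PRE, P_LOC2REG, P_REG2DIST,
       P_DET_LOC, P_DET_REG, P_DET_DIST };
// random channels (unique per person-cycle)
enum { CH_DISEASE = 0, CH_ADHERE, CH_PRIMARY_RESULT, CH_PRIMARY_COMPL,
       CH_FOLLOWUP_ADHERE, CH_COLO_RESULT, CH_COLO_COMPL, CH_DIAG_COMPL };
// event codes (match .EVENT_LEVELS on the R side, 1-based)
enum { EV_ONSET = 1, EV_AD_PROG, EV_PRECLIN, EV_STAGE, EV_SYMPT_DX,
       EV_SCREEN_DX, EV_TEST, EV_COMPL, EV_POLYP, EV_DEATH_CRC,
       EV_DEATH_OTHER, EV_POSITIVE };
// modalities / reasons
enum { MOD_COLO = 0, MOD_SIG, MOD_FIT, MOD_FOBT };
enum { RSN_SCREEN = 0, RSN_FOLLOWUP, RSN_SURV, RSN_DIAG };
// test_chars columns
enum { TC_SENS_LR = 0, TC_SENS_HR, TC_SENS_CRC, TC_SPEC, TC_COMPL,
       TC_WHOLE, TC_DISTAL };

struct EventLog {
  std::vector<int> person, age, event, detail;
  void add(int p, int a, int e, int d) {
    person.push_back(p); age.push_back(a); event.push_back(e);
    detail.push_back(d);
  }
};

// [[Rcpp::export(name = ".sim_cohort_cpp")]]
List sim_cohort_cpp(int n_persons, double seed,
                    NumericMatrix p_disease, NumericVector p_allcause,
                    NumericMatrix p_cancer,
                    bool screening,
                    IntegerVector phase_modality, IntegerVector phase_interval,
                    IntegerVector phase_start, IntegerVector phase_stop,
                    double adherence, double followup_adherence,
                    double surveillance_adherence,
                    NumericMatrix test_chars,
                    int surv_first, int surv_later, int surv_stop,
                    int entry_age_m) {
  const int n_cycles = p_disease.nrow();
  const uint64_t sd = (uint64_t)seed;
  const int n_phases = screening ? phase_modality.size() : 0;

  IntegerMatrix occ(n_cycles + 1, 11);
  EventLog log;
  log.person.reserve(n_persons * 6);
  IntegerVector death_age(n_persons, -1), death_type(n_persons, 0),
      dx_age(n_persons, -1), dx_stage_out(n_persons, -1),
      final_state(n_persons);

  for (int i = 0; i < n_persons; ++i) {
    int state = HEALTHY;
    int dx_m = -1, dx_stage = -1;
    bool in_surv = false;
    int surv_next = -1;
    int cur_phase = 0;
    int next_offer = n_phases > 0 ? phase_start[0] : -1;
    int lockout_until = 0;  // no screening before this age (negative scope)
    int died = 0;  // 0 alive, EV_DEATH_CRC, EV_DEATH_OTHER

    for (int t = 0; t < n_cycles && !died; ++t) {
      const int age_m = entry_age_m + t;
      occ(t, state)++;

      // ---- screening step (offers only to living, undiagnosed persons) ----
      if (n_phases > 0 && state <= PRE_DIST) {
        bool do_colo = false;
        int colo_reason = RSN_SCREEN;
        bool offered_colo_primary = false;

        if (in_surv) {
          if (surv_next == age_m && age_m <= surv_stop) {
            if (urand(sd, i, t, CH_ADHERE) < surveillance_adherence) {
              do_colo = true;
              colo_reason = RSN_SURV;
            } else {
              surv_next = age_m + surv_later;
            }
          }
        } else {
          while (cur_phase + 1 < n_phases && age_m > phase_stop[cur_phase]) {
            ++cur_phase;
            // the new phase starts its own offer grid, deferred only by an
            // active colonoscopy lockout
            next_offer = phase_start[cur_phase] > lockout_until
                             ? phase_start[cur_phase] : lockout_until;
          }
          const int interval = phase_interval[cur_phase];
          if (age_m == next_offer && age_m >= phase_start[cur_phase] &&
              age_m <= phase_stop[cur_phase]) {
            if (urand(sd, i, t, CH_ADHERE) >= adherence) {
              next_offer += interval;  // offer declined
            } else {
              const int mod = phase_modality[cur_phase];
              if (mod == MOD_COLO) {
                do_colo = true;
                colo_reason = RSN_SCREEN;
                offered_colo_primary = true;
              } else {
                // stool test or sigmoidoscopy
                log.add(i, age_m, EV_TEST, mod * 10 + RSN_SCREEN);
                double reach = 1.0;
                if (mod == MOD_SIG) {
                  reach = test_chars(MOD_SIG, TC_WHOLE) > 0.5
                              ? 1.0 : test_chars(MOD_SIG, TC_DISTAL);
                  if (urand(sd, i, t, CH_PRIMARY_COMPL) <
                      test_chars(MOD_SIG, TC_COMPL))
                    log.add(i, age_m, EV_COMPL, MOD_SIG * 10 + RSN_SCREEN);
                }
                double p_pos;
                if (state == HEALTHY) p_pos = 1.0 - test_chars(mod, TC_SPEC);
                else if (state == AD_LR) p_pos = test_chars(mod, TC_SENS_LR) * reach;
                else if (state == AD_HR) p_pos = test_chars(mod, TC_SENS_HR) * reach;
                else p_pos = test_chars(mod, TC_SENS_CRC) * reach;
                if (urand(sd, i, t, CH_PRIMARY_RESULT) < p_pos) {
                  log.add(i, age_m, EV_POSITIVE, mod);
                  if (urand(sd, i, t, CH_FOLLOWUP_ADHERE) < followup_adherence) {
                    do_colo = true;
                    colo_reason = RSN_FOLLOWUP;
                  } else {
                    next_offer += interval;  // positive but no follow-up
                  }
                } else {
                  next_offer += interval;  // negative first-line test
                }
              }
            }
          }
        }

        if (do_colo) {
          log.add(i, age_m, EV_TEST, MOD_COLO * 10 + colo_reason);
          if (urand(sd, i, t, CH_COLO_COMPL) < test_chars(MOD_COLO, TC_COMPL))
            log.add(i, age_m, EV_COMPL, MOD_COLO * 10 + colo_reason);
          const double u = urand(sd, i, t, CH_COLO_RESULT);
          int finding = 0;  // 0 none, 1 LR, 2 HR, 3 CRC
          if (state == AD_LR && u < test_chars(MOD_COLO, TC_SENS_LR)) finding = 1;
          else if (state == AD_HR && u < test_chars(MOD_COLO, TC_SENS_HR)) finding = 2;
          else if (state >= PRE_LOC && state <= PRE_DIST &&
                   u < test_chars(MOD_COLO, TC_SENS_CRC)) finding = 3;

          if (finding == 1 || finding == 2) {
            log.add(i, age_m, EV_POLYP, finding);
            state = HEALTHY;  // complete removal
          }
          if (finding == 3) {
            const int stg = state - PRE_LOC;  // 0 local, 1 regional, 2 distant
            state = CLIN_LOC + stg;
            dx_m = age_m; dx_stage = stg;
            log.add(i, age_m, EV_SCREEN_DX, stg + 1);
          }
          if (colo_reason == RSN_SURV) {
            surv_next = age_m + (finding == 2 ? surv_first : surv_later);
          } else {
            if (finding == 2) {
              in_surv = true;
              surv_next = age_m + surv_first;
            } else if (finding != 3) {
              // negative or LR-cleared colonoscopy: 10-year lockout
              lockout_until = age_m + 120;
              next_offer = lockout_until;
            }
          }
          (void)offered_colo_primary;
        }
      }

      // ---- disease / death transition (single multinomial draw) ----
      const double pd = p_allcause[t];
      const double u = urand(sd, i, t, CH_DISEASE);
      switch (state) {
        case HEALTHY: {
          const double p1 = p_disease(t, P_ONSET);
          if (u < p1) { state = AD_LR; log.add(i, age_m, EV_ONSET, 0); }
          else if (u < p1 + pd) died = EV_DEATH_OTHER;
          break;
        }
        case AD_LR: {
          const double p1 = p_disease(t, P_LR2HR);
          if (u < p1) { state = AD_HR; log.add(i, age_m, EV_AD_PROG, 0); }
          else if (u < p1 + pd) died = EV_DEATH_OTHER;
          break;
        }
        case AD_HR: {
          const double p1 = p_disease(t, P_HR2PRE);
          if (u < p1) { state = PRE_LOC; log.add(i, age_m, EV_PRECLIN, 1); }
          else if (u < p1 + pd) died = EV_DEATH_OTHER;
          break;
        }
        case PRE_LOC: case PRE_REG: case PRE_DIST: {
          const int stg = state - PRE_LOC;
          const double p_prog =
              stg == 0 ? p_disease(t, P_LOC2REG)
                       : (stg == 1 ? p_disease(t, P_REG2DIST) : 0.0);
          const double p_det = p_disease(t, P_DET_LOC + stg);
          if (u < p_prog) {
            ++state;
            log.add(i, age_m, EV_STAGE, stg + 2);
          } else if (u < p_prog + p_det) {
            state = CLIN_LOC + stg;
            dx_m = age_m; dx_stage = stg;
            log.add(i, age_m, EV_SYMPT_DX, stg + 1);
            // symptomatic presentation triggers one diagnostic colonoscopy
            log.add(i, age_m, EV_TEST, MOD_COLO * 10 + RSN_DIAG);
            if (urand(sd, i, t, CH_DIAG_COMPL) < test_chars(MOD_COLO, TC_COMPL))
              log.add(i, age_m, EV_COMPL, MOD_COLO * 10 + RSN_DIAG);
          } else if (u < p_prog + p_det + pd) {
            died = EV_DEATH_OTHER;
          }
          break;
        }
        default: {  // clinical states
          const int stg = state - CLIN_LOC;
          const int m = age_m - dx_m;  // months since diagnosis
          const double pc =
              (m >= 1 && m <= 120) ? p_cancer(m - 1, stg) : 0.0;
          if (u < pc) died = EV_DEATH_CRC;
          else if (u < pc + pd) died = EV_DEATH_OTHER;
          break;
        }
      }

      if (died) {
        log.add(i, age_m, died == EV_DEATH_CRC ? EV_DEATH_CRC : EV_DEATH_OTHER, 0);
        death_age[i] = age_m;
        death_type[i] = died == EV_DEATH_CRC ? 1 : 2;
        state = died == EV_DEATH_CRC ? DEATH_CRC : DEATH_OTHER;
        for (int tt = t + 1; tt <= n_cycles; ++tt) occ(tt, state)++;
      }
    }

    if (!died) occ(n_cycles, state)++;
    final_state[i] = state;
    dx_age[i] = dx_m;
    dx_stage_out[i] = dx_stage;
  }

  return List::create(
      _["person"] = wrap(log.person), _["age_months"] = wrap(log.age),
      _["event"] = wrap(log.event), _["detail"] = wrap(log.detail),
      _["occupancy"] = occ, _["final_state"] = final_state,
      _["death_age"] = death_age, _["death_type"] = death_type,
      _["dx_age"] = dx_age, _["dx_stage"] = dx_stage_out);
}

// Deterministic forward recursion over the six pre-diagnosis states,
// accumulating calibration-target quantities. Diagnosed persons leave the
// risk pool, so clinical survival does not enter. Row t of p_disease is the
// cycle-t parameter vector; band_of_cycle maps cycles to incidence age
// bands; prev_read[t] >= 0 requests a prevalence readout slot.
// [[Rcpp::export(name = ".forward_targets_cpp")]]
List forward_targets_cpp(NumericMatrix p_disease, NumericVector p_allcause,
                         IntegerVector band_of_cycle, int n_bands,
                         IntegerVector prev_read, int n_prev) {
  const int n_cycles = p_disease.nrow();
  double v0 = 1, v1 = 0, v2 = 0, v3 = 0, v4 = 0, v5 = 0;
  NumericVector dx_band(n_bands), pm_band(n_bands), prev(n_prev),
      stage_flow(3);
  for (int t = 0; t < n_cycles; ++t) {
    if (prev_read[t] >= 0) {
      const double tot = v0 + v1 + v2 + v3 + v4 + v5;
      prev[prev_read[t]] = tot > 0 ? (v1 + v2) / tot : 0.0;
    }
    const double pd = p_allcause[t];
    const double d0 = v3 * p_disease(t, P_DET_LOC);
    const double d1 = v4 * p_disease(t, P_DET_REG);
    const double d2 = v5 * p_disease(t, P_DET_DIST);
    const int b = band_of_cycle[t];
    dx_band[b] += d0 + d1 + d2;
    pm_band[b] += v0 + v1 + v2 + v3 + v4 + v5;
    stage_flow[0] += d0; stage_flow[1] += d1; stage_flow[2] += d2;

    const double n0 = v0 * (1 - p_disease(t, P_ONSET) - pd);
    const double n1 = v1 * (1 - p_disease(t, P_LR2HR) - pd) +
        v0 * p_disease(t, P_ONSET);
    const double n2 = v2 * (1 - p_disease(t, P_HR2PRE) - pd) +
        v1 * p_disease(t, P_LR2HR);
    const double n3 =
        v3 * (1 - p_disease(t, P_LOC2REG) - p_disease(t, P_DET_LOC) - pd) +
        v2 * p_disease(t, P_HR2PRE);
    const double n4 =
        v4 * (1 - p_disease(t, P_REG2DIST) - p_disease(t, P_DET_REG) - pd) +
        v3 * p_disease(t, P_LOC2REG);
    const double n5 = v5 * (1 - p_disease(t, P_DET_DIST) - pd) +
        v4 * p_disease(t, P_REG2DIST);
    v0 = n0; v1 = n1; v2 = n2; v3 = n3; v4 = n4; v5 = n5;
  }
  return List::create(_["dx_band"] = dx_band, _["pm_band"] = pm_band,
                      _["stage_flow"] = stage_flow, _["prev"] = prev);
}
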