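#!/usr/bin/env Rscript
# Temperature-dependence analysis: per-set temperatures from the
# before/after readings, the uniform-interval temperature uncertainty,
# the linear model fit, and the room-to-body-temperature correction.

suppressPackageStartupMessages(library(psdcal))

s <- read_session("results/sessions/temperature_psd.json")
sets <- unique(s$set)

# per-set temperature uncertainty: uniform-interval rule + calibration
u_temp <- vapply(sets, function(i) {
  row <- s[s$set == i, ][1, ]
  uniform_interval_u(temperature_reading(row$t_initial, row$t_final,
                                         u_cal = 0.045))
}, numeric(1))
cat(sprintf("per-set temperature uncertainty: %.3f-%.3f degC (k=1)\n",
            min(u_temp), max(u_temp)))

model <- fit_temperature_model(s$temperature, s$counts_per_100ms,
                               t0 = 25, u_temp = u_temp[s$set])
print(model)
cat(sprintf("slope: (%.2f +/- %.2f)%%/degC (k=1)\n",
            100 * model$a, 100 * model$u_a))

# room (25 degC) to body (37 degC) correction
resp_37 <- relative_response(model, 37)
cat(sprintf("response change 25 -> 37 degC: %.2f%%\n",
            100 * (resp_37 - 1)))
cat(sprintf("correction factor at 37 degC: %.5f\n",
            temperature_correction(model, 37)))

# patient-to-patient temperature spread, propagated to signal
u_patient_k2 <- round_half_up(expand_uncertainty(0.36, k = 2), 1)
u_sig <- temperature_signal_uncertainty(u_patient_k2, model)
cat(sprintf(
  "patient temperature %.1f degC (k=2) -> %.3f%% signal uncertainty\n",
  u_patient_k2, u_sig))

jsonlite::write_json(
  list(a_per_degc = model$a, u_a_per_degc = model$u_a, s0 = model$s0,
       response_change_37c_pct = 100 * (resp_37 - 1),
       correction_factor_37c = temperature_correction(model, 37),
       patient_signal_u_pct = u_sig),
  "results/temperature_summary.json", auto_unbox = TRUE, digits = NA)
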