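# simulations are deterministic; cache the expensive ones across test files
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(patient_id, kind, horizon = 10000, inoculum = 1) {
  key <- paste(patient_id, kind, horizon, inoculum, sep = "/")
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_patient(
      table3_patient(patient_id), regimen(kind),
      solver_control(horizon_days = horizon), inoculum = inoculum)
  }
  .sim_cache[[key]]
}
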