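# The full 74-patient protocol run takes minutes; several acceptance
# checks read different aspects of the same run, so it is computed once
# per test session and cached.
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort_run <- function(n = 74, seed = 1) {
  key <- paste0("n", n, "_s", seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- run_pipeline(n = n, seed = seed)
  }
  .cohort_cache[[key]]
}

# One full-protocol reference-patient run, likewise shared.
cached_reference_run <- function(op_time_s = 7200) {
  key <- paste0("ref", op_time_s)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- run_protocol(ref_patient(), op_time_s = op_time_s)
  }
  .cohort_cache[[key]]
}
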