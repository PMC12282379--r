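# internal objects exercised directly by the tests
MORPH_PARAMS <- ecgphewas:::MORPH_PARAMS
morphology_defaults <- ecgphewas:::morphology_defaults
reference_lead_scales <- ecgphewas:::reference_lead_scales
n_qrs_complexes <- ecgphewas:::n_qrs_complexes
detector_forward <- ecgphewas:::detector_forward
bce_with_logits <- ecgphewas:::bce_with_logits
backbone_bwd <- ecgphewas:::backbone_bwd
collect_params <- ecgphewas:::collect_params
collect_grads <- ecgphewas:::collect_grads
assign_params <- ecgphewas:::assign_params

# Shared synthetic cohorts, generated once per test run.

.cohort_cache <- new.env(parent = emptyenv())

# mid-size two-site cohort for label/gate/baseline tests
mid_cohort <- function() {
  if (is.null(.cohort_cache$mid)) {
    .cohort_cache$mid <- generate_cohort(
      generator_config(n_patients_per_site = 2500, seed = 424))
  }
  .cohort_cache$mid
}

mid_labels <- function() {
  if (is.null(.cohort_cache$mid_lb)) {
    .cohort_cache$mid_lb <- build_labels(mid_cohort(), min_total = 30,
                                         min_per_split = 5)
  }
  .cohort_cache$mid_lb
}

# small cohort where waveforms are affordable
small_cohort <- function() {
  if (is.null(.cohort_cache$small)) {
    .cohort_cache$small <- generate_cohort(
      generator_config(n_patients_per_site = 150, seed = 77,
                       ecgs_per_patient = 1))
  }
  .cohort_cache$small
}
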