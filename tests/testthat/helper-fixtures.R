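# Shared fixtures built in code.

# small, fully deterministic intake table covering every bundled component
make_intake_table <- function(n = 12, seed = 42, at_means = FALSE) {
  set.seed(seed)
  comps <- union(dii_reference()$component, dobs_reference()$component)
  dii <- dii_reference()
  out <- data.frame(participant_id = seq_len(n))
  for (cmp in comps) {
    mu <- if (cmp %in% dii$component) dii$global_mean[dii$component == cmp]
          else c(calcium = 900, copper = 1.2)[[cmp]]
    out[[cmp]] <- if (at_means) rep(mu, n) else mu * exp(rnorm(n, 0, 0.4))
  }
  out
}

small_cohort <- function(n = 400, seed = 11, ...) {
  generate_cohort(cohort_config(n_participants = n, seed = seed, ...))
}

equal_design <- function(n) survey_design(rep(1, n))
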