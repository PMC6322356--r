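# Shorthand for the control-vs-model modelling path used across tests.
pareto_scale_cm <- function(ft) {
  pareto_scale(subset_samples(ft, c("control", "model")))
}

cm_labels <- function(ft) {
  sample_info(subset_samples(ft, c("control", "model")))$group
}

# Full screen on a synthetic study: OPLS-DA VIPs + Welch screen.
screen_study <- function(st, seed = 1) {
  ft <- st$table
  m <- fit_oplsda(pareto_scale_cm(ft), cm_labels(ft), seed = seed)
  screen_markers(ft, vip_scores(m))
}
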