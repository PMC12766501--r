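# Shared fixtures: small synthetic cohorts, graph sequences and a tiny
# fitted model, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

# evaluate expr under a fixed seed (test-local convenience)
with_seed <- function(seed, expr) {
  set.seed(seed)
  expr
}

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

make_cohort <- function(n = 60, seed = 1, ...) {
  generate_cohort(cohort_config(n_patients = n, seed = seed, ...))
}

# cohort -> preprocessed tensor + graph sequences
cohort_to_graphs <- function(coh, seed = 1, min_count = NULL) {
  pp <- preprocess_pipeline(coh$events, seed = seed)
  if (is.null(min_count)) min_count <- 0.25 * coh$config$n_patients
  sch <- organ_schema(coh$config$systems,
                      split(coh$feature_map$feature_id, coh$feature_map$system)[coh$config$systems])
  de <- encode_diagnoses(coh$diagnoses, patient_ids = pp$tensor$patient_ids,
                         min_count = min_count)
  gs <- build_graph_sequences(pp$tensor, coh$demographics, de, sch)
  list(pp = pp, schema = sch, diag = de, graphs = gs)
}

truth_for <- function(coh, ids) {
  coh$truth$phenotype[match(ids, coh$truth$patient_id)]
}

# a small fitted model shared by the model/coupling tests
tiny_fit <- function() {
  memo("tiny_fit", {
    coh <- make_cohort(n = 60, seed = 11)
    parts <- cohort_to_graphs(coh, seed = 11)
    ctl <- odtgc_control(d_latent = 8, cvae_hidden = 8, epochs = 5,
                         pretrain_epochs = 10, seed = 3)
    fit <- odtgcnet(parts$graphs, coh$outcomes, ctl)
    list(coh = coh, parts = parts, fit = fit)
  })
}
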