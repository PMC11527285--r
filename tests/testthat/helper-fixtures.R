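# Shared fixtures for the expensive end-to-end tests. Everything is built in
# code at test time; trained models are cached in this environment so the
# pretraining cost is paid once per test run.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, expr, envir = .fx)
  get(key, envir = .fx)
}

# default study conditions
fx_spec <- function(seed = 1, ...) synthetic_spec(seed = seed, ...)

fx_sc <- function(seed = 1) {
  fx_cached(paste0("sc_", seed), generate_single_cell(fx_spec(seed)))
}

fx_split <- function(seed = 1) {
  fx_cached(paste0("split_", seed),
            split_cells(fx_sc(seed)$dataset, seed = seed))
}

# headline model: default spec, seed 1, 15 epochs (desk-scale reduction of
# the 50-epoch protocol)
fx_model_main <- function() {
  fx_cached("model_main", {
    sp <- fx_split(1)
    train_capsnet(sp$train, sp$val, train_config(epochs = 15, seed = 1))
  })
}

# reduced 5-epoch models over seeds, for multi-seed stochastic checks
fx_model_seed <- function(seed) {
  fx_cached(paste0("model_s", seed), {
    sp <- fx_split(seed)
    train_capsnet(sp$train, sp$val, train_config(epochs = 5, seed = seed))
  })
}

fx_bulk <- function(seed = 1) {
  fx_cached(paste0("bulk_", seed), generate_bulk(fx_spec(seed), 3))
}

# held-out evaluation of the 70% of a cohort not used for fine-tuning
fx_cohort_holdout <- function(cohort, tc) {
  idx_ft <- capstx:::with_seed(tc$seed,
    capstx:::stratified_sample(cohort$labels, tc$fine_tune_fraction))
  rest <- setdiff(seq_along(cohort$labels), idx_ft)
  list(matrix = capstx:::em_subset(cohort$matrix, samples = rest),
       labels = cohort$labels[rest])
}
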