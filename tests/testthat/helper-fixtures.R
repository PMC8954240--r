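# Shared fixtures, built lazily and cached for the whole test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), .fixtures)
  get(name, envir = .fixtures)
}

# full-size study phantom (the default simulation conditions)
study_phantom <- function() {
  fixture("study_phantom", function()
    generate_phantom(phantom_spec(), c(256, 256), c(0.6, 0.6)))
}

# small, fast phantom for unit tests: same geometry at coarser spacing
small_phantom <- function() {
  fixture("small_phantom", function()
    generate_phantom(phantom_spec(seed = 7L), c(128, 128), c(1.25, 1.25)))
}

# small learned operator pair (PA/MR) for registration unit tests
small_operators <- function() {
  fixture("small_operators", function() {
    ph <- small_phantom()
    ens <- extract_patch_pairs(ph$pa, ph$mr, 7, 800, seed = 21)
    learn_operators(ens, sparsity_config(), admm_control(max_iter = 40),
                    seed = 5, modalities = c("PA", "MR"))
  })
}

# small mono-modal operators for cost-landscape unit tests
mono_small_operators <- function() {
  fixture("mono_small_operators", function() {
    ph <- small_phantom()
    ens <- extract_patch_pairs(ph$mr, ph$mr, 7, 400, seed = 23)
    learn_operators(ens, sparsity_config(), admm_control(max_iter = 30),
                    seed = 5, modalities = c("MR", "MR"))
  })
}

# mono-modal operators (MR/MR) for the identity-recovery checks
mono_operators <- function() {
  fixture("mono_operators", function() {
    ph <- study_phantom()
    ens <- extract_patch_pairs(ph$mr, ph$mr, 7, 1000, seed = 3)
    learn_operators(ens, sparsity_config(), admm_control(max_iter = 40),
                    seed = 5, modalities = c("MR", "MR"))
  })
}

# the five-repeat study at the default conditions; shared by the
# registration-recovery and method-ordering acceptance checks
study_experiment <- function() {
  fixture("study_experiment", function()
    run_experiment(experiment_config(n_repeats = 5)))
}

# per-method TRE vectors from the study, in repeat order
study_tre <- function(method) {
  rows <- Filter(function(r) r$method == method, study_experiment()$rows)
  vapply(rows, `[[`, numeric(1), "tre_mm")
}

random_unit_rows <- function(k, n, seed) {
  set.seed(seed)
  m <- matrix(rnorm(k * n), k, n)
  m / sqrt(rowSums(m^2))
}
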