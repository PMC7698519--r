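# Small fixtures shared across the test files; everything is built in code.

tiny_catalog <- function(n = 10L, controls = 1L, seed = 99L) {
  generate_catalog(n_peptides = n, n_controls = controls, seed = seed)
}

# Explicit 3-family map over a 10-peptide catalog (pep ids from tiny_catalog
# with seed 99); controls are excluded by construction in generate_map, but
# this hand-built map pins exact peptide sets for set-arithmetic tests.
hand_map <- function() {
  tibble::tribble(
    ~kinase_id, ~family_id, ~peptide_id,
    "LCK", "SRC", "p1",
    "LCK", "SRC", "p2",
    "LYN", "SRC", "p2",
    "LYN", "SRC", "p3",
    "FYN", "SRC", "p4",
    "TEC", "TEC", "p5",
    "TEC", "TEC", "p6",
    "DDR1", "DDR", "p7"
  )
}

# A deterministic exposure series lying exactly on a line.
exact_series <- function(slope = 2, intercept = 0,
                         exposures = c(10, 20, 50, 100, 200)) {
  list(exposure = exposures, intensity = slope * exposures + intercept)
}

# Standard small simulated comparison used by several files.
demo_comparison <- function(seed = 7L, noise_sd = 0, effect = 1,
                            spiked_kinase = "KIN01",
                            nonlinear_fraction = 0, undetectable_fraction = 0) {
  catalog <- generate_catalog(seed = seed)
  map <- generate_map(catalog, n_kinases = 40L, mean_peptides = 8, seed = seed)
  truth <- synthetic_truth(
    spiked_kinases = tibble::tibble(kinase_id = spiked_kinase, effect_log2fc = effect),
    noise_sd = noise_sd,
    nonlinear_fraction = nonlinear_fraction,
    undetectable_fraction = undetectable_fraction,
    seed = seed
  )
  run <- simulate_run(catalog, map, truth)
  list(catalog = catalog, map = map, truth = truth, run = run)
}
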