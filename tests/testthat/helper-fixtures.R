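# Shared fixture builders. Everything is generated in code; no binary
# fixtures live in the repository.

# a small fully-crossed experiment with known signals (no noise)
make_exact_experiment <- function() {
  tidy_experiment(
    tibble::tibble(
      well = c("A01", "A02", "A03", "B01", "B02", "B03"),
      condition = rep(c("control", "geneA"), each = 3),
      firefly = c(1000, 2000, 1500, 4000, 8000, 6000),
      renilla = c(500, 1000, 750, 1000, 2000, 1500)
    ),
    factor_names = "condition"
  )
}

# single-factor simulation spec used across tests
spec_single <- function(seed = 1, replicates = 3,
                        transfection_sigma = 0.3, measurement_sigma = 0.05,
                        tfc = c(control = 1, geneA = 2, geneB = 0.5)) {
  simulation_spec(
    factors = list(condition = names(tfc)),
    true_fold_change = tfc,
    replicates = replicates,
    transfection_sigma = transfection_sigma,
    measurement_sigma = measurement_sigma,
    seed = seed
  )
}

# the paper-style multi-factor screen: 3 vectors x 4 drugs x 2 cells x 3 reps
spec_screen <- function(seed = 1, transfection_sigma = 0.3,
                        measurement_sigma = 0.05) {
  simulation_spec(seed = seed, transfection_sigma = transfection_sigma,
                  measurement_sigma = measurement_sigma)
}

# write a design CSV for an experiment
write_design_csv <- function(exp, path) {
  readr::write_csv(as.data.frame(exp[c("well", factor_names(exp))]), path,
                   progress = FALSE)
  path
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol * pmax(abs(expected), 1)),
              label = sprintf("max relative deviation %.3g within %.3g",
                              max(abs(actual - expected) /
                                    pmax(abs(expected), 1)), tol))
}
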