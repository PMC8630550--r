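test_that("simulation specs validate their fields", {
  expect_error(simulation_spec(replicates = 0), "replicates")
  expect_error(simulation_spec(true_fold_change = c(control = -1)), "positive")
  expect_error(simulation_spec(replicates = 5), "96")
  expect_error(simulation_spec(factors = list(c("a", "b"))), "named")
})

test_that("generation is deterministic and does not disturb the session RNG", {
  a <- generate_experiment(spec_screen(seed = 9))
  b <- generate_experiment(spec_screen(seed = 9))
  expect_equal(as.data.frame(a$experiment), as.data.frame(b$experiment))
  c_ <- generate_experiment(spec_screen(seed = 10))
  expect_false(isTRUE(all.equal(a$experiment$firefly, c_$experiment$firefly)))

  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(generate_experiment(spec_screen(seed = 9)))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("the noiseless limit reproduces true fold changes exactly", {
  spec <- spec_single(transfection_sigma = 0, measurement_sigma = 0)
  sim <- generate_experiment(spec)
  exp <- compute_ratios(sim$experiment)
  # every geneA ratio is exactly twice every control ratio
  expect_equal(unique(exp$ratio[exp$condition == "geneA"]) /
                 unique(exp$ratio[exp$condition == "control"]), 2)
  fc <- fold_change(exp, "condition=control")
  expect_identical(as.numeric(tapply(fc$fold_change, fc$condition, mean)[
    sim$truth$condition]), sim$truth$true_fold_change)
})

test_that("wells fill the plate in row-major order", {
  sim <- generate_experiment(spec_single())
  expect_identical(sim$experiment$well, plate_wells()[1:9])
})

test_that("true fold changes may be given per condition key", {
  spec <- simulation_spec(
    factors = list(vector = c("control", "geneA"), cell = c("Hek", "neuron")),
    true_fold_change = c(control_Hek = 1, geneA_Hek = 2,
                         control_neuron = 1, geneA_neuron = 0.5),
    transfection_sigma = 0, measurement_sigma = 0, replicates = 2)
  sim <- generate_experiment(spec)
  fc <- fold_change(sim$experiment, "vector=control")
  got <- tapply(fc$fold_change, condition_keys(fc), mean)
  expect_equal(got[["geneA_Hek"]], 2)
  expect_equal(got[["geneA_neuron"]], 0.5)
})

test_that("estimates converge to the truth with many replicates", {
  # law of large numbers: heavy transfection noise, no measurement noise;
  # transfection noise cancels in the ratio so the estimate is exact up to
  # the reference-mean Monte-Carlo error
  spec <- simulation_spec(
    factors = list(condition = c("control", "geneA")),
    true_fold_change = c(control = 1, geneA = 2),
    replicates = 48, transfection_sigma = 0.5, measurement_sigma = 0,
    seed = 99)
  sim <- generate_experiment(spec)
  fc <- fold_change(sim$experiment, "condition=control")
  est <- mean(fc$fold_change[fc$condition == "geneA"])
  expect_equal(est, 2, tolerance = 1e-9)  # sigma_m = 0: ratios are exact
})

test_that("transfection noise inflates raw signals but not fold changes", {
  var_fc <- function(sigma_t, seeds) {
    vapply(seeds, function(s) {
      spec <- spec_single(seed = s, transfection_sigma = sigma_t,
                          measurement_sigma = 0.05)
      fc <- fold_change(generate_experiment(spec)$experiment,
                        "condition=control")
      stats::var(fc$fold_change[fc$condition == "geneA"] / 2)
    }, numeric(1))
  }
  var_ff <- function(sigma_t, seeds) {
    vapply(seeds, function(s) {
      spec <- spec_single(seed = s, transfection_sigma = sigma_t,
                          measurement_sigma = 0.05)
      e <- generate_experiment(spec)$experiment
      stats::var(log(e$firefly[e$condition == "geneA"]))
    }, numeric(1))
  }
  seeds <- 1:500
  expect_gt(mean(var_ff(1, seeds)), 5 * mean(var_ff(0, seeds)))
  expect_lte(mean(var_fc(1, seeds)), 1.5 * mean(var_fc(0, seeds)))
})

test_that("fixture bundles are complete, consistent and deterministic", {
  spec <- spec_screen(seed = 17, transfection_sigma = 0, measurement_sigma = 0)
  d1 <- withr::local_tempdir()
  paths <- write_fixture_bundle(spec, d1)
  expect_true(all(file.exists(paths)))

  # the three data files describe the same experiment
  pr <- suppressMessages(read_glomax(paths[["workbook"]]))
  exp <- merge_design(pr, read_design(paths[["design"]]))
  tidy <- read_tidy(paths[["tidy"]])
  expect_equal(exp$firefly, tidy$firefly[match(exp$well, tidy$well)])

  # noiseless bundle recovers the truth end to end
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)$truth
  fc <- fold_change(exp, "vector=control")
  got <- tapply(fc$fold_change, condition_keys(fc), mean)
  expect_equal(as.numeric(got[truth$condition]), truth$true_fold_change)

  # same spec, second write: identical bytes for every file
  d2 <- withr::local_tempdir()
  paths2 <- write_fixture_bundle(spec, d2)
  for (nm in names(paths)) {
    expect_identical(readBin(paths[[nm]], "raw", file.size(paths[[nm]])),
                     readBin(paths2[[nm]], "raw", file.size(paths2[[nm]])),
                     label = nm)
  }
})
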