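test_that("ratios divide firefly by the internal control", {
  exp <- compute_ratios(make_exact_experiment())
  expect_equal(exp$ratio, c(2, 2, 2, 4, 4, 4))
  # element-by-element oracle on a larger fixture
  sim <- generate_experiment(spec_screen(seed = 21))
  r <- compute_ratios(sim$experiment)
  oracle <- vapply(seq_len(nrow(r)),
                   function(i) r$firefly[i] / r$renilla[i], numeric(1))
  expect_equal(r$ratio, oracle)
  # zero firefly is a legitimate zero ratio
  z <- tidy_experiment(tibble::tibble(well = "A01", condition = "a",
                                      firefly = 0, renilla = 500), "condition")
  expect_equal(compute_ratios(z)$ratio, 0)
})

test_that("zero renilla is fatal unless wells are dropped explicitly", {
  df <- tibble::tibble(well = c("A01", "A02"), condition = c("a", "b"),
                       firefly = c(1, 2), renilla = c(0, 4))
  exp <- tidy_experiment(df, "condition")
  expect_error(compute_ratios(exp), "A01")
  expect_warning(ok <- compute_ratios(exp, drop_zero_control = TRUE), "dropping")
  expect_identical(ok$well, "A02")
})

test_that("well and condition exclusions remove exactly the matching rows", {
  sim <- generate_experiment(spec_single(seed = 4))
  exp <- sim$experiment  # 3 conditions x 3 replicates
  f <- filter_experiment(exp, exclude_wells = "A01")
  expect_identical(nrow(f), nrow(exp) - 1L)
  expect_false("A01" %in% f$well)

  # oracle scan for the condition exclusion count
  n_control <- sum(exp$condition == "control")
  f2 <- filter_experiment(exp, exclude_conditions = "condition=control")
  expect_identical(nrow(f2), nrow(exp) - n_control)
  expect_identical(attr(f2, "removal_report")[["condition:condition=control"]],
                   n_control)

  # empty exclusions leave the table untouched
  f3 <- filter_experiment(exp)
  expect_equal(as.data.frame(f3), as.data.frame(exp), ignore_attr = TRUE)

  # absent selectors warn but do not error
  expect_warning(filter_experiment(exp, exclude_wells = "H12"), "H12")
  expect_warning(filter_experiment(exp, exclude_conditions = "condition=nope"),
                 "no rows")
})

test_that("fold change divides by the mean reference ratio", {
  # reference ratios {2,2,2}, sample ratios {4,4,4} -> fold change 2
  exp <- fold_change(compute_ratios(make_exact_experiment()),
                     "condition=control")
  expect_equal(exp$fold_change, c(1, 1, 1, 2, 2, 2))
  # self-normalization: reference rows average to exactly 1
  expect_equal(mean(exp$fold_change[exp$condition == "control"]), 1)
  # full-key selector addresses the same group
  exp2 <- fold_change(compute_ratios(make_exact_experiment()), "control")
  expect_equal(exp2$fold_change, exp$fold_change)
})

test_that("fold change errors are informative", {
  exp <- compute_ratios(make_exact_experiment())
  expect_error(fold_change(exp, "condition=nope"), "available condition keys")
  expect_error(fold_change(exp, "typo=control"), "not a design column")
  zero <- tidy_experiment(tibble::tibble(well = c("A01", "A02"),
                                         condition = c("ref", "x"),
                                         firefly = c(0, 5), renilla = c(1, 1)),
                          "condition")
  expect_error(fold_change(compute_ratios(zero), "condition=ref"),
               "mean ratio is zero")
})

test_that("stratified referencing uses each stratum's own reference mean", {
  # two strata with different reference baselines and effects {1, 2, 0.5}
  df <- tibble::tibble(
    well = parse_well(paste0("A", 1:8)),
    vector = rep(c("control", "control", "geneA", "geneB"), 2),
    cell = rep(c("Hek", "neuron"), each = 4),
    renilla = rep(100, 8),
    firefly = c(100, 100, 200, 50,     # Hek: baseline ratio 1
                400, 400, 800, 200))   # neuron: baseline ratio 4
  exp <- compute_ratios(tidy_experiment(df, c("vector", "cell")))
  strat <- fold_change(exp, "vector=control")  # default: stratified
  expect_true(attr(strat, "normalization")$stratified)
  expect_equal(strat$fold_change,
               rep(c(1, 1, 2, 0.5), 2))
  # global mode collapses the strata into one denominator (mean ratio 2.5)
  glob <- fold_change(exp, "vector=control", stratified = FALSE)
  expect_equal(glob$fold_change, exp$ratio / 2.5)
  # a stratum without reference wells is an error naming the stratum
  noref <- exp[exp$vector != "control" | exp$cell != "neuron", ]
  noref <- tidy_experiment(noref, c("vector", "cell"))
  expect_error(fold_change(noref, "vector=control"), "neuron")
})

test_that("geometric-mean referencing is available and self-normalizes in log space", {
  exp <- compute_ratios(make_exact_experiment())
  geo <- fold_change(exp, "condition=control", geometric = TRUE)
  ref <- geo$fold_change[geo$condition == "control"]
  expect_equal(mean(log(ref)), 0)
})

test_that("fold change is invariant to common scale and linear in firefly", {
  sim <- generate_experiment(spec_screen(seed = 31))
  base <- fold_change(sim$experiment, "vector=control")
  for (c_scale in c(0.001, 1000)) {
    scaled <- sim$experiment
    scaled$firefly <- scaled$firefly * c_scale
    scaled$renilla <- scaled$renilla * c_scale
    fc <- fold_change(scaled, "vector=control")
    expect_rel_equal(fc$fold_change, base$fold_change, 1e-12)
  }
  # multiplying every firefly value by k cancels through the reference
  k <- 7.5
  all_k <- sim$experiment
  all_k$firefly <- all_k$firefly * k
  expect_rel_equal(fold_change(all_k, "vector=control")$fold_change,
                   base$fold_change, 1e-12)
  # multiplying only non-reference firefly values scales their fold changes by k
  part <- sim$experiment
  nonref <- part$vector != "control"
  part$firefly[nonref] <- part$firefly[nonref] * k
  fc <- fold_change(part, "vector=control")
  expect_rel_equal(fc$fold_change[nonref], k * base$fold_change[nonref], 1e-12)
  expect_rel_equal(fc$fold_change[!nonref], base$fold_change[!nonref], 1e-12)
})

test_that("summaries match textbook values and a group-by oracle", {
  df <- tibble::tibble(well = c("A01", "A02", "A03", "A04"),
                       condition = c(rep("a", 3), "b"),
                       firefly = c(1, 2, 3, 5), renilla = rep(1, 4))
  s <- summarize_experiment(compute_ratios(tidy_experiment(df, "condition")))
  a <- s[s$condition == "a", ]
  expect_equal(a$n, 3L)
  expect_equal(a$mean, 2)
  expect_equal(a$median, 2)
  expect_equal(a$sd, 1)
  expect_equal(a$sem, 1 / sqrt(3))
  expect_equal(a$ci95_low, 2 - stats::qt(0.975, 2) / sqrt(3))
  expect_equal(a$ci95_high, 2 + stats::qt(0.975, 2) / sqrt(3))
  # n = 1: spread statistics are unset
  b <- s[s$condition == "b", ]
  expect_equal(b$mean, 5)
  expect_true(is.na(b$sd) && is.na(b$sem) && is.na(b$ci95_low))

  # every row of a 24-condition summary matches an independent recomputation
  sim <- generate_experiment(spec_screen(seed = 41))
  exp <- fold_change(sim$experiment, "vector=control")
  s24 <- summarize_experiment(exp)
  expect_identical(nrow(s24), 24L)
  keys <- condition_keys(exp)
  for (i in seq_len(nrow(s24))) {
    v <- exp$fold_change[keys == s24$condition[i]]
    expect_equal(s24$n[i], length(v))
    expect_equal(s24$mean[i], mean(v))
    expect_equal(s24$sd[i], sd(v))
    expect_equal(s24$median[i], median(v))
  }
})

test_that("summary tables write as CSV and paginated text", {
  sim <- generate_experiment(spec_single(seed = 6))
  s <- summarize_experiment(compute_ratios(sim$experiment))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_summary(s, csv)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(back$mean, s$mean)
  txt <- withr::local_tempfile(fileext = ".txt")
  write_summary(s, txt)
  expect_true(any(grepl("page 1/", readLines(txt))))
  pdf <- withr::local_tempfile(fileext = ".pdf")
  write_summary(s, pdf)
  expect_identical(readBin(pdf, "raw", 4), charToRaw("%PDF"))
})
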