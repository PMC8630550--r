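#' Specification of a synthetic dual-luciferase experiment
#'
#' Describes the generative model behind [generate_experiment()]. The model
#' mirrors why dual-luciferase assays carry an internal control: each well
#' receives a random transfection efficiency that scales *both* channels, so
#' the firefly/renilla ratio cancels it. For well \eqn{w} in condition
#' \eqn{c}:
#' \deqn{t_w \sim \mathrm{LogNormal}(0, \sigma_t)}
#' \deqn{renilla_w = \mu_R \, t_w \, \mathrm{LogNormal}(0, \sigma_m)}
#' \deqn{firefly_w = \mu_R \, F(c) \, t_w \, \mathrm{LogNormal}(0, \sigma_m)}
#' where \eqn{F(c)} is the true fold change of condition \eqn{c} relative to
#' the reference (fixed at 1) and \eqn{\mu_R} the mean renilla count.
#'
#' The default design mirrors a realistic multi-factor reporter screen:
#' three transfected vectors (an empty-vector control plus two candidate
#' regulators) crossed with four drug treatments and two cell types, three
#' replicate wells each -- 72 of the plate's 96 wells.
#'
#' @param factors Named list of factor levels, in condition-key join order.
#' @param true_fold_change Named positive vector of true fold changes. Names
#'   are either full condition keys or levels of exactly one factor (then
#'   recycled across the other factors). Must include the reference level
#'   with value 1.
#' @param replicates Wells per condition.
#' @param renilla_mean Mean renilla count (arbitrary units); luminescence
#'   plate readers typically report 1e4--1e6 counts.
#' @param transfection_sigma Log-scale SD of per-well transfection
#'   efficiency (shared by both channels).
#' @param measurement_sigma Log-scale SD of per-channel measurement noise.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(
    factors = list(vector = c("control", "geneA", "geneB"),
                   drug = c("none", "drug1", "drug2", "drug1+drug2"),
                   cell = c("Hek", "neuron")),
    true_fold_change = c(control = 1, geneA = 2.5, geneB = 0.4),
    replicates = 3,
    renilla_mean = 1e5,
    transfection_sigma = 0.3,
    measurement_sigma = 0.05,
    seed = 1L) {
  stopifnot(is.list(factors), length(factors) >= 1,
            replicates >= 1, renilla_mean > 0,
            transfection_sigma >= 0, measurement_sigma >= 0)
  if (is.null(names(factors)) || any(!nzchar(names(factors)))) {
    stop("factors must be a named list", call. = FALSE)
  }
  if (any(true_fold_change <= 0)) {
    stop("true fold changes must be positive", call. = FALSE)
  }
  n_wells <- prod(lengths(factors)) * replicates
  if (n_wells > 96) {
    stop("design needs ", n_wells, " wells but a plate has 96; ",
         "reduce levels or replicates", call. = FALSE)
  }
  structure(list(factors = factors, true_fold_change = true_fold_change,
                 replicates = as.integer(replicates),
                 renilla_mean = renilla_mean,
                 transfection_sigma = transfection_sigma,
                 measurement_sigma = measurement_sigma,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# expand a named fold-change vector to one value per design row
resolve_truth <- function(spec, design) {
  tfc <- spec$true_fold_change
  keys <- condition_key(design[names(spec$factors)])
  if (all(names(tfc) %in% keys) && length(setdiff(keys, names(tfc))) == 0) {
    return(unname(tfc[keys]))
  }
  hit <- vapply(names(spec$factors),
                function(f) all(names(tfc) %in% spec$factors[[f]]) &&
                  all(spec$factors[[f]] %in% names(tfc)),
                logical(1))
  if (!any(hit)) {
    stop("true_fold_change names must cover either all condition keys or ",
         "all levels of one factor", call. = FALSE)
  }
  f <- names(spec$factors)[which(hit)[1]]
  unname(tfc[design[[f]]])
}

#' Generate a synthetic experiment with known ground truth
#'
#' Draws one plate from the model described in [simulation_spec()].
#' Conditions are laid out in the expansion order of `factors` and wells are
#' assigned plate positions in row-major order (A01, A02, ...). With all
#' sigmas zero the data are exact: every well's ratio equals its condition's
#' true fold change times the reference ratio.
#'
#' @param spec A [simulation_spec()].
#' @return A list: `experiment` (a [tidy_experiment()]), `truth` (tibble of
#'   condition key and true fold change) and `spec`.
#' @export
generate_experiment <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  design <- rev(expand.grid(rev(spec$factors), stringsAsFactors = FALSE,
                            KEEP.OUT.ATTRS = FALSE))
  design <- design[rep(seq_len(nrow(design)), each = spec$replicates), ,
                   drop = FALSE]
  n <- nrow(design)
  design$well <- plate_wells()[seq_len(n)]
  truth_row <- resolve_truth(spec, design)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  t_w <- stats::rlnorm(n, 0, spec$transfection_sigma)
  renilla <- spec$renilla_mean * t_w * stats::rlnorm(n, 0, spec$measurement_sigma)
  firefly <- spec$renilla_mean * truth_row * t_w *
    stats::rlnorm(n, 0, spec$measurement_sigma)

  exp <- tidy_experiment(
    tibble::tibble(well = design$well, design[names(spec$factors)],
                   firefly = firefly, renilla = renilla),
    factor_names = names(spec$factors))
  truth <- tibble::tibble(
    condition = condition_key(unique(design[names(spec$factors)])),
    true_fold_change = resolve_truth(spec, unique(design[names(spec$factors)])))
  list(experiment = exp, truth = truth, spec = spec)
}

#' Write a matched fixture bundle to disk
#'
#' Emits the trio of files the import paths accept, all describing the same
#' simulated experiment: a dual-channel plate workbook (XLSX), a design CSV,
#' and a combined tidy CSV; plus the ground truth as JSON. Useful for
#' end-to-end tests and for demonstrating the command-line interface without
#' instrument data.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_fixture_bundle <- function(spec = simulation_spec(), dir) {
  sim <- generate_experiment(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  exp <- sim$experiment
  paths <- c(workbook = file.path(dir, "plate.xlsx"),
             design = file.path(dir, "design.csv"),
             tidy = file.path(dir, "tidy.csv"),
             truth = file.path(dir, "truth.json"))
  readings <- plate_readings(exp$well, exp$firefly, exp$renilla,
                             plate_id = "simulated_plate")
  write_glomax(readings, paths[["workbook"]])
  readr::write_csv(as.data.frame(exp[c("well", factor_names(exp))]),
                   paths[["design"]], progress = FALSE)
  write_tidy(exp, paths[["tidy"]])
  jsonlite::write_json(
    list(truth = sim$truth,
         spec = sim$spec[c("replicates", "renilla_mean", "transfection_sigma",
                           "measurement_sigma", "seed")]),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
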