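#' Normalize firefly signal by the renilla internal control
#'
#' Computes each well's firefly/renilla ratio, cancelling well-to-well
#' variation in cell density and transfection efficiency. When the
#' experiment carries no internal-control channel the ratio is the raw
#' firefly signal and downstream results are unnormalized.
#'
#' @param exp A [tidy_experiment()].
#' @param drop_zero_control Drop wells whose renilla signal is zero (with a
#'   warning) instead of erroring.
#' @return The experiment with a `ratio` column.
#' @export
compute_ratios <- function(exp, drop_zero_control = FALSE) {
  stopifnot(inherits(exp, "tidy_experiment"))
  if (has_renilla(exp)) {
    zero <- exp$renilla == 0
    if (any(zero)) {
      if (!drop_zero_control) {
        stop("renilla signal is zero in well(s): ",
             paste(sort(exp$well[zero]), collapse = ", "),
             "; the ratio is undefined (use drop_zero_control = TRUE to drop them)",
             call. = FALSE)
      }
      warning("dropping ", sum(zero), " well(s) with zero renilla signal",
              call. = FALSE)
      exp <- restore_experiment(exp[!zero, ], exp)
    }
    exp$ratio <- exp$firefly / exp$renilla
  } else {
    exp$ratio <- exp$firefly
  }
  exp
}

#' Exclude wells or conditions from an experiment
#'
#' Removes individual wells and/or whole conditions before analysis, e.g.
#' pipetting failures or conditions outside the question at hand. A selector
#' naming a well or condition absent from the data raises a warning, not an
#' error, so one exclusion list can serve a batch of plates. The removal
#' counts are attached as attribute `removal_report`.
#'
#' @param exp A [tidy_experiment()].
#' @param exclude_wells Character vector of well identifiers.
#' @param exclude_conditions Character vector of condition selectors: full
#'   condition keys or `"factor=level"` pairs (see [parse_reference()]).
#' @return The filtered experiment.
#' @export
filter_experiment <- function(exp, exclude_wells = character(),
                              exclude_conditions = character()) {
  stopifnot(inherits(exp, "tidy_experiment"))
  drop <- rep(FALSE, nrow(exp))
  report <- list()
  if (length(exclude_wells)) {
    ew <- parse_well(exclude_wells)
    absent <- setdiff(ew, exp$well)
    if (length(absent)) {
      warning("excluded well(s) not present in the data: ",
              paste(absent, collapse = ", "), call. = FALSE)
    }
    hit <- exp$well %in% ew
    report$wells <- sum(hit)
    drop <- drop | hit
  }
  for (sel in exclude_conditions) {
    ref <- parse_reference(sel)
    hit <- tryCatch(reference_rows(exp, ref), error = function(e) rep(FALSE, nrow(exp)))
    if (!any(hit)) {
      warning("excluded condition matches no rows: ", sel, call. = FALSE)
    }
    report[[paste0("condition:", sel)]] <- sum(hit & !drop)
    drop <- drop | hit
  }
  out <- restore_experiment(exp[!drop, , drop = FALSE], exp)
  attr(out, "removal_report") <- report
  out
}

#' Fold change relative to a reference condition
#'
#' Implements the dual-luciferase fold-change normalization: each well's
#' firefly/renilla ratio is divided by the *mean* ratio of the wells in the
#' reference condition, so the reference group averages to a fold change of
#' exactly 1. Two referencing modes exist:
#'
#' * **global** -- one denominator, the mean ratio of all reference rows.
#' * **stratified** -- the reference selector names a single
#'   `"factor=level"` pair; the remaining factors partition the plate into
#'   strata (e.g. drug x cell type) and each stratum is divided by the mean
#'   ratio of its *own* reference wells. This is the natural mode when a
#'   control vector is present within every treatment combination.
#'
#' By default the mode is stratified when the selector is a factor=level
#' pair and the design has more than one factor, global otherwise.
#'
#' @param exp A [tidy_experiment()] with ratios computed (computed on the
#'   fly if absent).
#' @param reference Reference selector: a full condition key or a
#'   `"factor=level"` pair.
#' @param stratified Force stratified (`TRUE`) or global (`FALSE`)
#'   referencing; `NULL` picks the default above.
#' @param geometric Use the geometric rather than arithmetic mean of the
#'   reference ratios as denominator (ratios are approximately log-normal).
#'   The arithmetic mean is the default and matches the conventional
#'   group-average normalization.
#' @return The experiment with a `fold_change` column; the selector, mode
#'   and denominators used are attached as attribute `normalization`.
#' @export
fold_change <- function(exp, reference, stratified = NULL, geometric = FALSE) {
  stopifnot(inherits(exp, "tidy_experiment"))
  if (!"ratio" %in% names(exp)) exp <- compute_ratios(exp)
  ref <- if (is.list(reference)) reference else parse_reference(reference)
  if (is.null(stratified)) {
    stratified <- ref$kind == "pair" && length(factor_names(exp)) > 1
  }
  if (stratified && ref$kind != "pair") {
    stop("stratified referencing needs a FACTOR=LEVEL reference selector",
         call. = FALSE)
  }
  is_ref <- reference_rows(exp, ref)
  if (!any(is_ref)) {
    stop("reference matches no rows; available condition keys: ",
         paste(sort(unique(condition_keys(exp))), collapse = ", "),
         call. = FALSE)
  }
  mean_fun <- if (geometric) function(x) base::exp(mean(log(x))) else mean

  if (stratified) {
    strata_cols <- setdiff(factor_names(exp), ref$factor)
    key <- condition_key(exp[strata_cols], sep = attr(exp, "sep") %||% "_")
    denom <- vapply(split(seq_len(nrow(exp)), key), function(idx) {
      r <- idx[is_ref[idx]]
      if (!length(r)) {
        stop("stratum '", key[idx[1]], "' has no reference wells (",
             ref$factor, "=", ref$level, ")", call. = FALSE)
      }
      mean_fun(exp$ratio[r])
    }, numeric(1))
    if (any(denom == 0)) {
      stop("reference mean ratio is zero in stratum: ",
           paste(names(denom)[denom == 0], collapse = ", "), call. = FALSE)
    }
    exp$fold_change <- exp$ratio / unname(denom[key])
  } else {
    d <- mean_fun(exp$ratio[is_ref])
    if (d == 0) stop("reference mean ratio is zero", call. = FALSE)
    denom <- c(global = d)
    exp$fold_change <- exp$ratio / d
  }
  attr(exp, "normalization") <- list(reference = ref, stratified = stratified,
                                     geometric = geometric,
                                     denominators = denom)
  exp
}

is_reference_row <- function(exp) {
  nz <- attr(exp, "normalization")
  if (is.null(nz)) rep(FALSE, nrow(exp)) else reference_rows(exp, nz$reference)
}

#' Per-condition summary statistics
#'
#' Summarizes the ratio or fold change per condition: n, mean, sample
#' standard deviation (n-1 denominator), standard error of the mean, median,
#' and a 95% t-interval on the mean (n-1 degrees of freedom). Spread
#' statistics are `NA` for conditions with a single observation.
#'
#' @param exp A [tidy_experiment()].
#' @param value `"fold_change"` or `"ratio"`; defaults to fold change when
#'   computed, ratio otherwise.
#' @return A tibble of class `summary_table`: one row per condition key, in
#'   order of first appearance, with the factor columns retained.
#' @export
summarize_experiment <- function(exp, value = NULL) {
  stopifnot(inherits(exp, "tidy_experiment"))
  if (is.null(value)) value <- if ("fold_change" %in% names(exp)) "fold_change" else "ratio"
  value <- match.arg(value, c("fold_change", "ratio"))
  if (!value %in% names(exp)) {
    if (value == "ratio") exp <- compute_ratios(exp)
    else stop("fold_change has not been computed; call fold_change() first",
              call. = FALSE)
  }
  df <- tibble::as_tibble(exp)
  df$condition <- condition_keys(exp)
  df$.value <- df[[value]]
  out <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("condition", factor_names(exp))))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$.value),
      sd = ifelse(dplyr::n() > 1, stats::sd(.data$.value), NA_real_),
      sem = .data$sd / sqrt(.data$n),
      median = stats::median(.data$.value),
      ci95_low = .data$mean - ifelse(.data$n > 1,
        stats::qt(0.975, .data$n - 1) * .data$sem, NA_real_),
      ci95_high = .data$mean + ifelse(.data$n > 1,
        stats::qt(0.975, .data$n - 1) * .data$sem, NA_real_),
      .groups = "drop"
    )
  out <- out[match(unique(df$condition), out$condition), , drop = FALSE]
  attr(out, "value") <- value
  class(out) <- c("summary_table", class(out))
  out
}

#' Write a summary table
#'
#' @param summary A `summary_table` from [summarize_experiment()].
#' @param path Output path; format follows the extension unless given.
#' @param format `"csv"`, `"txt"` (paginated plain text) or `"pdf"`.
#' @param rows_per_page Rows per page for the paginated renderings.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path,
                          format = c("auto", "csv", "txt", "pdf"),
                          rows_per_page = 40) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", txt = "txt", pdf = "pdf", "csv")
  }
  if (format == "csv") {
    readr::write_csv(as.data.frame(summary), path, progress = FALSE)
    return(invisible(path))
  }
  fmt <- as.data.frame(summary)
  num <- vapply(fmt, is.numeric, logical(1))
  fmt[num] <- lapply(fmt[num], function(x) formatC(x, digits = 4, format = "g"))
  lines <- utils::capture.output(print(fmt, row.names = FALSE))
  pages <- split(lines[-1], (seq_along(lines[-1]) - 1) %/% rows_per_page)
  if (format == "txt") {
    out <- unlist(lapply(seq_along(pages), function(p) {
      c(sprintf("== page %d/%d ==", p, length(pages)), lines[1], pages[[p]], "")
    }))
    writeLines(out, path)
  } else {
    grDevices::pdf(path, width = 8.27, height = 11.69)
    on.exit(grDevices::dev.off())
    for (p in seq_along(pages)) {
      graphics::par(mar = c(1, 1, 1, 1))
      graphics::plot.new()
      txt <- paste(c(lines[1], pages[[p]]), collapse = "\n")
      graphics::text(0, 1, txt, adj = c(0, 1), family = "mono", cex = 0.7)
    }
  }
  invisible(path)
}
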