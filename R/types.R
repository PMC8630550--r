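#' Plate readings: paired firefly/renilla luminescence for one 96-well plate
#'
#' Long-form container for one plate of a dual-luciferase experiment: one row
#' per well with both luminescence channels. Values are instrument counts in
#' arbitrary units; they must be finite, and non-negative unless
#' `allow_negative = TRUE` (plate readers that background-subtract can emit
#' small negative counts).
#'
#' @param well Well identifiers (any form [parse_well()] accepts).
#' @param firefly,renilla Numeric luminescence counts, one per well.
#' @param plate_id Text label for the plate.
#' @param allow_negative Accept negative counts instead of erroring.
#' @return A tibble of class `plate_readings` with columns `well`, `firefly`,
#'   `renilla` and attribute `plate_id`.
#' @export
plate_readings <- function(well, firefly, renilla, plate_id = "plate1",
                           allow_negative = FALSE) {
  well <- parse_well(well)
  stopifnot(length(firefly) == length(well), length(renilla) == length(well))
  if (anyDuplicated(well)) {
    stop("duplicate well(s) in plate readings: ",
         paste(unique(well[duplicated(well)]), collapse = ", "), call. = FALSE)
  }
  if (length(well) > 96) stop("a plate has at most 96 wells", call. = FALSE)
  check_counts(firefly, "firefly", allow_negative)
  check_counts(renilla, "renilla", allow_negative)
  out <- tibble::tibble(well = well, firefly = as.numeric(firefly),
                        renilla = as.numeric(renilla))
  attr(out, "plate_id") <- plate_id
  class(out) <- c("plate_readings", class(out))
  out
}

check_counts <- function(x, channel, allow_negative = FALSE) {
  if (anyNA(x) || any(!is.finite(x))) {
    stop(channel, " signal contains missing or non-finite values", call. = FALSE)
  }
  if (!allow_negative && any(x < 0)) {
    stop(channel, " signal contains negative values; ",
         "use allow_negative = TRUE to accept background-subtracted data",
         call. = FALSE)
  }
  invisible(x)
}

#' Design table: experimental condition assignments per well
#'
#' @param df Data frame with a `well` column (matched case-insensitively) and
#'   one or more factor columns giving the condition labels. Factor column
#'   order is preserved and defines the condition-key join order.
#' @return A tibble of class `design_table` with attribute `factor_names`.
#' @export
design_table <- function(df) {
  df <- tibble::as_tibble(df)
  wcol <- which(tolower(names(df)) == "well")
  if (length(wcol) != 1) {
    stop("design table needs exactly one 'well' column", call. = FALSE)
  }
  fac <- setdiff(seq_along(df), wcol)
  if (length(fac) == 0) {
    stop("design table needs at least one condition column besides 'well'",
         call. = FALSE)
  }
  out <- df[c(wcol, fac)]
  names(out)[1] <- "well"
  out$well <- parse_well(out$well)
  if (anyDuplicated(out$well)) {
    stop("duplicate well(s) in design: ",
         paste(unique(out$well[duplicated(out$well)]), collapse = ", "),
         call. = FALSE)
  }
  fn <- names(out)[-1]
  if (anyDuplicated(fn) || any(!nzchar(fn))) {
    stop("factor names must be unique and non-empty", call. = FALSE)
  }
  out[fn] <- lapply(out[fn], as.character)
  if (any(vapply(out[fn], function(x) any(is.na(x) | !nzchar(x)), logical(1)))) {
    stop("condition labels must be non-empty", call. = FALSE)
  }
  attr(out, "factor_names") <- fn
  class(out) <- c("design_table", class(out))
  out
}

#' Tidy experiment table
#'
#' The central analysis table: one row per well carrying the condition
#' factors, the firefly signal, optionally the renilla internal control, and
#' (once computed) the firefly/renilla `ratio` and `fold_change` columns.
#' The renilla channel is either present for every row or absent for the
#' whole table; when absent the data are analysed unnormalized
#' (ratio = firefly).
#'
#' @param df Data frame with columns `well`, the factor columns, `firefly`,
#'   and optionally `renilla`, `ratio`, `fold_change`.
#' @param factor_names Character vector naming the condition columns, in join
#'   order.
#' @param sep Condition-key separator (see [condition_key()]).
#' @param allow_negative Accept negative luminescence counts.
#' @return A tibble of class `tidy_experiment` with attributes `factor_names`
#'   and `sep`.
#' @export
tidy_experiment <- function(df, factor_names, sep = "_", allow_negative = FALSE) {
  df <- tibble::as_tibble(df)
  if (!all(c("well", "firefly") %in% names(df))) {
    stop("a tidy experiment needs 'well' and 'firefly' columns", call. = FALSE)
  }
  missing_fac <- setdiff(factor_names, names(df))
  if (length(missing_fac)) {
    stop("factor column(s) not found: ", paste(missing_fac, collapse = ", "),
         call. = FALSE)
  }
  df$well <- parse_well(df$well)
  check_counts(df$firefly, "firefly", allow_negative)
  if ("renilla" %in% names(df)) {
    if (anyNA(df$renilla)) {
      stop("renilla must be present for all rows or for none; ",
           "mixed presence is invalid", call. = FALSE)
    }
    check_counts(df$renilla, "renilla", allow_negative)
  }
  df[factor_names] <- lapply(df[factor_names], as.character)
  keep <- c("well", factor_names,
            intersect(c("firefly", "renilla", "ratio", "fold_change"), names(df)))
  out <- df[keep]
  attr(out, "factor_names") <- factor_names
  attr(out, "sep") <- sep
  class(out) <- unique(c("tidy_experiment", class(out)))
  out
}

#' @export
print.tidy_experiment <- function(x, ...) {
  cat("<tidy_experiment> ", nrow(x), " wells; factors: ",
      paste(factor_names(x), collapse = ", "),
      if (!has_renilla(x)) " (unnormalized: no internal control)", "\n", sep = "")
  NextMethod()
}

#' Accessors for tidy experiments
#'
#' `factor_names()` returns the condition columns in join order;
#' `has_renilla()` reports whether the internal-control channel is present;
#' `condition_keys()` returns the per-row condition key.
#'
#' @param exp A [tidy_experiment()].
#' @export
factor_names <- function(exp) attr(exp, "factor_names")

#' @rdname factor_names
#' @export
has_renilla <- function(exp) "renilla" %in% names(exp)

#' @rdname factor_names
#' @export
condition_keys <- function(exp) {
  condition_key(exp[factor_names(exp)], sep = attr(exp, "sep") %||% "_")
}

# restore class + attributes after dplyr-style manipulation
restore_experiment <- function(df, template) {
  tidy_experiment(df, factor_names = factor_names(template),
                  sep = attr(template, "sep") %||% "_",
                  allow_negative = TRUE)
}

#' Reference condition selector
#'
#' The fold-change denominator is defined by a reference condition. A
#' selector is either a full condition key (all factor labels joined, e.g.
#' `"control_none_Hek"`) or a single `"factor=level"` pair (e.g.
#' `"vector=control"`), which in stratified mode marks the reference rows
#' within every stratum formed by the remaining factors.
#'
#' @param x Selector string.
#' @return A list with elements `kind` (`"key"` or `"pair"`), and either
#'   `key`, or `factor` + `level`.
#' @export
parse_reference <- function(x) {
  stopifnot(is.character(x), length(x) == 1, nzchar(x))
  if (grepl("=", x, fixed = TRUE)) {
    parts <- strsplit(x, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !nzchar(parts[1]) || !nzchar(parts[2])) {
      stop("malformed reference selector: ", x,
           " (expected FACTOR=LEVEL or a full condition key)", call. = FALSE)
    }
    list(kind = "pair", factor = parts[1], level = parts[2])
  } else {
    list(kind = "key", key = x)
  }
}

reference_rows <- function(exp, ref) {
  if (ref$kind == "pair") {
    if (!ref$factor %in% factor_names(exp)) {
      stop("reference factor '", ref$factor, "' is not a design column (",
           paste(factor_names(exp), collapse = ", "), ")", call. = FALSE)
    }
    exp[[ref$factor]] == ref$level
  } else {
    condition_keys(exp) == ref$key
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
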