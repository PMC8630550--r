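# CSV dialect: comma-delimited UTF-8 with "." decimals; a European
# semicolon dialect is auto-detected by sniffing the header line.
sniff_delim <- function(path) {
  hdr <- readLines(path, n = 1, warn = FALSE)
  if (grepl(";", hdr, fixed = TRUE) && !grepl(",", hdr, fixed = TRUE)) ";" else ","
}

read_csv_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- sniff_delim(path)
  readr::read_delim(path, delim = delim,
                    locale = readr::locale(decimal_mark = if (delim == ";") "," else "."),
                    show_col_types = FALSE, progress = FALSE,
                    name_repair = "minimal")
}

#' Read a per-well experimental design table
#'
#' The design CSV maps wells to condition labels: a `well` column (matched
#' case-insensitively) plus one or more factor columns, whose file order
#' defines the condition-key join order.
#'
#' @param path Path to the CSV file.
#' @return A [design_table()].
#' @export
read_design <- function(path) {
  design_table(read_csv_auto(path))
}

#' Merge plate readings with an experimental design
#'
#' Joins the two channels onto the design by well. Wells measured on the
#' plate but absent from the design are dropped with a message reporting the
#' count (`policy = "strict"` turns this into an error); wells listed in the
#' design but missing from the readings always error, because a designed
#' well without data indicates a broken upload.
#'
#' @param readings A [plate_readings()] table.
#' @param design A [design_table()].
#' @param policy `"drop"` (default) or `"strict"` for undesigned wells.
#' @param sep Condition-key separator.
#' @return A [tidy_experiment()] with one row per designed well.
#' @export
merge_design <- function(readings, design, policy = c("drop", "strict"),
                         sep = "_") {
  policy <- match.arg(policy)
  stopifnot(inherits(readings, "plate_readings"), inherits(design, "design_table"))
  missing_wells <- setdiff(design$well, readings$well)
  if (length(missing_wells)) {
    stop("design references well(s) absent from the plate readings: ",
         paste(sort(missing_wells), collapse = ", "), call. = FALSE)
  }
  undesigned <- setdiff(readings$well, design$well)
  if (length(undesigned)) {
    if (policy == "strict") {
      stop(length(undesigned), " measured well(s) are missing from the design: ",
           paste(sort(undesigned), collapse = ", "), call. = FALSE)
    }
    message("dropping ", length(undesigned),
            " measured well(s) not present in the design")
  }
  merged <- dplyr::inner_join(tibble::as_tibble(design),
                              tibble::as_tibble(readings), by = "well")
  tidy_experiment(merged, factor_names = attr(design, "factor_names"), sep = sep)
}

#' Read a tidy experiment table from CSV
#'
#' A tidy upload carries everything in one file: a well column, one or more
#' condition columns, the firefly signal, and optionally the renilla
#' internal control. Column roles are resolved in this order: explicit
#' arguments, then case-insensitive header match (`firefly`; `renilla`,
#' `control` or `reference` for the internal control), then positional
#' fallback (the first numeric column that is not the control is firefly).
#' All remaining columns except `well`, `ratio` and `fold_change` are taken
#' as condition factors in file order. Without an internal-control column
#' the experiment is analysed unnormalized.
#'
#' @param path Path to the CSV file.
#' @param firefly_col,renilla_col Optional explicit column names.
#' @param sep Condition-key separator.
#' @param allow_negative Accept negative luminescence counts.
#' @return A [tidy_experiment()].
#' @export
read_tidy <- function(path, firefly_col = NULL, renilla_col = NULL, sep = "_",
                      allow_negative = FALSE) {
  df <- read_csv_auto(path)
  nm <- names(df)
  lnm <- tolower(nm)

  wcol <- nm[lnm == "well"]
  if (length(wcol) != 1) stop("tidy file needs exactly one 'well' column", call. = FALSE)

  numeric_cols <- nm[vapply(df, is.numeric, logical(1))]
  pick <- function(explicit, patterns, taken) {
    if (!is.null(explicit)) {
      if (!explicit %in% nm) stop("column '", explicit, "' not found", call. = FALSE)
      return(explicit)
    }
    hit <- nm[lnm %in% patterns & !nm %in% taken]
    if (length(hit)) hit[1] else NA_character_
  }
  rn <- pick(renilla_col, c("renilla", "control", "reference"), wcol)
  ff <- pick(firefly_col, "firefly", c(wcol, rn))
  if (is.na(ff)) {
    cand <- setdiff(numeric_cols, c(rn, nm[lnm %in% c("ratio", "fold_change")]))
    if (!length(cand)) {
      stop("no numeric signal column found in ", path, call. = FALSE)
    }
    ff <- cand[1]
  }
  for (col in c(ff, if (!is.na(rn)) rn)) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))) & !is.na(df[[col]]))
      stop("non-numeric entries in signal column '", col, "' at row(s): ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
    }
  }

  derived <- nm[lnm %in% c("ratio", "fold_change")]
  fac <- setdiff(nm, c(wcol, ff, rn, derived))
  # a signal-named column displaced from its role by an explicit override is
  # ignored, not silently reinterpreted as a condition
  displaced <- fac[tolower(fac) %in% c("firefly", "renilla", "control", "reference")]
  if (length(displaced)) {
    message("ignoring column(s) not assigned a role: ",
            paste(displaced, collapse = ", "))
    fac <- setdiff(fac, displaced)
  }
  if (!length(fac)) stop("tidy file needs at least one condition column", call. = FALSE)

  out <- df[c(wcol, fac)]
  names(out)[1] <- "well"
  out$firefly <- df[[ff]]
  if (!is.na(rn)) out$renilla <- df[[rn]]
  for (dcol in derived) out[[tolower(dcol)]] <- df[[dcol]]
  tidy_experiment(out, factor_names = fac, sep = sep,
                  allow_negative = allow_negative)
}

#' Write a tidy experiment table to CSV
#'
#' Columns: `well`, one column per condition factor, `firefly`, `renilla`
#' (when present), `ratio` and `fold_change` (when computed); one row per
#' observation. The writer is deterministic.
#'
#' @param exp A [tidy_experiment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tidy <- function(exp, path) {
  stopifnot(inherits(exp, "tidy_experiment"))
  readr::write_csv(as.data.frame(exp), path, progress = FALSE)
  invisible(path)
}
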