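#' Parse microplate well identifiers
#'
#' Converts well labels such as `"A1"`, `"a01"` or `"H12"` into the canonical
#' three-character form used throughout the package: an upper-case row letter
#' `A`--`H` followed by a zero-padded column number `01`--`12` (`"A01"` ...
#' `"H12"`). Parsing is case-insensitive and accepts unpadded column numbers;
#' rendering always zero-pads, so `parse_well("A1")` and `parse_well("A01")`
#' are identical.
#'
#' @param x Character vector of well labels.
#' @return Character vector of canonical well identifiers.
#' @examples
#' parse_well(c("A1", "h12"))
#' @export
parse_well <- function(x) {
  if (length(x) == 0) return(character())
  x_in <- as.character(x)
  x_trim <- toupper(trimws(x_in))
  m <- regmatches(x_trim, regexec("^([A-Z])0*([0-9]{1,2})$", x_trim))
  bad <- vapply(m, function(g) length(g) == 0, logical(1))
  row <- ifelse(bad, NA_character_, vapply(m, function(g) if (length(g)) g[2] else NA_character_, ""))
  col <- suppressWarnings(as.integer(
    vapply(m, function(g) if (length(g)) g[3] else NA_character_, "")
  ))
  bad <- bad | is.na(x_in) | !row %in% LETTERS[1:8] | is.na(col) | col < 1 | col > 12
  if (any(bad)) {
    stop("invalid well identifier(s): ",
         paste(unique(x_in[bad]), collapse = ", "),
         " (expected row A-H and column 1-12, e.g. \"A01\")",
         call. = FALSE)
  }
  sprintf("%s%02d", row, col)
}

#' Row letter and column number of a well
#'
#' @param well Character vector of well identifiers (any form [parse_well()]
#'   accepts).
#' @return `well_row()` returns the row letter (`"A"`--`"H"`); `well_col()`
#'   the column number (1--12).
#' @export
well_row <- function(well) substr(parse_well(well), 1, 1)

#' @rdname well_row
#' @export
well_col <- function(well) as.integer(substr(parse_well(well), 2, 3))

#' All 96 canonical well identifiers in row-major order
#'
#' Row-major means `A01, A02, ..., A12, B01, ...`, the order in which the
#' simulator fills a plate.
#'
#' @return Character vector of length 96.
#' @export
plate_wells <- function() {
  as.vector(t(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0)))
}

#' Combine factor labels into a condition key
#'
#' Experimental conditions are often described by several design columns
#' (e.g. transfected vector, drug, cell type). A condition key is the
#' deterministic join of the labels in declared column order, used for
#' grouping, reference selection and summary tables.
#'
#' @param factors A data frame (one column per factor, rows are wells) or a
#'   named list/vector of single labels.
#' @param sep Separator between labels. A warning is raised if the separator
#'   already occurs inside a label, because the key is then not injective.
#' @return Character vector of keys (one per row for a data frame input).
#' @examples
#' condition_key(list(vector = "geneA", drug = "drug1", cell = "neuron"))
#' @export
condition_key <- function(factors, sep = "_") {
  if (!is.data.frame(factors)) {
    factors <- as.data.frame(lapply(factors, as.character),
                             optional = TRUE, stringsAsFactors = FALSE)
  }
  if (ncol(factors) == 0) stop("at least one factor is required", call. = FALSE)
  labs <- lapply(factors, as.character)
  if (any(vapply(labs, function(l) any(grepl(sep, l, fixed = TRUE)), logical(1)))) {
    warning("separator \"", sep, "\" occurs inside a factor label; ",
            "condition keys may collide", call. = FALSE)
  }
  do.call(paste, c(labs, sep = sep))
}
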