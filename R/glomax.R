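#' Describe where the luminescence blocks sit in a plate workbook
#'
#' A plate workbook stores the firefly and renilla channels as two 8x12
#' tables (rows A--H by columns 1--12). By default [read_glomax()] locates
#' the two blocks automatically; a layout pins them explicitly when the
#' export dialect is unusual.
#'
#' @param sheet Sheet name or 1-based index.
#' @param firefly_anchor,renilla_anchor Cell address (e.g. `"B5"`) of the
#'   top-left *data* cell of each block, i.e. the well-A01 value. `NULL`
#'   leaves that block to auto-detection.
#' @return A `workbook_layout` list.
#' @export
workbook_layout <- function(sheet = 1, firefly_anchor = NULL,
                            renilla_anchor = NULL) {
  parse_anchor <- function(a) {
    if (is.null(a)) return(NULL)
    addr <- cellranger::as.cell_addr(a, strict = FALSE)
    c(row = addr$row, col = addr$col)
  }
  structure(list(sheet = sheet,
                 firefly = parse_anchor(firefly_anchor),
                 renilla = parse_anchor(renilla_anchor)),
            class = "workbook_layout")
}

# all-text rectangular view of one worksheet
read_sheet_text <- function(path, sheet = 1) {
  suppressMessages(
    df <- readxl::read_excel(path, sheet = sheet, col_names = FALSE,
                             col_types = "text",
                             .name_repair = "minimal")
  )
  as.matrix(df)
}

# find 8x12 numeric blocks flanked by A-H row labels and 1-12 headers;
# returns list of c(row, col) anchors of the A01 data cell, in reading order
locate_blocks <- function(cells) {
  nr <- nrow(cells); nc <- ncol(cells)
  anchors <- list()
  norm <- function(x) toupper(trimws(ifelse(is.na(x), "", x)))
  for (i in seq_len(max(nr - 7, 0))) {
    for (j in seq_len(nc)) {
      if (norm(cells[i, j]) != "A") next
      if (!identical(norm(cells[i:(i + 7), j]), LETTERS[1:8])) next
      if (i < 2 || j + 12 > nc) next
      hdr <- suppressWarnings(as.numeric(cells[i - 1, (j + 1):(j + 12)]))
      if (anyNA(hdr) || !identical(hdr, as.numeric(1:12))) next
      anchors[[length(anchors) + 1]] <- c(row = i, col = j + 1L)
    }
  }
  anchors
}

read_block <- function(cells, anchor) {
  i <- anchor[["row"]]; j <- anchor[["col"]]
  if (i + 7 > nrow(cells) || j + 11 > ncol(cells)) {
    stop("luminescence block at row ", i, ", column ", j,
         " runs off the sheet", call. = FALSE)
  }
  raw <- cells[i:(i + 7), j:(j + 11), drop = FALSE]
  vals <- suppressWarnings(matrix(as.numeric(raw), 8, 12))
  bad <- !is.na(raw) & nzchar(trimws(raw)) & is.na(vals)
  if (any(bad)) {
    w <- paste0(LETTERS[1:8][row(raw)[bad]], sprintf("%02d", col(raw)[bad]))
    stop("non-numeric value(s) in luminescence block at well(s): ",
         paste(w, collapse = ", "), call. = FALSE)
  }
  vals
}

#' Read a dual-channel plate workbook
#'
#' Parses an XLSX plate-reader export holding two 8x12 luminescence tables
#' (firefly first, renilla second, in top-to-bottom reading order). When
#' `layout` is omitted the blocks are auto-located by scanning for 8x12
#' numeric regions flanked by row labels A--H on the left and column headers
#' 1--12 above; metadata rows elsewhere on the sheet are ignored. Wells blank
#' in both channels are skipped with a message (`skip_blank = FALSE` turns
#' this into an error); a well blank in only one channel is always an error
#' because the pairing is broken.
#'
#' @param path Path to the workbook.
#' @param layout Optional [workbook_layout()] override.
#' @param skip_blank Skip wells blank in both channels.
#' @param allow_negative Accept negative counts (background-subtracted data).
#' @param plate_id Plate label; defaults to the file name.
#' @return A [plate_readings()] table.
#' @export
read_glomax <- function(path, layout = NULL, skip_blank = TRUE,
                        allow_negative = FALSE,
                        plate_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("workbook not found: ", path, call. = FALSE)
  sheet <- if (!is.null(layout)) layout$sheet else 1
  cells <- read_sheet_text(path, sheet = sheet)

  ff_anchor <- layout$firefly
  rn_anchor <- layout$renilla
  if (is.null(ff_anchor) || is.null(rn_anchor)) {
    found <- locate_blocks(cells)
    if (length(found) < 2) {
      stop("could not locate two 8x12 luminescence blocks on sheet '", sheet,
           "' (found ", length(found), "); expected firefly and renilla ",
           "tables with A-H row labels and 1-12 column headers, or an ",
           "explicit workbook_layout()", call. = FALSE)
    }
    if (length(found) > 2) {
      warning(length(found), " candidate blocks found; using the first two ",
              "in reading order", call. = FALSE)
    }
    if (is.null(ff_anchor)) ff_anchor <- found[[1]]
    if (is.null(rn_anchor)) rn_anchor <- found[[2]]
  }

  ff <- read_block(cells, ff_anchor)
  rn <- read_block(cells, rn_anchor)

  wells <- paste0(LETTERS[1:8][row(ff)], sprintf("%02d", col(ff)))
  half <- is.na(ff) != is.na(rn)
  if (any(half)) {
    stop("well(s) present in one channel but blank in the other: ",
         paste(sort(wells[half]), collapse = ", "), call. = FALSE)
  }
  blank <- is.na(ff) & is.na(rn)
  if (any(blank) && !skip_blank) {
    stop(sum(blank), " blank well(s) in the workbook: ",
         paste(sort(wells[blank]), collapse = ", "), call. = FALSE)
  }
  if (any(blank)) {
    message("skipping ", sum(blank), " well(s) blank in both channels")
  }
  keep <- !blank
  ord <- order(wells[keep])
  plate_readings(well = wells[keep][ord],
                 firefly = ff[keep][ord],
                 renilla = rn[keep][ord],
                 plate_id = plate_id,
                 allow_negative = allow_negative)
}

#' Write plate readings as a dual-channel workbook
#'
#' Emits an XLSX workbook in the same dialect [read_glomax()] parses: a
#' metadata line, then the firefly and renilla 8x12 tables with A--H row
#' labels and 1--12 column headers. Wells absent from `readings` are left
#' blank in both blocks. The writer is deterministic: identical inputs give
#' byte-identical files.
#'
#' @param readings A [plate_readings()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_glomax <- function(readings, path) {
  stopifnot(inherits(readings, "plate_readings"))
  ri <- match(well_row(readings$well), LETTERS[1:8])
  ci <- well_col(readings$well)

  block_cells <- function(top, title, values) {
    out <- data.frame(row = integer(), col = integer())
    out_vals <- list()
    add <- function(r, c, v) {
      out <<- rbind(out, data.frame(row = r, col = c))
      out_vals[[length(out_vals) + 1]] <<- v
    }
    add(top, 1, title)
    for (k in 1:12) add(top + 1, 1 + k, as.numeric(k))
    for (k in 1:8) add(top + 1 + k, 1, LETTERS[k])
    for (i in seq_along(values)) {
      add(top + 1 + ri[i], 1 + ci[i], as.numeric(values[i]))
    }
    out$value <- out_vals
    out
  }

  meta <- data.frame(row = 1, col = 1)
  meta$value <- list(paste0("Plate results: ", attr(readings, "plate_id") %||% "plate"))
  cells <- rbind(meta,
                 block_cells(3, "Firefly", readings$firefly),
                 block_cells(14, "Renilla", readings$renilla))
  write_cells_xlsx(cells, path, sheet_name = "Results")
  invisible(path)
}
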