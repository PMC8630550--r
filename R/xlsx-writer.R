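# Minimal deterministic XLSX writer.
#
# Emits a single-sheet workbook from a sparse cell table (row, col, value).
# Numbers are written as native numeric cells at full double precision,
# strings as inline strings, so readxl parses them back exactly. File
# timestamps inside the archive are pinned, making two writes of the same
# content byte-identical -- a property the round-trip and determinism tests
# rely on.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

excel_col <- function(j) {
  vapply(as.integer(j), function(n) {
    s <- ""
    while (n > 0) {
      r <- (n - 1L) %% 26L
      s <- paste0(LETTERS[r + 1L], s)
      n <- (n - 1L) %/% 26L
    }
    s
  }, character(1))
}

# cells: data.frame(row, col) with list-column `value` (numeric or character)
write_cells_xlsx <- function(cells, path, sheet_name = "Sheet1") {
  ord <- order(cells$row, cells$col)
  cells <- cells[ord, , drop = FALSE]
  cell_xml <- vapply(seq_len(nrow(cells)), function(i) {
    ref <- paste0(excel_col(cells$col[i]), cells$row[i])
    v <- cells$value[[i]]
    if (is.numeric(v)) {
      sprintf('<c r="%s"><v>%s</v></c>', ref,
              format(v, digits = 17, scientific = FALSE, trim = TRUE))
    } else {
      sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>',
              ref, xml_escape(as.character(v)))
    }
  }, character(1))
  row_xml <- vapply(split(cell_xml, cells$row), paste, character(1), collapse = "")
  row_xml <- sprintf('<row r="%s">%s</row>', names(row_xml), row_xml)

  ns_main <- "http://schemas.openxmlformats.org/spreadsheetml/2006/main"
  ns_rel <- "http://schemas.openxmlformats.org/officeDocument/2006/relationships"
  hdr <- '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>'
  parts <- list(
    "[Content_Types].xml" = paste0(hdr,
      '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
      '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
      '<Default Extension="xml" ContentType="application/xml"/>',
      '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
      '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
      '</Types>'),
    "_rels/.rels" = paste0(hdr,
      '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
      '<Relationship Id="rId1" Type="', ns_rel, '/officeDocument" Target="xl/workbook.xml"/>',
      '</Relationships>'),
    "xl/workbook.xml" = paste0(hdr,
      '<workbook xmlns="', ns_main, '" xmlns:r="', ns_rel, '">',
      '<sheets><sheet name="', xml_escape(sheet_name),
      '" sheetId="1" r:id="rId1"/></sheets></workbook>'),
    "xl/_rels/workbook.xml.rels" = paste0(hdr,
      '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
      '<Relationship Id="rId1" Type="', ns_rel, '/worksheet" Target="worksheets/sheet1.xml"/>',
      '</Relationships>'),
    "xl/worksheets/sheet1.xml" = paste0(hdr,
      '<worksheet xmlns="', ns_main, '"><sheetData>',
      paste(row_xml, collapse = ""), '</sheetData></worksheet>')
  )

  staging <- tempfile("xlsx")
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  for (f in names(parts)) {
    full <- file.path(staging, f)
    dir.create(dirname(full), recursive = TRUE, showWarnings = FALSE)
    con <- file(full, open = "wb")
    writeLines(parts[[f]], con, sep = "")
    close(con)
    Sys.setFileTime(full, as.POSIXct("2000-01-01", tz = "UTC"))
  }
  if (file.exists(path)) unlink(path)
  zip::zip(normalizePath(path, mustWork = FALSE), names(parts),
           root = staging, include_directories = FALSE)
  invisible(path)
}
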