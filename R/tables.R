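spanAttr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) return(1L)
  v <- suppressWarnings(as.integer(v))
  if (is.na(v) || v < 1L) 1L else v
}

# Expand row/column spans into a dense rectangular character grid.
# rows: list of rows, each a list of list(value, colspan, rowspan).
# A spanned value is duplicated into every covered cell so downstream
# column matching sees dense columns; ragged rows are padded with "".
expandSpans <- function(rows) {
  nR <- length(rows)
  if (nR == 0L) return(matrix(character(), 0L, 0L))
  grid <- matrix(NA_character_, nR, 0L)
  occ <- matrix(FALSE, nR, 0L)
  ensureCols <- function(k) {
    if (ncol(grid) < k) {
      add <- k - ncol(grid)
      grid <<- cbind(grid, matrix(NA_character_, nR, add))
      occ <<- cbind(occ, matrix(FALSE, nR, add))
    }
  }
  for (r in seq_len(nR)) {
    cpos <- 1L
    for (cell in rows[[r]]) {
      ensureCols(cpos)
      while (cpos <= ncol(occ) && occ[r, cpos]) cpos <- cpos + 1L
      cs <- cell$colspan
      rs <- min(cell$rowspan, nR - r + 1L)
      ensureCols(cpos + cs - 1L)
      for (rr in r:(r + rs - 1L)) for (cc in cpos:(cpos + cs - 1L)) {
        grid[rr, cc] <- cell$value
        occ[rr, cc] <- TRUE
      }
      cpos <- cpos + cs
    }
  }
  grid[is.na(grid)] <- ""
  grid
}

parseXhtmlTable <- function(tableNode) {
  parseTr <- function(tr) {
    lapply(xml2::xml_find_all(tr, "./td | ./th"), function(cell) list(
      value = normalizeText(xml2::xml_text(cell)),
      colspan = spanAttr(cell, "colspan"),
      rowspan = spanAttr(cell, "rowspan")
    ))
  }
  headTr <- xml2::xml_find_all(tableNode, "./thead/tr")
  bodyTr <- xml2::xml_find_all(tableNode, "./tbody/tr | ./tr")
  rows <- c(lapply(headTr, parseTr), lapply(bodyTr, parseTr))
  list(rows = rows, nHeader = length(headTr))
}

parseOasisTable <- function(tgroupNode) {
  colspecs <- xml2::xml_find_all(tgroupNode, "./colspec")
  colNames <- vapply(colspecs, function(n) {
    v <- xml2::xml_attr(n, "colname")
    if (is.na(v)) "" else v
  }, character(1))
  parseRow <- function(row) {
    lapply(xml2::xml_find_all(row, "./entry"), function(entry) {
      cs <- 1L
      st <- xml2::xml_attr(entry, "namest")
      en <- xml2::xml_attr(entry, "nameend")
      if (!is.na(st) && !is.na(en)) {
        i <- match(st, colNames)
        j <- match(en, colNames)
        if (!is.na(i) && !is.na(j) && j >= i) cs <- j - i + 1L
      }
      mr <- xml2::xml_attr(entry, "morerows")
      rs <- if (is.na(mr)) 1L else {
        mr <- suppressWarnings(as.integer(mr))
        if (is.na(mr) || mr < 0L) 1L else mr + 1L
      }
      list(value = normalizeText(xml2::xml_text(entry)),
           colspan = cs, rowspan = rs)
    })
  }
  headRows <- xml2::xml_find_all(tgroupNode, "./thead/row")
  bodyRows <- xml2::xml_find_all(tgroupNode, "./tbody/row")
  rows <- c(lapply(headRows, parseRow), lapply(bodyRows, parseRow))
  list(rows = rows, nHeader = length(headRows))
}

#' Extract and normalize all tables of an article
#'
#' Every `table-wrap` element yields one [NormalizedTable-class].
#' JATS permits two table markups — the XHTML model (`table`/`tr`/`td`
#' with `colspan`/`rowspan`) and the OASIS exchange model
#' (`tgroup`/`row`/`entry` with `namest`/`nameend`/`morerows`); both
#' produce identical grids for semantically identical tables. A table
#' whose structure cannot be parsed is skipped with a warning, never
#' fatal.
#'
#' @param article an `xml_document` for one article
#' @return list of [NormalizedTable-class] objects, in document order
#' @export
extractTables <- function(article) {
  wraps <- xml2::xml_find_all(article, "//table-wrap")
  out <- list()
  for (i in seq_along(wraps)) {
    wrap <- wraps[[i]]
    tableId <- xml2::xml_attr(wrap, "id")
    if (is.na(tableId)) tableId <- sprintf("table-%d", i)
    parsed <- tryCatch({
      xhtml <- xml2::xml_find_first(wrap, ".//table")
      oasis <- xml2::xml_find_first(wrap, ".//tgroup")
      if (!inherits(oasis, "xml_missing")) {
        c(parseOasisTable(oasis), dialect = "oasis")
      } else if (!inherits(xhtml, "xml_missing")) {
        c(parseXhtmlTable(xhtml), dialect = "xhtml")
      } else NULL
    }, error = function(e) {
      warning(sprintf("table '%s' skipped: %s", tableId,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(parsed)) next
    labelTxt <- xmlText1(wrap, "./label")
    captionTxt <- xmlText1(wrap, "./caption")
    footnotes <- vapply(
      xml2::xml_find_all(wrap,
                         "./table-wrap-foot//fn | ./table-wrap-foot/p"),
      function(n) normalizeText(xml2::xml_text(n)), character(1)
    )
    out[[length(out) + 1L]] <- new(
      "NormalizedTable", tableId = tableId,
      label = if (is.na(labelTxt)) "" else labelTxt,
      caption = if (is.na(captionTxt)) "" else captionTxt,
      nHeaderRows = as.integer(parsed$nHeader),
      cells = expandSpans(parsed$rows),
      footnotes = footnotes, sourceDialect = parsed$dialect
    )
  }
  out
}

#' Write a normalized table as CSV
#'
#' All rows (header rows included) are written as data rows, every
#' field quoted, UTF-8, LF line endings — byte-identical across repeated
#' extractions of the same file.
#'
#' @param table a [NormalizedTable-class]
#' @param path output file
#' @export
writeTableCsv <- function(table, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(table@cells, con, col.names = FALSE, row.names = FALSE,
                     sep = ",", qmethod = "double", quote = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}
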