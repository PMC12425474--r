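coordToken <- function(cell) {
  # strip units and decoration: "x (mm)", "X", "x-coord" -> "x"
  t <- tolower(trimws(cell))
  t <- gsub("\\(.*?\\)", "", t)
  t <- gsub("\\b(mm|coord(inate)?s?)\\b", "", t)
  t <- gsub("[^a-z,;/ ]", " ", t)
  gsub(" +", " ", trimws(t))
}

#' Locate coordinate columns in a normalized table
#'
#' Searches header cells for x/y/z tokens, case-insensitively and
#' ignoring surrounding punctuation and units. Recognizes either three
#' separate columns labelled x, y, z (in that order) or one combined
#' column whose label contains all three tokens in order ("x, y, z").
#' The declared header rows are searched; when no header is marked, the
#' first body row is tried instead.
#'
#' @param table a [NormalizedTable-class]
#' @return list `(x =, y =, z =)` of column indices, or
#'   `list(xyz = <index>)` for a combined column, or NULL
#' @export
findCoordinateColumns <- function(table) {
  cells <- table@cells
  if (nrow(cells) == 0L) return(NULL)
  headerRowIdx <- if (table@nHeaderRows > 0L) seq_len(table@nHeaderRows) else 1L
  for (r in headerRowIdx) {
    toks <- unname(vapply(cells[r, ], coordToken, character(1)))
    xi <- which(toks == "x")
    if (length(xi) >= 1L) {
      for (i in xi) {
        if (i + 2L <= length(toks) && toks[i + 1L] == "y" &&
            toks[i + 2L] == "z")
          return(list(x = i, y = i + 1L, z = i + 2L,
                      headerRow = r, combined = FALSE))
      }
    }
    combined <- which(vapply(toks, function(t)
      grepl("^x[ ,;/]+y[ ,;/]+z$", t), logical(1)))
    if (length(combined) >= 1L)
      return(list(xyz = unname(combined[1L]), headerRow = r,
                  combined = TRUE))
  }
  NULL
}

# Numeric parsing accepting ASCII hyphen, Unicode minus (U+2212) and
# en-dash as negative signs.
parseCoordValue <- function(s) {
  s <- trimws(s)
  s <- gsub("−|–", "-", s)
  s <- gsub(",", "", s)
  if (!grepl("^-?[0-9]+(\\.[0-9]+)?$", s)) return(NA_real_)
  as.numeric(s)
}

#' Parse raw (x, y, z) triplets from a table
#'
#' Rows below the header are parsed at the mapped columns; combined
#' cells are split on comma, semicolon, or whitespace. A row where any
#' of the three values fails to parse is skipped.
#'
#' @param table a [NormalizedTable-class]
#' @param mapping output of [findCoordinateColumns()]
#' @return data.frame: row_index (0-based table row), x, y, z, rowKey
#'   (the raw cell values, used for byte-identical duplicate detection)
#' @export
parseTriplets <- function(table, mapping) {
  empty <- data.frame(row_index = integer(), x = numeric(), y = numeric(),
                      z = numeric(), rowKey = character(),
                      stringsAsFactors = FALSE)
  if (is.null(mapping)) return(empty)
  cells <- table@cells
  firstBody <- mapping$headerRow + 1L
  if (firstBody > nrow(cells)) return(empty)
  out <- vector("list", nrow(cells) - firstBody + 1L)
  for (r in firstBody:nrow(cells)) {
    if (isTRUE(mapping$combined)) {
      parts <- strsplit(trimws(cells[r, mapping$xyz]), "[,;[:space:]]+")[[1]]
      if (length(parts) != 3L) next
      vals <- vapply(parts, parseCoordValue, numeric(1))
      key <- cells[r, mapping$xyz]
    } else {
      raw <- cells[r, c(mapping$x, mapping$y, mapping$z)]
      vals <- vapply(raw, parseCoordValue, numeric(1))
      key <- paste(raw, collapse = "\x1f")
    }
    if (anyNA(vals)) next
    out[[r - firstBody + 1L]] <- data.frame(
      row_index = r - 1L, x = vals[1], y = vals[2], z = vals[3],
      rowKey = key, stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Filter implausible coordinate triplets
#'
#' Keeps triplets with all coordinates within 150 mm of the origin
#' (anything farther is outside any human head) and drops the exact
#' origin (0, 0, 0), a common table artifact. Within one table,
#' byte-identical repeated rows are collapsed to one; distinct rows that
#' happen to carry the same peak are kept.
#'
#' @param triplets data.frame from [parseTriplets()]
#' @return the filtered data.frame
#' @export
filterPlausible <- function(triplets) {
  if (nrow(triplets) == 0L) return(triplets)
  keep <- abs(triplets$x) <= 150 & abs(triplets$y) <= 150 &
    abs(triplets$z) <= 150 &
    !(triplets$x == 0 & triplets$y == 0 & triplets$z == 0)
  triplets <- triplets[keep, , drop = FALSE]
  triplets[!duplicated(triplets$rowKey), , drop = FALSE]
}

#' Detect the coordinate space of an article
#'
#' Deterministic keyword heuristic over title + abstract + body:
#' occurrences of Talairach cues ("talairach", "t88") and MNI cues
#' ("mni", "icbm") are counted; the higher count wins, a tie with both
#' present resolves to MNI, and no cue words yield UNKNOWN.
#'
#' @param articleText an `ArticleText` (see [extractText()])
#' @return one of "MNI", "TAL", "UNKNOWN"
#' @export
detectSpace <- function(articleText) {
  txt <- tolower(paste(articleText$title, articleText$abstract,
                       articleText$body, sep = " "))
  countCue <- function(cues) {
    sum(vapply(cues, function(cue) {
      m <- gregexpr(cue, txt, fixed = TRUE)[[1]]
      sum(m > 0L)
    }, numeric(1)))
  }
  tal <- countCue(c("talairach", "t88"))
  mni <- countCue(c("mni", "icbm"))
  if (tal == 0L && mni == 0L) return("UNKNOWN")
  if (tal > mni) "TAL" else "MNI"
}

#' Extract all coordinate records of an article
#'
#' Runs column detection, triplet parsing, and plausibility filtering
#' over every table, attaching the article-level space label.
#'
#' @param pmcid the article identifier
#' @param tables list of [NormalizedTable-class] objects
#' @param articleText the article's `ArticleText`, for space detection
#' @return data.frame: pmcid, table_id, row_index, x, y, z, space — one
#'   row per peak, in table order with rows ascending
#' @export
extractCoordinates <- function(pmcid, tables, articleText) {
  space <- detectSpace(articleText)
  out <- lapply(tables, function(tb) {
    mapping <- findCoordinateColumns(tb)
    if (is.null(mapping)) return(NULL)
    tri <- filterPlausible(parseTriplets(tb, mapping))
    if (nrow(tri) == 0L) return(NULL)
    data.frame(pmcid = pmcid, table_id = tb@tableId,
               row_index = tri$row_index, x = tri$x, y = tri$y, z = tri$z,
               space = space, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(pmcid = character(), table_id = character(),
                      row_index = integer(), x = numeric(), y = numeric(),
                      z = numeric(), space = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract coordinates for a whole corpus
#'
#' @param corpus output of [readCorpus()]
#' @return one data.frame of coordinate records across all articles
#' @export
corpusCoordinates <- function(corpus) {
  res <- do.call(rbind, lapply(corpus, function(a)
    extractCoordinates(a$metadata$pmcid, a$tables, a$text)))
  if (is.null(res))
    res <- data.frame(pmcid = character(), table_id = character(),
                      row_index = integer(), x = numeric(), y = numeric(),
                      z = numeric(), space = character(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
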