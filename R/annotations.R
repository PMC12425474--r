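# Character offsets in the interchange formats are 0-based, half-open,
# as the annotation tool counts them; R's substr is 1-based inclusive.
sliceText <- function(text, start, end) substr(text, start + 1L, end)

labelbuddyText <- function(article) {
  paste(article$text$title, article$text$abstract, article$text$body,
        sep = "\n\n")
}

#' Export a corpus to the annotation tool's JSONLines format
#'
#' One JSON object per line per article: `text` is title, abstract, and
#' body joined by blank lines (section character offsets recorded in
#' the metadata), `metadata` carries the pmcid, doi, and year. UTF-8,
#' LF line endings. The file imports directly into a labelbuddy
#' database.
#'
#' @param corpus output of [readCorpus()]
#' @param path output `.jsonl` file
#' @return the path, invisibly
#' @export
exportLabelbuddy <- function(corpus, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (a in corpus) {
    title <- a$text$title
    abstract <- a$text$abstract
    txt <- labelbuddyText(a)
    titleEnd <- nchar(title)
    absStart <- titleEnd + 2L
    absEnd <- absStart + nchar(abstract)
    bodyStart <- absEnd + 2L
    obj <- list(
      text = txt,
      display_title = paste0(a$metadata$pmcid, " ", title),
      metadata = list(
        pmcid = a$metadata$pmcid,
        doi = a$metadata$doi,
        publication_year = a$metadata$publicationYear,
        field_positions = list(
          title = c(0L, titleEnd),
          abstract = c(absStart, absEnd),
          body = c(bodyStart, nchar(txt))
        )
      )
    )
    line <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null",
                             na = "null", digits = NA)
    writeBin(charToRaw(paste0(line, "\n")), con)
  }
  invisible(path)
}

#' Import annotations from JSON or JSONLines
#'
#' Accepts a JSON array or one JSON object per line; both the
#' `start`/`end` and `start_char`/`end_char` offset spellings and both
#' `label` and `label_name` are understood. Every annotation is
#' validated against the document text it carries: offsets must be in
#' bounds and, when `selected_text` is present, must slice to exactly
#' that string.
#'
#' @param path annotation file
#' @return named list (by pmcid): each element a list with `text` and
#'   `annotations` (data.frame start, end, label, selected_text)
#' @export
importAnnotations <- function(path) {
  firstChar <- substr(trimws(readChar(path, 1000L, useBytes = FALSE)), 1, 1)
  docs <- if (firstChar == "[") {
    jsonlite::read_json(path)
  } else {
    lapply(readLines(path, encoding = "UTF-8", warn = FALSE),
           jsonlite::parse_json)
  }
  out <- list()
  for (doc in docs) {
    pmcid <- doc$metadata$pmcid %||% doc$display_title %||% "unknown"
    text <- doc$text %||% ""
    anns <- doc$annotations %||% list()
    rows <- lapply(seq_along(anns), function(k) {
      ann <- anns[[k]]
      start <- ann$start_char %||% ann$start
      end <- ann$end_char %||% ann$end
      label <- ann$label_name %||% ann$label
      if (is.null(start) || is.null(end) || is.null(label))
        stop(sprintf("document '%s', annotation %d: missing offsets or label",
                     pmcid, k))
      start <- as.integer(start)
      end <- as.integer(end)
      if (start < 0L || end <= start || end > nchar(text))
        stop(sprintf(
          "document '%s', annotation %d: span [%d, %d) out of bounds",
          pmcid, k, start, end))
      sel <- ann$selected_text
      if (!is.null(sel) && !identical(sliceText(text, start, end), sel))
        stop(sprintf(
          "document '%s', annotation %d: selected_text does not match slice [%d, %d)",
          pmcid, k, start, end))
      data.frame(start = start, end = end, label = label,
                 selected_text = sel %||% sliceText(text, start, end),
                 stringsAsFactors = FALSE)
    })
    out[[pmcid]] <- list(
      text = text,
      annotations = if (length(rows)) do.call(rbind, rows)
      else data.frame(start = integer(), end = integer(),
                      label = character(), selected_text = character(),
                      stringsAsFactors = FALSE)
    )
  }
  out
}

#' Build a sample-size truth table from annotations
#'
#' For each document, parses the integer inside the first span carrying
#' `labelName`; documents without the label are absent from the result.
#'
#' @param annotations output of [importAnnotations()]
#' @param labelName the label to read (e.g. "total" or "count")
#' @return named numeric vector: pmcid -> sample size
#' @export
annotationsToTruth <- function(annotations, labelName = "total") {
  out <- numeric()
  for (pmcid in names(annotations)) {
    anns <- annotations[[pmcid]]$annotations
    hit <- which(anns$label == labelName)
    if (length(hit) == 0L) next
    span <- anns$selected_text[hit[1]]
    digits <- regmatches(span, regexpr("\\d[\\d,]*", span, perl = TRUE))
    if (length(digits) == 0L)
      stop(sprintf("document '%s': span '%s' under label '%s' is not numeric",
                   pmcid, span, labelName))
    out[pmcid] <- as.numeric(gsub(",", "", digits))
  }
  out
}

#' Export coordinates as a coordinate-dataset JSON file
#'
#' Writes the layout used by coordinate-based meta-analysis libraries
#' (NiMARE): one entry per article keyed by its identifier, each holding
#' one contrast with its peak coordinate lists and basic metadata.
#' Articles with no peaks are omitted; an article with coordinates but
#' no metadata gets an identifier-only entry with a warning.
#'
#' @param coords coordinate records (see [corpusCoordinates()])
#' @param metadata data.frame of article metadata
#'   (`corpusTables(corpus)$metadata`), or NULL
#' @param path output JSON file
#' @return the path, invisibly
#' @export
exportNimare <- function(coords, metadata = NULL, path) {
  entries <- list()
  for (pmcid in unique(coords$pmcid)) {
    pk <- coords[coords$pmcid == pmcid, , drop = FALSE]
    if (nrow(pk) == 0L) next
    space <- pk$space[1]
    contrast <- list(
      coords = list(
        space = space,
        x = pk$x, y = pk$y, z = pk$z
      ),
      metadata = list()
    )
    if (!is.null(metadata) && pmcid %in% metadata$pmcid) {
      m <- metadata[metadata$pmcid == pmcid, , drop = FALSE]
      contrast$metadata <- list(
        title = m$title[1],
        year = m$publication_year[1],
        journal = m$journal[1]
      )
    } else {
      warning(sprintf("article '%s' has coordinates but no metadata", pmcid))
    }
    entries[[pmcid]] <- list(contrasts = list(`1` = contrast))
  }
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
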