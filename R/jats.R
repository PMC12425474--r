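#' Split an article-set batch into single-article documents
#'
#' @param batchFile path to an article-set XML file (one download batch)
#' @return list of `xml_document`s, one per `article` element, in batch
#'   order; each is independently well-formed
#' @export
splitArticleSet <- function(batchFile) {
  doc <- tryCatch(xml2::read_xml(batchFile), error = function(e)
    stop(sprintf("malformed XML in batch '%s': %s", batchFile,
                 conditionMessage(e))))
  nodes <- xml2::xml_find_all(doc, "//article")
  lapply(nodes, function(node) xml2::read_xml(as.character(node)))
}

xmlText1 <- function(doc, xpath) {
  node <- xml2::xml_find_first(doc, xpath)
  if (inherits(node, "xml_missing")) return(NA_character_)
  txt <- normalizeText(xml2::xml_text(node))
  if (!nzchar(txt)) NA_character_ else txt
}

# Year precedence: print date, else electronic date, else collection
# date, else any pub-date.
extractYear <- function(article) {
  for (xp in c(
    "//article-meta/pub-date[@pub-type='ppub' or @publication-format='print']/year",
    "//article-meta/pub-date[@pub-type='epub' or @date-type='pub']/year",
    "//article-meta/pub-date[@pub-type='collection']/year",
    "//article-meta/pub-date/year"
  )) {
    y <- xmlText1(article, xp)
    if (!is.na(y) && grepl("^[0-9]{4}$", y)) return(as.integer(y))
  }
  NA_integer_
}

#' Extract article metadata
#'
#' Pulls identifiers, title, journal, publication year, authors, and
#' license from a single-article JATS document. Fields that cannot be
#' located are `NA`, never empty strings; a missing PMCID is an error
#' because identity is mandatory.
#'
#' @param article an `xml_document` for one article
#' @return named list: pmcid, pmid, doi, title, journal,
#'   publicationYear, authors (data.frame surname/givenNames), license
#' @export
extractMetadata <- function(article) {
  pmcid <- xmlText1(
    article,
    "//article-meta/article-id[@pub-id-type='pmcid' or @pub-id-type='pmc']"
  )
  if (is.na(pmcid)) stop("article has no pmcid")
  if (!grepl("^PMC", pmcid)) pmcid <- paste0("PMC", pmcid)
  authorNodes <- xml2::xml_find_all(
    article, "//article-meta/contrib-group/contrib[@contrib-type='author']/name"
  )
  if (length(authorNodes) == 0L)
    authorNodes <- xml2::xml_find_all(
      article, "//article-meta/contrib-group/contrib/name")
  authors <- data.frame(
    surname = vapply(authorNodes, function(n)
      normalizeText(xml2::xml_text(
        xml2::xml_find_first(n, "./surname"))), character(1)),
    givenNames = vapply(authorNodes, function(n) {
      g <- xml2::xml_find_first(n, "./given-names")
      if (inherits(g, "xml_missing")) NA_character_
      else normalizeText(xml2::xml_text(g))
    }, character(1)),
    stringsAsFactors = FALSE
  )
  list(
    pmcid = pmcid,
    pmid = xmlText1(article, "//article-meta/article-id[@pub-id-type='pmid']"),
    doi = xmlText1(article, "//article-meta/article-id[@pub-id-type='doi']"),
    title = xmlText1(article, "//article-meta/title-group/article-title"),
    journal = xmlText1(article, "//journal-meta//journal-title"),
    publicationYear = extractYear(article),
    authors = authors,
    license = xmlText1(article, "//article-meta/permissions/license")
  )
}

# Text content of a node with table-wrap subtrees removed (tables are
# extracted separately) and inline markup reduced to its text.
nodeTextNoTables <- function(node) {
  copy <- xml2::read_xml(as.character(node))
  for (tw in xml2::xml_find_all(copy, ".//table-wrap")) xml2::xml_remove(tw)
  normalizeText(xml2::xml_text(copy))
}

#' Extract markup-free text from an article
#'
#' Returns the title, keywords, abstract, and body with all XML markup
#' stripped: inline emphasis and links are reduced to their text, tables
#' are excluded (they are extracted separately by [extractTables()]),
#' paragraphs are separated by blank lines, and whitespace is
#' normalized.
#'
#' @param article an `xml_document` for one article
#' @return named list of class `ArticleText`: title, keywords
#'   (character vector), abstract, body
#' @export
extractText <- function(article) {
  title <- xmlText1(article, "//article-meta/title-group/article-title")
  keywords <- vapply(
    xml2::xml_find_all(article, "//article-meta/kwd-group/kwd"),
    function(n) normalizeText(xml2::xml_text(n)), character(1)
  )
  absNode <- xml2::xml_find_first(article, "//article-meta/abstract")
  abstract <- if (inherits(absNode, "xml_missing")) ""
  else nodeTextNoTables(absNode)
  bodyNode <- xml2::xml_find_first(article, "//body")
  body <- ""
  if (!inherits(bodyNode, "xml_missing")) {
    paras <- xml2::xml_find_all(
      bodyNode, ".//p[not(ancestor::table-wrap)] | .//title[not(ancestor::table-wrap)]"
    )
    chunks <- vapply(paras, function(p) normalizeText(xml2::xml_text(p)),
                     character(1))
    body <- paste(chunks[nzchar(chunks)], collapse = "\n\n")
  }
  structure(
    list(title = if (is.na(title)) "" else title,
         keywords = keywords, abstract = abstract, body = body),
    class = "ArticleText"
  )
}

#' Read, parse and assemble a full corpus from downloaded batches
#'
#' Convenience wrapper running [splitArticleSet()], [extractMetadata()],
#' [extractText()] and [extractTables()] over every batch file in a
#' directory.
#'
#' @param articlesetsDir directory holding `batch_*.xml` files
#' @return list of articles; each has elements `metadata`, `text`,
#'   `tables`
#' @export
readCorpus <- function(articlesetsDir) {
  files <- sort(list.files(articlesetsDir, pattern = "^batch_.*\\.xml$",
                           full.names = TRUE))
  out <- list()
  for (f in files) {
    for (doc in splitArticleSet(f)) {
      meta <- extractMetadata(doc)
      out[[meta$pmcid]] <- list(
        metadata = meta,
        text = extractText(doc),
        tables = extractTables(doc)
      )
    }
  }
  out
}

#' Flatten corpus metadata and text into data frames
#'
#' @param corpus output of [readCorpus()]
#' @return list with `metadata` and `text` data.frames (one row per
#'   article, CSV-ready)
#' @export
corpusTables <- function(corpus) {
  meta <- do.call(rbind, lapply(corpus, function(a) {
    m <- a$metadata
    data.frame(
      pmcid = m$pmcid, pmid = m$pmid, doi = m$doi, title = m$title,
      journal = m$journal, publication_year = m$publicationYear,
      authors = paste(
        paste(m$authors$surname, m$authors$givenNames, sep = ", "),
        collapse = "; "
      ),
      license = m$license, stringsAsFactors = FALSE
    )
  }))
  txt <- do.call(rbind, lapply(corpus, function(a) {
    data.frame(
      pmcid = a$metadata$pmcid, title = a$text$title,
      keywords = paste(a$text$keywords, collapse = "; "),
      abstract = a$text$abstract, body = a$text$body,
      stringsAsFactors = FALSE
    )
  }))
  rownames(meta) <- rownames(txt) <- NULL
  list(metadata = meta, text = txt)
}
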