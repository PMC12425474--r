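# Hand-built JATS fixtures, constructed in code at test time.

jatsArticle <- function(pmcid = "PMC1234567", pmid = NULL, year = 2021,
                        yearTag = "ppub", authors = list(c("Doe", "Jane")),
                        title = "A planted title", abstract = "Planted abstract.",
                        keywords = character(), bodySecs = "Planted body.",
                        tablesXml = "") {
  authorXml <- paste(vapply(authors, function(a) sprintf(
    paste0("<contrib contrib-type=\"author\"><name><surname>%s</surname>",
           "<given-names>%s</given-names></name></contrib>"),
    a[1], a[2]), character(1)), collapse = "")
  pmidXml <- if (is.null(pmid)) ""
  else sprintf("<article-id pub-id-type=\"pmid\">%s</article-id>", pmid)
  kwXml <- if (length(keywords))
    paste0("<kwd-group>", paste(sprintf("<kwd>%s</kwd>", keywords),
                                collapse = ""), "</kwd-group>")
  else ""
  secs <- paste(vapply(seq_along(bodySecs), function(i) sprintf(
    "<sec><title>Section %d</title><p>%s</p></sec>", i, bodySecs[i]),
    character(1)), collapse = "")
  sprintf(paste0(
    "<article><front><article-meta>",
    "<article-id pub-id-type=\"pmcid\">%s</article-id>%s",
    "<title-group><article-title>%s</article-title></title-group>",
    "<contrib-group>%s</contrib-group>",
    "<pub-date pub-type=\"%s\"><year>%d</year></pub-date>",
    "%s<abstract><p>%s</p></abstract>",
    "</article-meta></front><body>%s%s</body></article>"),
    pmcid, pmidXml, title, authorXml, yearTag, year, kwXml, abstract,
    secs, tablesXml)
}

articleSet <- function(...) paste0("<pmc-articleset>",
                                   paste(..., collapse = ""),
                                   "</pmc-articleset>")

readArticle <- function(xmlString) xml2::read_xml(xmlString)

# Paired-dialect coordinate table builders (same logical content).
xhtmlTable <- function(header, rows, id = "tbl1") {
  h <- paste(sprintf("<th>%s</th>", header), collapse = "")
  b <- paste(vapply(rows, function(r)
    paste0("<tr>", paste(sprintf("<td>%s</td>", r), collapse = ""), "</tr>"),
    character(1)), collapse = "")
  sprintf(paste0("<table-wrap id=\"%s\"><table><thead><tr>%s</tr></thead>",
                 "<tbody>%s</tbody></table></table-wrap>"), id, h, b)
}

oasisTable <- function(header, rows, id = "tbl1") {
  n <- length(header)
  cs <- paste(sprintf("<colspec colname=\"c%d\"/>", seq_len(n)),
              collapse = "")
  h <- paste(sprintf("<entry>%s</entry>", header), collapse = "")
  b <- paste(vapply(rows, function(r)
    paste0("<row>", paste(sprintf("<entry>%s</entry>", r), collapse = ""),
           "</row>"), character(1)), collapse = "")
  sprintf(paste0("<table-wrap id=\"%s\"><table><tgroup cols=\"%d\">%s",
                 "<thead><row>%s</row></thead><tbody>%s</tbody>",
                 "</tgroup></table></table-wrap>"), id, n, cs, h, b)
}

firstTable <- function(tableXml) {
  extractTables(readArticle(jatsArticle(tablesXml = tableXml)))[[1]]
}

# Shared acceptance-scale corpus (200 studies, seed 11), built once per
# test run.
acceptanceEnv <- new.env(parent = emptyenv())

acceptanceCorpus <- function() {
  if (is.null(acceptanceEnv$data)) {
    dir <- tempfile("acc-corpus")
    ledger <- generateCorpus(corpusSpec(nArticles = 200, seed = 11), dir)
    corpus <- readCorpus(file.path(dir, "articlesets"))
    coords <- corpusCoordinates(corpus)
    acceptanceEnv$data <- list(dir = dir, ledger = ledger, corpus = corpus,
                               coords = coords)
  }
  acceptanceEnv$data
}

# Byte content of every file under a directory (step sentinels carry
# run ids, so they are excluded from byte-identity comparisons).
treeBytes <- function(root, exclude = "info\\.json$") {
  files <- list.files(root, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl(exclude, files)]
  out <- lapply(files, function(f) readBin(f, "raw", file.size(f)))
  names(out) <- sub(paste0("^", root), "", files)
  out
}

# Linear (1-based, column-major) voxel index of a world coordinate.
voxelIndexOf <- function(grid, xyz) {
  ijk <- round((xyz - grid@origin) / grid@voxelSize)
  as.integer(1L + ijk[1] + grid@shape[1] * (ijk[2] + grid@shape[2] * ijk[3]))
}
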