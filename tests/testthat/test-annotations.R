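miniCorpus <- function(n = 3) {
  dir <- tempfile()
  generateCorpus(corpusSpec(nArticles = n, seed = 21), dir)
  readCorpus(file.path(dir, "articlesets"))
}

test_that("labelbuddy export writes one parseable JSON object per article", {
  corpus <- miniCorpus(3)
  f <- tempfile(fileext = ".jsonl")
  exportLabelbuddy(corpus, f)
  lines <- readLines(f, encoding = "UTF-8")
  expect_length(lines, 3L)
  objs <- lapply(lines, jsonlite::parse_json)
  expect_identical(
    vapply(objs, function(o) o$metadata$pmcid, character(1)),
    unname(vapply(corpus, function(a) a$metadata$pmcid, character(1)))
  )
  # section offsets slice the joined text back into its parts
  o <- objs[[1]]
  fp <- o$metadata$field_positions
  a <- corpus[[1]]
  expect_identical(substr(o$text, fp$title[[1]] + 1, fp$title[[2]]),
                   a$text$title)
  expect_identical(substr(o$text, fp$abstract[[1]] + 1, fp$abstract[[2]]),
                   a$text$abstract)
})

test_that("export then import round-trips text and metadata", {
  corpus <- miniCorpus(3)
  f <- tempfile(fileext = ".jsonl")
  exportLabelbuddy(corpus, f)
  docs <- importAnnotations(f)
  for (pmcid in names(docs)) {
    expect_identical(docs[[pmcid]]$text,
                     paste(corpus[[pmcid]]$text$title,
                           corpus[[pmcid]]$text$abstract,
                           corpus[[pmcid]]$text$body, sep = "\n\n"))
  }
})

test_that("annotation import validates spans against the carried text", {
  f <- tempfile(fileext = ".jsonl")
  good <- list(text = "We recruited 25 healthy participants.",
               metadata = list(pmcid = "PMC1"),
               annotations = list(list(start_char = 13, end_char = 18,
                                       label_name = "count",
                                       selected_text = "25 he")))
  writeLines(jsonlite::toJSON(good, auto_unbox = TRUE), f)
  docs <- importAnnotations(f)
  expect_identical(docs$PMC1$annotations$selected_text, "25 he")

  # both offset spellings are accepted
  alt <- good
  alt$annotations <- list(list(start = 13, end = 18, label = "count"))
  writeLines(jsonlite::toJSON(alt, auto_unbox = TRUE), f)
  expect_identical(importAnnotations(f)$PMC1$annotations$label, "count")

  # out-of-bounds end
  bad <- good
  bad$annotations[[1]]$end_char <- 99999
  writeLines(jsonlite::toJSON(bad, auto_unbox = TRUE), f)
  expect_error(importAnnotations(f), "out of bounds")

  # slice mismatch
  bad2 <- good
  bad2$annotations[[1]]$selected_text <- "mismatch"
  writeLines(jsonlite::toJSON(bad2, auto_unbox = TRUE), f)
  expect_error(importAnnotations(f), "selected_text")

  # a JSON array (not JSONLines) also parses
  writeLines(jsonlite::toJSON(list(good), auto_unbox = TRUE), f)
  expect_identical(names(importAnnotations(f)), "PMC1")
})

test_that("truth tables read the first labelled span, extracting the integer", {
  f <- tempfile(fileext = ".jsonl")
  doc <- function(pmcid, text, spans) {
    list(text = text, metadata = list(pmcid = pmcid), annotations = spans)
  }
  span <- function(s, e, label) list(start_char = s, end_char = e,
                                     label_name = label)
  docs <- list(
    doc("PMC1", "Total was 38 subjects.", list(span(10, 12, "total"))),
    doc("PMC2", "A group of n = 25 scanned.", list(span(11, 17, "total"))),
    doc("PMC3", "No relevant label here.", list(span(0, 2, "other")))
  )
  writeLines(vapply(docs, function(d)
    as.character(jsonlite::toJSON(d, auto_unbox = TRUE)), character(1)), f)
  truth <- annotationsToTruth(importAnnotations(f), "total")
  expect_identical(truth, c(PMC1 = 38, PMC2 = 25))  # "n = 25" -> 25; PMC3 absent
})

test_that("the coordinate-dataset export mirrors record counts and spaces", {
  coords <- data.frame(
    pmcid = c(rep("PMC1", 3), rep("PMC2", 2)),
    table_id = "tbl1", row_index = 0:4 %% 3,
    x = c(1, 2, 3, 4, 5), y = 0, z = 0,
    space = c(rep("MNI", 3), rep("TAL", 2)), stringsAsFactors = FALSE
  )
  meta <- data.frame(pmcid = c("PMC1", "PMC2"), title = c("t1", "t2"),
                     publication_year = c(2020L, 2021L),
                     journal = "J", stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".json")
  exportNimare(coords, meta, f)
  ds <- jsonlite::read_json(f)
  expect_identical(names(ds), c("PMC1", "PMC2"))
  expect_length(ds$PMC1$contrasts$`1`$coords$x, 3L)
  expect_length(ds$PMC2$contrasts$`1`$coords$x, 2L)
  expect_identical(ds$PMC2$contrasts$`1`$coords$space, "TAL")
  # total exported peaks equal the record count
  nPeaks <- sum(vapply(ds, function(e)
    length(e$contrasts$`1`$coords$x), integer(1)))
  expect_identical(nPeaks, nrow(coords))
  # missing metadata still yields an identifier-only entry, with a warning
  expect_warning(exportNimare(coords[coords$pmcid == "PMC1", ],
                              meta[meta$pmcid == "PMC2", , drop = FALSE], f),
                 "metadata")
})
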