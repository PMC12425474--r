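test_that("coordinate columns are found as separate or combined headers", {
  sep <- firstTable(xhtmlTable(c("Region", "x", "y", "z", "t"),
                               list(c("ACC", "1", "2", "3", "4"))))
  m <- findCoordinateColumns(sep)
  expect_identical(m[c("x", "y", "z")], list(x = 2L, y = 3L, z = 4L))

  comb <- firstTable(xhtmlTable(c("Region", "x, y, z"),
                                list(c("ACC", "1, 2, 3"))))
  mc <- findCoordinateColumns(comb)
  expect_true(mc$combined)
  expect_identical(mc$xyz, 2L)

  none <- firstTable(xhtmlTable(c("Region", "N", "p"),
                                list(c("ACC", "20", ".01"))))
  expect_null(findCoordinateColumns(none))

  # decorations and case are ignored
  dec <- firstTable(xhtmlTable(c("Region", "X (mm)", "Y (mm)", "Z (mm)"),
                               list(c("ACC", "1", "2", "3"))))
  expect_identical(findCoordinateColumns(dec)$x, 2L)

  # unmarked header: first body row is tried
  raw <- paste0("<table-wrap id=\"t\"><table><tbody>",
                "<tr><td>Region</td><td>x</td><td>y</td><td>z</td></tr>",
                "<tr><td>ACC</td><td>1</td><td>2</td><td>3</td></tr>",
                "</tbody></table></table-wrap>")
  expect_identical(findCoordinateColumns(firstTable(raw))$x, 2L)
})

test_that("triplets parse Unicode minus, split combined cells, skip bad rows", {
  tb <- firstTable(xhtmlTable(
    c("Region", "x", "y", "z", "t"),
    list(c("ACC", "−42", "12", "8", "3.1"),   # Unicode minus
         c("SMA", "n.s.", "1", "2", "0.5"),        # unparseable -> skipped
         c("PCC", "–0", "–52", "26", "2.2"))  # en-dash minus
  ))
  tri <- parseTriplets(tb, findCoordinateColumns(tb))
  expect_identical(nrow(tri), 2L)
  expect_identical(tri$x, c(-42, 0))
  expect_identical(tri$y, c(12, -52))
  expect_identical(tri$row_index, c(1L, 3L))

  comb <- firstTable(xhtmlTable(c("Region", "x, y, z"),
                                list(c("ACC", "12; −34; 56"))))
  tric <- parseTriplets(comb, findCoordinateColumns(comb))
  expect_identical(unlist(tric[1, c("x", "y", "z")], use.names = FALSE),
                   c(12, -34, 56))
})

test_that("plausibility filtering drops out-of-range and origin artifacts", {
  tri <- data.frame(
    row_index = 0:3,
    x = c(-42, 1200, 0, -42), y = c(12, 4, 0, 12), z = c(8, 7, 0, 8),
    rowKey = c("a", "b", "c", "a"), stringsAsFactors = FALSE
  )
  kept <- filterPlausible(tri)
  # (-42,12,8) kept once (byte-identical repeat collapsed),
  # (1200,4,7) out of range, (0,0,0) origin artifact
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$x, -42)

  # distinct rows carrying the same peak are kept
  tri2 <- tri[c(1, 4), ]
  tri2$rowKey <- c("a", "a2")
  expect_identical(nrow(filterPlausible(tri2)), 2L)
})

test_that("space detection follows the cue-count precedence", {
  txt <- function(body) list(title = "", keywords = character(),
                             abstract = "", body = body)
  expect_identical(detectSpace(txt("registered to Talairach atlas space")),
                   "TAL")
  expect_identical(detectSpace(txt("normalized to MNI152 template")), "MNI")
  expect_identical(detectSpace(txt("no cue words at all")), "UNKNOWN")
  # tie with both present resolves to MNI
  expect_identical(detectSpace(txt("Talairach coordinates converted to MNI")),
                   "MNI")
  # majority wins
  expect_identical(
    detectSpace(txt("Talairach, Talairach again, and mni once")), "TAL")
})

test_that("planted coordinates are recovered exactly across both dialects", {
  for (mix in c(0, 1)) {
    dir <- tempfile()
    ledger <- generateCorpus(corpusSpec(nArticles = 15, seed = 3,
                                        tableDialectMix = mix), dir)
    corpus <- readCorpus(file.path(dir, "articlesets"))
    got <- corpusCoordinates(corpus)
    expect_identical(
      sort(paste(got$pmcid, got$x, got$y, got$z)),
      sort(paste(ledger$coords$pmcid, ledger$coords$x, ledger$coords$y,
                 ledger$coords$z))
    )
    # records preserve table order with ascending rows
    for (id in unique(got$pmcid)) {
      ri <- got$row_index[got$pmcid == id]
      expect_identical(ri, sort(ri))
    }
    # space label is constant within an article
    expect_true(all(tapply(got$space, got$pmcid,
                           function(s) length(unique(s))) == 1L))
  }
})
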