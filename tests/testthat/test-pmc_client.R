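test_that("search builds handles with distinct-ID semantics and scripted counts", {
  tp <- mockPmcTransport(character(), searchCount = 1234L)
  h <- searchPmc("fMRI[Abstract]", tp)
  expect_s4_class(h, "SearchHandle")
  expect_identical(resultCount(h), 1234L)
  expect_true(nzchar(h@webenv) && nzchar(h@queryKey))

  ids <- c("PMC1", "PMC2", "PMC3")
  expect_identical(resultCount(searchPmc(ids, mockPmcTransport(ids))), 3L)
  # duplicated entry collapses: set semantics
  dup <- c("PMC1", "PMC2", "PMC3", "PMC2")
  expect_identical(resultCount(searchPmc(dup, mockPmcTransport(dup))), 3L)
  # no request is issued for an ID list
  tp2 <- mockPmcTransport(ids)
  searchPmc(ids, tp2)
  expect_identical(callCount(tp2), 0L)
})

test_that("batch planning partitions the result set", {
  h <- function(n) new("SearchHandle", query = "q", ids = character(),
                       resultCount = as.integer(n), webenv = "w",
                       queryKey = "1", createdAt = Sys.time())
  st <- planBatches(h(1234), batchSize = 500, dir = tempfile())
  expect_identical(nrow(st@batches), 3L)
  expect_identical(st@batches$index, 0:2)
  # last batch carries the remainder: 500, 500, 234
  ids <- sprintf("PMC%d", 1:1234)
  hIds <- searchPmc(ids, mockPmcTransport(ids))
  stIds <- planBatches(hIds, 500, dir = tempfile())
  expect_identical(nrow(stIds@batches), 3L)

  expect_identical(nrow(planBatches(h(500), 500, tempfile())@batches), 1L)
  expect_identical(nrow(planBatches(h(0), 500, tempfile())@batches), 0L)
})

test_that("response validation distinguishes article sets from masked errors", {
  ok <- validateResponse("<pmc-articleset><article/><article/></pmc-articleset>",
                         200L)
  expect_true(ok$valid)
  # a 200 status whose body is an error message is invalid
  soft <- validateResponse("internal server error occurred", 200L)
  expect_false(soft$valid)
  expect_false(validateResponse("<pmc-articleset/>", 500L)$valid)
  expect_false(validateResponse("<pmc-articleset><error/></pmc-articleset>",
                                200L)$valid)
})

test_that("fetch retries failing batches and resumes without re-downloading", {
  ids <- sprintf("PMC%d", 1:30)
  dir <- tempfile()
  noSleep <- function(s) NULL

  # fails twice on batch 0, succeeds on the 3rd call
  tp <- mockPmcTransport(ids, failPlan = c(`0` = 2L))
  st <- planBatches(searchPmc(ids, tp), batchSize = 10, dir = dir)
  st <- fetchAll(st, tp, dir = dir, maxAttempts = 3, sleeper = noSleep)
  expect_identical(st@batches$status, rep("done", 3))
  calls <- transportCalls(tp)
  batch0 <- Filter(function(p) identical(p$retstart, 0L), calls)
  expect_length(batch0, 3L)

  # second run: already complete, zero transport calls, identical bytes
  before <- lapply(st@batches$path, function(p) readBin(p, "raw", file.size(p)))
  tp2 <- mockPmcTransport(ids)
  st2 <- fetchAll(loadDownloadState(dir), tp2, dir = dir, sleeper = noSleep)
  expect_identical(callCount(tp2), 0L)
  after <- lapply(st2@batches$path, function(p) readBin(p, "raw", file.size(p)))
  expect_identical(before, after)

  # crash-safety: with one batch done, only the remaining two are fetched
  dir3 <- tempfile()
  tpA <- mockPmcTransport(ids)
  stA <- planBatches(searchPmc(ids, tpA), batchSize = 10, dir = dir3)
  stA@batches$status[2:3] <- "pending"
  oneDone <- stA
  oneDone@batches <- oneDone@batches[1, , drop = FALSE]
  oneDone@handle@resultCount <- 10L
  oneDone@handle@ids <- ids[1:10]
  fetchAll(oneDone, tpA, dir = dir3, sleeper = noSleep)
  tpB <- mockPmcTransport(ids)
  stB <- stA
  stB@batches$status[1] <- "done"
  fetchAll(stB, tpB, dir = dir3, sleeper = noSleep)
  expect_identical(callCount(tpB), 2L)
})

test_that("a persistently failing transport marks batches failed after maxAttempts", {
  ids <- sprintf("PMC%d", 1:20)
  tp <- mockPmcTransport(ids, failPlan = c(`0` = 99L, `10` = 99L))
  dir <- tempfile()
  st <- planBatches(searchPmc(ids, tp), batchSize = 10, dir = dir)
  nBefore <- callCount(tp)
  st <- fetchAll(st, tp, dir = dir, maxAttempts = 2, sleeper = function(s) NULL)
  expect_identical(st@batches$status, rep("failed", 2))
  expect_identical(callCount(tp) - nBefore, 4L)
})

test_that("throttling enforces the rate over a sliding window and attaches the key", {
  clock <- fakeClock()
  inner <- newTransport(function(params) list(status = 200L, body = "ok"))
  tp <- throttleTransport(inner, ratePerSec = 3, clock = clock)
  for (i in 1:10) tp$request(list(endpoint = "efetch"))
  expect_gte(clock$now(), 3)

  # a non-binding limit passes straight through
  clock2 <- fakeClock()
  tp2 <- throttleTransport(newTransport(function(p) list(status = 200L, body = "")),
                           ratePerSec = 1000, clock = clock2)
  for (i in 1:10) tp2$request(list(endpoint = "efetch"))
  expect_identical(clock2$now(), 0)

  # API key on every request, and the with-key default rate is 10/s
  inner3 <- newTransport(function(p) list(status = 200L, body = ""))
  tp3 <- throttleTransport(inner3, apiKey = "SECRET", clock = fakeClock())
  for (i in 1:5) tp3$request(list(endpoint = "esearch"))
  keys <- vapply(transportCalls(inner3), function(p) p$api_key, character(1))
  expect_identical(keys, rep("SECRET", 5))
})
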