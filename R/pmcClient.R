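#' Search PMC or register an explicit ID list
#'
#' For a query string, runs E-Search against the PMC database and stores
#' the history-server keys identifying the (immutable) result set. For a
#' character vector of PMCIDs, builds a handle directly from the distinct
#' well-formed IDs; no request is made.
#'
#' @param queryOrIds a single query string, or a character vector of
#'   PMCIDs ("PMC1234567" or plain digits)
#' @param transport a `pmcTransport` (see [newTransport()])
#' @param maxAttempts attempts before a transport failure becomes an error
#' @param backoff initial retry delay in seconds, doubled per attempt
#' @param sleeper sleep function, injectable for tests
#' @return a [SearchHandle-class]
#' @export
searchPmc <- function(queryOrIds, transport, maxAttempts = 4L, backoff = 1,
                      sleeper = Sys.sleep) {
  if (length(queryOrIds) > 1L || grepl("^(PMC)?[0-9]+$", queryOrIds[1])) {
    ids <- unique(queryOrIds[grepl("^(PMC)?[0-9]+$", queryOrIds)])
    if (length(ids) == 0L) stop("no well-formed PMCIDs in the ID list")
    ids <- ifelse(grepl("^PMC", ids), ids, paste0("PMC", ids))
    ids <- unique(ids)
    return(new("SearchHandle", query = "", ids = ids,
               resultCount = length(ids), webenv = "", queryKey = "",
               createdAt = Sys.time()))
  }
  if (!nzchar(queryOrIds)) stop("query must be non-empty")
  resp <- requestWithRetry(
    transport,
    list(endpoint = "esearch", db = "pmc", term = queryOrIds,
         usehistory = "y"),
    maxAttempts = maxAttempts, backoff = backoff, sleeper = sleeper,
    validate = function(resp) {
      resp$status == 200L && grepl("<Count>", resp$body, fixed = TRUE)
    }
  )
  doc <- xml2::read_xml(resp$body)
  count <- as.integer(xml2::xml_text(xml2::xml_find_first(doc, "//Count")))
  webenv <- xml2::xml_text(xml2::xml_find_first(doc, "//WebEnv"))
  qk <- xml2::xml_text(xml2::xml_find_first(doc, "//QueryKey"))
  new("SearchHandle", query = queryOrIds, ids = character(),
      resultCount = count,
      webenv = if (is.na(webenv)) "" else webenv,
      queryKey = if (is.na(qk)) "" else qk,
      createdAt = Sys.time())
}

requestWithRetry <- function(transport, params, maxAttempts, backoff,
                             sleeper, validate) {
  last <- NULL
  for (attempt in seq_len(maxAttempts)) {
    last <- transport$request(params)
    if (validate(last)) return(last)
    if (attempt < maxAttempts) sleeper(backoff * 2^(attempt - 1L))
  }
  structure(
    class = c("pmcRetrievalError", "error", "condition"),
    list(message = sprintf("request failed after %d attempts (last status %d)",
                           maxAttempts, last$status),
         call = sys.call(-1), response = last)
  ) |> stop()
}

#' Plan download batches for a result set
#'
#' Partitions the result set into batches of `batchSize` articles (the
#' last batch may be smaller) and assigns each its output file under
#' `dir/articlesets/`.
#'
#' @param handle a [SearchHandle-class]
#' @param batchSize articles per batch (default 500)
#' @param dir download directory
#' @return a [DownloadState-class] with all batches pending
#' @export
planBatches <- function(handle, batchSize = 500L, dir = ".") {
  stopifnot(batchSize >= 1L)
  nBatches <- as.integer(ceiling(handle@resultCount / batchSize))
  idx <- if (nBatches > 0L) seq_len(nBatches) - 1L else integer()
  batches <- data.frame(
    index = idx,
    status = rep("pending", nBatches),
    path = file.path(dir, "articlesets", sprintf("batch_%05d.xml", idx)),
    stringsAsFactors = FALSE
  )
  new("DownloadState", handle = handle, batchSize = as.integer(batchSize),
      batches = batches)
}

#' Validate an E-Fetch response body
#'
#' The NLM servers sometimes answer with status 200 although an internal
#' error occurred and the body is an error message, so a batch counts as
#' downloaded only when its payload is a well-formed article set: status
#' 200, parseable XML, root element `pmc-articleset` (or `article`), and
#' no error element.
#'
#' @param payload response body (character)
#' @param status HTTP status code
#' @return list(valid = logical, reason = character)
#' @export
validateResponse <- function(payload, status) {
  if (status != 200L)
    return(list(valid = FALSE, reason = sprintf("status %d", status)))
  doc <- tryCatch(xml2::read_xml(payload), error = function(e) NULL)
  if (is.null(doc))
    return(list(valid = FALSE, reason = "body is not well-formed XML"))
  root <- xml2::xml_name(xml2::xml_root(doc))
  if (!root %in% c("pmc-articleset", "article"))
    return(list(valid = FALSE,
                reason = sprintf("unexpected root element '%s'", root)))
  if (length(xml2::xml_find_all(doc, "//error | //ERROR")) > 0L)
    return(list(valid = FALSE, reason = "error element in response"))
  list(valid = TRUE, reason = "")
}

stateFile <- function(dir) file.path(dir, "articlesets", "state.json")

saveDownloadState <- function(state, dir) {
  dirPath <- file.path(dir, "articlesets")
  if (!dir.exists(dirPath)) dir.create(dirPath, recursive = TRUE)
  obj <- list(
    query = state@handle@query, ids = state@handle@ids,
    resultCount = state@handle@resultCount,
    webenv = state@handle@webenv, queryKey = state@handle@queryKey,
    batchSize = state@batchSize,
    batches = state@batches
  )
  jsonlite::write_json(obj, stateFile(dir), auto_unbox = TRUE, digits = NA)
  invisible(state)
}

#' Reload a persisted download state
#'
#' @param dir the download directory passed to [planBatches()]
#' @return a [DownloadState-class], or NULL when no state file exists
#' @export
loadDownloadState <- function(dir) {
  f <- stateFile(dir)
  if (!file.exists(f)) return(NULL)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  handle <- new("SearchHandle", query = obj$query %||% "",
                ids = as.character(obj$ids %||% character()),
                resultCount = as.integer(obj$resultCount),
                webenv = obj$webenv %||% "", queryKey = obj$queryKey %||% "",
                createdAt = Sys.time())
  batches <- as.data.frame(obj$batches)
  if (nrow(batches) > 0L) batches$index <- as.integer(batches$index)
  new("DownloadState", handle = handle,
      batchSize = as.integer(obj$batchSize), batches = batches)
}

#' Download all pending batches, with retries and resume
#'
#' Attempts every batch that is not already done. A batch is marked done
#' only after its payload passes [validateResponse()] and has been
#' written to disk; the state file is persisted after every batch so an
#' interrupted download can be resumed (batches already done are never
#' re-requested, and their files are left untouched). A batch failing
#' `maxAttempts` times is marked failed and the remaining batches are
#' still attempted.
#'
#' @param state a [DownloadState-class]
#' @param transport a `pmcTransport`
#' @param dir download directory (holds `articlesets/` and `state.json`)
#' @param maxAttempts attempts per batch before marking it failed
#' @param backoff initial retry delay in seconds, doubled per attempt
#' @param sleeper sleep function, injectable for tests
#' @return the updated [DownloadState-class]
#' @export
fetchAll <- function(state, transport, dir = ".", maxAttempts = 4L,
                     backoff = 1, sleeper = Sys.sleep) {
  batches <- state@batches
  handle <- state@handle
  if (nrow(batches) > 0L) {
    for (i in seq_len(nrow(batches))) {
      if (batches$status[i] == "done" && file.exists(batches$path[i]) &&
          file.size(batches$path[i]) > 0L) next
      params <- list(endpoint = "efetch", db = "pmc",
                     retstart = batches$index[i] * state@batchSize,
                     retmax = state@batchSize)
      if (length(handle@ids) > 0L) {
        lo <- batches$index[i] * state@batchSize + 1L
        hi <- min(handle@resultCount, lo + state@batchSize - 1L)
        params$id <- paste(sub("^PMC", "", handle@ids[lo:hi]), collapse = ",")
      } else {
        params$WebEnv <- handle@webenv
        params$query_key <- handle@queryKey
      }
      ok <- FALSE
      for (attempt in seq_len(maxAttempts)) {
        resp <- transport$request(params)
        v <- validateResponse(resp$body, resp$status)
        if (v$valid) {
          dirPath <- dirname(batches$path[i])
          if (!dir.exists(dirPath)) dir.create(dirPath, recursive = TRUE)
          con <- file(batches$path[i], open = "wb")
          writeBin(charToRaw(resp$body), con)
          close(con)
          ok <- TRUE
          break
        }
        if (attempt < maxAttempts) sleeper(backoff * 2^(attempt - 1L))
      }
      batches$status[i] <- if (ok) "done" else "failed"
      state@batches <- batches
      saveDownloadState(state, dir)
    }
  }
  saveDownloadState(state, dir)
  state
}
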