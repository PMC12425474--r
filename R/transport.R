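#' Transports: the pluggable request layer of the download client
#'
#' A *transport* is the contract through which the client talks to the
#' E-utilities: a function taking a named list of request parameters
#' (`endpoint`, `db`, `term`, `id`, `WebEnv`, `query_key`, `retstart`,
#' `retmax`, `api_key`, ...) and returning `list(status = <integer>,
#' body = <character>)`. Everything above the transport (batching,
#' retries, rate limiting, resume) is testable against scripted
#' transports; live HTTP is just one implementation.
#'
#' @param requestFn function(params) -> list(status, body)
#' @return a `pmcTransport` object; every call is recorded in its log
#' @export
newTransport <- function(requestFn) {
  log <- new.env(parent = emptyenv())
  log$calls <- list()
  structure(
    list(
      request = function(params) {
        log$calls[[length(log$calls) + 1L]] <- params
        requestFn(params)
      },
      log = log
    ),
    class = "pmcTransport"
  )
}

#' @describeIn newTransport parameters of every request made so far
#' @param transport a transport
#' @export
transportCalls <- function(transport) transport$log$calls

#' @describeIn newTransport number of requests made so far
#' @export
callCount <- function(transport) length(transport$log$calls)

#' Scripted E-utilities transport for offline runs and tests
#'
#' Emulates E-Search and E-Fetch over a fixed set of PMCIDs. E-Search
#' reports the ID count and history-server keys; E-Fetch returns
#' article-set XML slices by `retstart`/`retmax`. A fail plan makes the
#' first k calls for chosen batches fail, to exercise the retry path.
#'
#' @param ids character vector of PMCIDs in the scripted result set
#' @param articleXml function(pmcid) -> single-article XML string; the
#'   default emits a minimal JATS article
#' @param failPlan named integer vector: `retstart` value -> number of
#'   initial failures for that batch (status 500)
#' @param softFail if TRUE failures are status-200 responses whose body
#'   is a server error message, as the NLM servers sometimes send
#' @param searchCount reported match count (defaults to `length(ids)`)
#' @return a `pmcTransport`
#' @export
mockPmcTransport <- function(ids, articleXml = minimalArticleXml,
                             failPlan = integer(), softFail = FALSE,
                             searchCount = NULL) {
  remaining <- new.env(parent = emptyenv())
  for (nm in names(failPlan)) assign(nm, failPlan[[nm]], envir = remaining)
  count <- searchCount %||% length(ids)
  newTransport(function(params) {
    if (identical(params$endpoint, "esearch")) {
      body <- paste0(
        "<eSearchResult><Count>", count, "</Count>",
        "<WebEnv>WEB_mock</WebEnv><QueryKey>1</QueryKey></eSearchResult>"
      )
      return(list(status = 200L, body = body))
    }
    if (identical(params$endpoint, "efetch")) {
      key <- as.character(params$retstart %||% 0L)
      if (!is.null(remaining[[key]]) && remaining[[key]] > 0L) {
        assign(key, remaining[[key]] - 1L, envir = remaining)
        if (softFail)
          return(list(status = 200L, body = "internal server error occurred"))
        return(list(status = 500L, body = "server error"))
      }
      start <- as.integer(params$retstart %||% 0L) + 1L
      stop_ <- min(length(ids), start + as.integer(params$retmax) - 1L)
      batchIds <- if (start <= stop_) ids[start:stop_] else character()
      body <- paste0(
        "<pmc-articleset>",
        paste(vapply(batchIds, articleXml, character(1)), collapse = ""),
        "</pmc-articleset>"
      )
      return(list(status = 200L, body = body))
    }
    list(status = 400L, body = "unknown endpoint")
  })
}

# Minimal well-formed JATS article used by the scripted transport.
minimalArticleXml <- function(pmcid) {
  paste0(
    "<article><front><article-meta>",
    "<article-id pub-id-type=\"pmcid\">", pmcid, "</article-id>",
    "<title-group><article-title>Article ", pmcid,
    "</article-title></title-group>",
    "</article-meta></front><body><sec><p>Body of ", pmcid,
    ".</p></sec></body></article>"
  )
}

#' Live HTTP transport for the NCBI E-utilities
#'
#' Thin implementation of the transport contract over base R
#' connections. Offline workflows (and all tests) use scripted
#' transports instead.
#'
#' @param baseUrl E-utilities base URL
#' @export
httpTransport <- function(baseUrl = "https://eutils.ncbi.nlm.nih.gov/entrez/eutils") {
  newTransport(function(params) {
    endpoint <- params$endpoint
    params$endpoint <- NULL
    qs <- paste(
      vapply(names(params), function(nm)
        paste0(nm, "=", utils::URLencode(as.character(params[[nm]]),
                                         reserved = TRUE)),
        character(1)),
      collapse = "&"
    )
    url <- sprintf("%s/%s.fcgi?%s", baseUrl, endpoint, qs)
    tryCatch({
      body <- paste(readLines(url, warn = FALSE, encoding = "UTF-8"),
                    collapse = "\n")
      list(status = 200L, body = body)
    }, error = function(e) list(status = 599L, body = conditionMessage(e)))
  })
}

#' Fake clock for deterministic rate-limit tests
#'
#' @return list with `now()` (seconds) and `sleep(s)`; sleeping advances
#'   the fake time instantly
#' @export
fakeClock <- function() {
  env <- new.env(parent = emptyenv())
  env$t <- 0
  list(
    now = function() env$t,
    sleep = function(s) env$t <- env$t + s
  )
}

realClock <- function() {
  list(
    now = function() as.numeric(Sys.time()),
    sleep = function(s) Sys.sleep(s)
  )
}

#' Rate-limit a transport and attach the API key
#'
#' Wraps a transport so that no more than `ratePerSec` requests start
#' within any sliding one-second window, and so that the API key, when
#' provided, is attached to every request. Defaults follow the
#' E-utilities documentation: 3 requests/s without a key, 10 with one.
#'
#' @param transport the transport to wrap
#' @param apiKey optional API key added as the `api_key` parameter
#' @param ratePerSec maximum requests per second (default 3 without a
#'   key, 10 with one)
#' @param clock time source, injectable for tests (see [fakeClock()])
#' @return a rate-limited `pmcTransport` sharing the inner call log
#' @export
throttleTransport <- function(transport, apiKey = NULL,
                              ratePerSec = if (is.null(apiKey)) 3 else 10,
                              clock = realClock()) {
  stopifnot(ratePerSec > 0)
  stamps <- new.env(parent = emptyenv())
  stamps$t <- numeric()
  structure(
    list(
      request = function(params) {
        now <- clock$now()
        recent <- stamps$t[stamps$t > now - 1]
        if (length(recent) >= ratePerSec) {
          wait <- (min(recent) + 1) - now
          clock$sleep(wait)
          now <- clock$now()
          recent <- stamps$t[stamps$t > now - 1]
        }
        stamps$t <- c(recent, now)
        if (!is.null(apiKey)) params$api_key <- apiKey
        transport$request(params)
      },
      log = transport$log
    ),
    class = "pmcTransport"
  )
}
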