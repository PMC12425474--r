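# Step-cached pipeline: each step writes to its own directory under
# <outRoot>/<queryFingerprint>/ and records a sentinel (info.json) with
# the fingerprint of its parameters and a fresh run id. A step is
# skipped when its sentinel matches; downstream fingerprints include the
# upstream run ids, so re-running an upstream step (or deleting its
# sentinel) invalidates exactly the steps below it.

stepSentinelPath <- function(stepDir) file.path(stepDir, "info.json")

readSentinel <- function(stepDir) {
  f <- stepSentinelPath(stepDir)
  if (!file.exists(f)) return(NULL)
  tryCatch(jsonlite::read_json(f), error = function(e) NULL)
}

markStepComplete <- function(stepDir, name, fingerprint) {
  runId <- paste0(format(Sys.time(), "%Y%m%d%H%M%OS6"), "-",
                  basename(tempfile("")))
  jsonlite::write_json(
    list(name = name, status = "complete", fingerprint = fingerprint,
         run_id = runId),
    stepSentinelPath(stepDir), auto_unbox = TRUE
  )
  runId
}

runStep <- function(root, name, fingerprint, fn) {
  stepDir <- file.path(root, name)
  info <- readSentinel(stepDir)
  if (!is.null(info) && identical(info$status, "complete") &&
      identical(info$fingerprint, fingerprint)) {
    return(list(name = name, dir = stepDir, status = "complete",
                skipped = TRUE, runId = info$run_id))
  }
  if (!dir.exists(stepDir)) dir.create(stepDir, recursive = TRUE)
  res <- tryCatch({
    fn(stepDir)
    list(ok = TRUE)
  }, error = function(e) list(ok = FALSE, message = conditionMessage(e)))
  if (!res$ok) {
    jsonlite::write_json(
      list(name = name, status = "failed", fingerprint = fingerprint,
           message = res$message),
      stepSentinelPath(stepDir), auto_unbox = TRUE
    )
    return(list(name = name, dir = stepDir, status = "failed",
                skipped = FALSE, message = res$message))
  }
  runId <- markStepComplete(stepDir, name, fingerprint)
  list(name = name, dir = stepDir, status = "complete", skipped = FALSE,
       runId = runId)
}

#' Fingerprint of a query or ID list
#'
#' Short hash of the normalized query string (lowercased, collapsed
#' whitespace) or of the sorted ID list; names the per-query output
#' directory.
#'
#' @param queryOrIds query string or character vector of PMCIDs
#' @return 12-character hash
#' @export
queryFingerprint <- function(queryOrIds) {
  norm <- if (length(queryOrIds) > 1L ||
              grepl("^(PMC)?[0-9]+$", queryOrIds[1]))
    paste(sort(unique(queryOrIds)), collapse = ",")
  else tolower(gsub("\\s+", " ", trimws(queryOrIds)))
  substr(paramsFingerprint(list(q = norm)), 1, 12)
}

# ---- plugin registry ----

pluginRegistry <- new.env(parent = emptyenv())

#' Register a pipeline plugin
#'
#' Plugins contribute optional pipeline steps and command-line options.
#' They are enumerated at startup by [discoverPlugins()]; a plugin whose
#' load hook throws is skipped with a warning and never crashes the
#' host.
#'
#' @param name step name (also the output directory name)
#' @param option the command-line option the plugin contributes (e.g.
#'   "--participants")
#' @param run function(stepDir, corpus, context) executing the step
#' @param loadHook optional function() run at registration; an error
#'   here skips the plugin
#' @export
registerPlugin <- function(name, option, run, loadHook = NULL) {
  if (!is.null(loadHook)) {
    ok <- tryCatch({
      loadHook()
      TRUE
    }, error = function(e) {
      warning(sprintf("plugin '%s' failed to load and was skipped: %s",
                      name, conditionMessage(e)))
      FALSE
    })
    if (!ok) return(invisible(FALSE))
  }
  assign(name, list(name = name, option = option, run = run),
         envir = pluginRegistry)
  invisible(TRUE)
}

#' @describeIn registerPlugin remove a plugin from the registry
#' @export
unregisterPlugin <- function(name) {
  if (exists(name, envir = pluginRegistry))
    rm(list = name, envir = pluginRegistry)
  invisible(NULL)
}

#' List registered pipeline plugins
#'
#' @return list of plugin descriptors (name, option, run)
#' @export
discoverPlugins <- function() {
  nms <- sort(ls(pluginRegistry))
  lapply(nms, function(nm) get(nm, envir = pluginRegistry))
}

# ---- parallel map ----

#' Map a worker over items, optionally in parallel
#'
#' Results are identical to sequential execution regardless of
#' `nWorkers` (order is restored by item index); a failing item is
#' recorded and does not abort the batch.
#'
#' @param items list or vector of work items
#' @param workerFn function(item) -> value
#' @param nWorkers number of worker processes
#' @return list: `results` (NULL for failed items), `failures`
#'   (data.frame index, message)
#' @export
parallelMap <- function(items, workerFn, nWorkers = 1L) {
  wrap <- function(item) {
    tryCatch(list(ok = TRUE, value = workerFn(item)),
             error = function(e) list(ok = FALSE,
                                      message = conditionMessage(e)))
  }
  res <- if (nWorkers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(items, wrap, mc.cores = nWorkers)
  } else {
    lapply(items, wrap)
  }
  ok <- vapply(res, function(r) isTRUE(r$ok), logical(1))
  failures <- data.frame(
    index = which(!ok),
    message = vapply(res[!ok], function(r) r$message %||% "unknown",
                     character(1)),
    stringsAsFactors = FALSE
  )
  list(results = lapply(res, function(r) if (isTRUE(r$ok)) r$value),
       failures = failures)
}

# ---- the pipeline ----

#' Run the literature-mining pipeline
#'
#' Executes download, extraction, and coordinate extraction, plus any
#' requested optional steps (TF-IDF, meta-analysis fits, annotation and
#' coordinate-dataset exports, and registered plugins such as
#' participant demographics). Each step writes to
#' `<outRoot>/<queryFingerprint>/<step>/`; completed steps are skipped
#' on re-runs with identical parameters.
#'
#' @param queryOrIds PMC query string or character vector of PMCIDs
#'   (required unless `articlesetsDir` is given)
#' @param outRoot output root directory
#' @param transport a `pmcTransport` for the download step
#' @param articlesetsDir pre-existing article-set directory (e.g. from
#'   [generateCorpus()]); replaces the download step
#' @param tfidf,fitNeurosynth,fitNeuroquery,labelbuddy,nimare optional
#'   steps (the fits imply `tfidf`)
#' @param plugins character vector of plugin step names to run (see
#'   [discoverPlugins()])
#' @param nWorkers workers for per-article processing
#' @param apiKey E-utilities API key, attached to every request
#' @param ratePerSec request rate limit (default 3 without a key, 10
#'   with one)
#' @param radius sphere radius (mm) for binary maps
#' @param sigma Gaussian sd (mm) for density maps
#' @param voxelSize grid voxel size (mm)
#' @param qThreshold FDR level for the chi-square maps
#' @param maxTerms cap on the number of terms fitted by the
#'   meta-analysis steps (most frequent first)
#' @param batchSize download batch size
#' @param maxAttempts download retries per batch
#' @param sleeper sleep function for retry backoff (injectable)
#' @return (invisibly) list: `exitStatus` (0 iff no requested step
#'   failed), `root`, `steps` (per-step status)
#' @export
runPipeline <- function(queryOrIds = NULL, outRoot, transport = NULL,
                        articlesetsDir = NULL, tfidf = FALSE,
                        fitNeurosynth = FALSE, fitNeuroquery = FALSE,
                        labelbuddy = FALSE, nimare = FALSE,
                        plugins = character(), nWorkers = 1L,
                        apiKey = NULL,
                        ratePerSec = if (is.null(apiKey)) 3 else 10,
                        radius = 10, sigma = 3.82, voxelSize = 4,
                        qThreshold = 0.01, maxTerms = 20L,
                        batchSize = 500L, maxAttempts = 4L,
                        sleeper = Sys.sleep) {
  if (is.null(queryOrIds) && is.null(articlesetsDir))
    stop("either a query/ID list or an articlesets directory is required")
  if (tfidf || fitNeurosynth || fitNeuroquery) tfidf <- TRUE
  fp0 <- if (!is.null(articlesetsDir))
    substr(paramsFingerprint(list(src = normalizePath(articlesetsDir))), 1, 12)
  else queryFingerprint(queryOrIds)
  root <- file.path(outRoot, fp0)
  if (!dir.exists(root)) dir.create(root, recursive = TRUE)
  steps <- list()
  grid <- defaultGrid(voxelSize = voxelSize)

  # download (or import of pre-existing article sets)
  if (is.null(articlesetsDir)) {
    if (is.null(transport))
      transport <- throttleTransport(httpTransport(), apiKey = apiKey,
                                     ratePerSec = ratePerSec)
    dlFp <- paramsFingerprint(list(step = "download", q = fp0,
                                   batchSize = batchSize))
    dl <- runStep(root, "download", dlFp, function(stepDir) {
      prev <- loadDownloadState(stepDir)
      state <- if (!is.null(prev)) prev else {
        handle <- searchPmc(queryOrIds, transport, sleeper = sleeper)
        planBatches(handle, batchSize = batchSize, dir = stepDir)
      }
      state <- fetchAll(state, transport, dir = stepDir,
                        maxAttempts = maxAttempts, sleeper = sleeper)
      if (any(state@batches$status == "failed"))
        warning(sprintf("%d batch(es) failed",
                        sum(state@batches$status == "failed")))
    })
    steps$download <- dl
    srcDir <- file.path(dl$dir, "articlesets")
    upstreamId <- dl$runId %||% ""
  } else {
    srcDir <- articlesetsDir
    upstreamId <- fp0
  }

  # conservative downstream invalidation: every step's fingerprint
  # includes the run ids of all steps executed before it
  chain <- upstreamId

  # extract
  exFp <- paramsFingerprint(list(step = "extract", up = chain))
  corpusCache <- new.env(parent = emptyenv())
  loadCorpus <- function() {
    if (is.null(corpusCache$corpus))
      corpusCache$corpus <- readCorpus(srcDir)
    corpusCache$corpus
  }
  ex <- runStep(root, "extract", exFp, function(stepDir) {
    corpus <- loadCorpus()
    flat <- corpusTables(corpus)
    writeCsv(flat$metadata, file.path(stepDir, "metadata.csv"))
    writeCsv(flat$text, file.path(stepDir, "text.csv"))
    tdir <- file.path(stepDir, "tables")
    res <- parallelMap(corpus, function(a) {
      adir <- file.path(tdir, a$metadata$pmcid)
      if (!dir.exists(adir)) dir.create(adir, recursive = TRUE)
      for (tb in a$tables)
        writeTableCsv(tb, file.path(adir, paste0(tb@tableId, ".csv")))
      length(a$tables)
    }, nWorkers = nWorkers)
    if (nrow(res$failures) > 0L)
      warning(sprintf("%d article(s) failed table export",
                      nrow(res$failures)))
  })
  steps$extract <- ex
  if (ex$status == "failed") {
    return(invisible(list(exitStatus = 1L, root = root, steps = steps)))
  }
  chain <- paste0(chain, "/", ex$runId)

  # coordinates
  coFp <- paramsFingerprint(list(step = "coordinates", up = chain))
  co <- runStep(root, "coordinates", coFp, function(stepDir) {
    writeCsv(corpusCoordinates(loadCorpus()),
             file.path(stepDir, "coordinates.csv"))
  })
  steps$coordinates <- co
  chain <- paste0(chain, "/", co$runId %||% "")

  readCoords <- function() read.csv(
    file.path(root, "coordinates", "coordinates.csv"),
    stringsAsFactors = FALSE
  )

  # optional: TF-IDF
  if (tfidf) {
    tfFp <- paramsFingerprint(list(step = "tfidf", up = chain))
    tf <- runStep(root, "tfidf", tfFp, function(stepDir) {
      writeDocTermMatrix(corpusTfidf(loadCorpus()), stepDir)
    })
    steps$tfidf <- tf
    chain <- paste0(chain, "/", tf$runId %||% "")
  }

  metaTerms <- function(dtm) {
    # terms must vary across studies to be testable: present in at
    # least 2 and absent from at least 2; most balanced first
    df <- Matrix::colSums(dtm@rawCounts > 0)
    n <- nrow(dtm@rawCounts)
    ok <- which(df >= 2 & df <= n - 2)
    ok <- ok[order(df[ok] * (n - df[ok]), decreasing = TRUE)]
    dtm@terms[ok[seq_len(min(maxTerms, length(ok)))]]
  }

  # optional: chi-square meta-analysis maps
  if (fitNeurosynth) {
    nsFp <- paramsFingerprint(list(step = "fit_neurosynth", up = chain,
                                   radius = radius, voxelSize = voxelSize,
                                   q = qThreshold, maxTerms = maxTerms))
    ns <- runStep(root, "fit_neurosynth", nsFp, function(stepDir) {
      corpus <- loadCorpus()
      dtm <- corpusTfidf(corpus)
      maps <- buildStudyMaps(readCoords(), grid, radius = radius,
                             sigma = sigma)
      terms <- metaTerms(dtm)
      manifest <- list()
      for (term in terms) {
        present <- as.numeric(
          dtm@rawCounts[match(maps@pmcids, dtm@pmcids),
                        match(term, dtm@terms)]) > 0
        if (sum(present) < 2L || sum(!present) < 2L) next
        res <- chiSquareMap(maps@binary, present, term = term,
                            grid = grid, qThreshold = qThreshold)
        writeVolume(res@z, grid, file.path(stepDir, paste0(term, "_z.nii.gz")))
        writeVolume(res@p, grid, file.path(stepDir, paste0(term, "_p.nii.gz")))
        manifest[[term]] <- sum(res@significant)
      }
      writeCsv(data.frame(term = names(manifest),
                          n_significant = unlist(manifest)),
               file.path(stepDir, "terms.csv"))
      writeLines(c("<html><body><h1>Meta-analytic maps</h1><ul>",
                   sprintf("<li>%s</li>", names(manifest)),
                   "</ul></body></html>"),
                 file.path(stepDir, "index.html"))
    })
    steps$fit_neurosynth <- ns
    chain <- paste0(chain, "/", ns$runId %||% "")
  }

  # optional: ridge model maps
  if (fitNeuroquery) {
    nqFp <- paramsFingerprint(list(step = "fit_neuroquery", up = chain,
                                   sigma = sigma, voxelSize = voxelSize,
                                   maxTerms = maxTerms))
    nq <- runStep(root, "fit_neuroquery", nqFp, function(stepDir) {
      corpus <- loadCorpus()
      dtm <- corpusTfidf(corpus)
      maps <- buildStudyMaps(readCoords(), grid, radius = radius,
                             sigma = sigma)
      rows <- match(maps@pmcids, dtm@pmcids)
      sub <- tfidfMatrix(dtm@rawCounts[rows, , drop = FALSE],
                         dtm@pmcids[rows], dtm@terms)
      model <- fitTermModel(sub, maps@density, ridgePenalty = 0.1,
                            grid = grid)
      for (term in metaTerms(sub))
        writeVolume(model$coefficients[term, ], grid,
                    file.path(stepDir, paste0(term, "_coef.nii.gz")))
      writeCsv(data.frame(term = metaTerms(sub)),
               file.path(stepDir, "terms.csv"))
    })
    steps$fit_neuroquery <- nq
    chain <- paste0(chain, "/", nq$runId %||% "")
  }

  # optional: annotation export
  if (labelbuddy) {
    lbFp <- paramsFingerprint(list(step = "labelbuddy", up = chain))
    steps$labelbuddy <- runStep(root, "labelbuddy", lbFp, function(stepDir) {
      exportLabelbuddy(loadCorpus(), file.path(stepDir, "documents.jsonl"))
    })
  }

  # optional: coordinate-dataset export
  if (nimare) {
    nmFp <- paramsFingerprint(list(step = "nimare", up = chain))
    steps$nimare <- runStep(root, "nimare", nmFp, function(stepDir) {
      exportNimare(readCoords(), corpusTables(loadCorpus())$metadata,
                   file.path(stepDir, "nimare_dataset.json"))
    })
  }

  # plugins
  for (pluginName in plugins) {
    plugin <- if (exists(pluginName, envir = pluginRegistry))
      get(pluginName, envir = pluginRegistry) else NULL
    if (is.null(plugin)) {
      warning(sprintf("no plugin named '%s' is registered", pluginName))
      next
    }
    plFp <- paramsFingerprint(list(step = pluginName, up = chain))
    steps[[pluginName]] <- runStep(root, pluginName, plFp,
                                   function(stepDir) {
      plugin$run(stepDir, loadCorpus(), list(root = root, grid = grid))
    })
  }

  failed <- any(vapply(steps, function(s) identical(s$status, "failed"),
                       logical(1)))
  invisible(list(exitStatus = if (failed) 1L else 0L, root = root,
                 steps = steps))
}
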