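# Synthetic JATS corpus with fully known ground truth: every pipeline
# stage (splitting, metadata, text, tables in both dialects, coordinate
# and demographics extraction, featurization, meta-analysis) can be
# exercised offline against the generator's ledger.

numberToWord <- function(n) {
  all <- c(onesWords, teenWords, tensWords)
  hit <- names(all)[all == n]
  if (length(hit)) return(hit[1])
  tens <- (n %/% 10) * 10
  unit <- n %% 10
  paste0(names(tensWords)[tensWords == tens], "-",
         names(onesWords)[onesWords == unit])
}

capitalize <- function(s) paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))

#' Demographics sentence templates with their expected parse
#'
#' Each template instantiates one participant-description sentence
#' together with the mentions the grammar must produce and the group
#' structure the aggregation must infer. Templates cover single-group
#' studies, patients + controls + total, word-number counts, mean age
#' with sd, age ranges, and sex counts.
#'
#' @param id one of "single_healthy", "patients_controls_total",
#'   "word_count", "age_mean_sd", "age_range", "sex_counts"
#' @param params named list of template parameters (n, n1, n2, ageMean,
#'   ageSd, ageMin, ageMax, nFemale, nMale as required by the template)
#' @return list: sentence, mentions (data.frame of expected count /
#'   status / age / sex fields), total, singleGroup
#' @export
sentenceTemplates <- function(id, params) {
  mk <- function(count, status, age_mean = NA_real_, age_sd = NA_real_,
                 age_min = NA_real_, age_max = NA_real_,
                 n_female = NA_real_, n_male = NA_real_) {
    data.frame(count = as.numeric(count), status = status,
               age_mean = as.numeric(age_mean), age_sd = as.numeric(age_sd),
               age_min = as.numeric(age_min), age_max = as.numeric(age_max),
               n_female = as.numeric(n_female), n_male = as.numeric(n_male),
               stringsAsFactors = FALSE)
  }
  switch(
    id,
    single_healthy = list(
      sentence = sprintf("We recruited %d healthy participants.", params$n),
      mentions = mk(params$n, "healthy"),
      total = params$n, singleGroup = TRUE
    ),
    patients_controls_total = list(
      sentence = sprintf("We studied %d subjects: %d patients and %d controls.",
                         params$n1 + params$n2, params$n1, params$n2),
      mentions = rbind(mk(params$n1 + params$n2, "unknown"),
                       mk(params$n1, "patients"),
                       mk(params$n2, "healthy")),
      total = params$n1 + params$n2, singleGroup = FALSE
    ),
    word_count = list(
      sentence = sprintf("%s volunteers completed the task.",
                         capitalize(numberToWord(params$n))),
      mentions = mk(params$n, "unknown"),
      total = params$n, singleGroup = TRUE
    ),
    age_mean_sd = list(
      sentence = sprintf(
        "We recruited %d healthy participants (mean age %.1f ± %.1f years).",
        params$n, params$ageMean, params$ageSd),
      mentions = mk(params$n, "healthy", age_mean = params$ageMean,
                    age_sd = params$ageSd),
      total = params$n, singleGroup = TRUE
    ),
    age_range = list(
      sentence = sprintf("%d patients aged %d–%d years took part.",
                         params$n, params$ageMin, params$ageMax),
      mentions = mk(params$n, "patients", age_min = params$ageMin,
                    age_max = params$ageMax),
      total = params$n, singleGroup = TRUE
    ),
    sex_counts = list(
      sentence = sprintf("We recruited %d participants (%d female, %d male).",
                         params$n, params$nFemale, params$nMale),
      mentions = mk(params$n, "unknown", n_female = params$nFemale,
                    n_male = params$nMale),
      total = params$n, singleGroup = TRUE
    ),
    stop(sprintf("unknown template '%s'", id))
  )
}

allTemplateIds <- c("single_healthy", "patients_controls_total",
                    "word_count", "age_mean_sd", "age_range", "sex_counts")

#' Sample template parameters for one article
#'
#' Sample sizes are drawn log-normally (median `medianN`, log-sd 0.4),
#' mirroring the right skew of real cohorts, and clamped to [5, 200].
#'
#' @param id template id
#' @param medianN median sample size of the log-normal draw
#' @return named list of parameters for [sentenceTemplates()]
#' @export
sampleTemplateParams <- function(id, medianN = 25) {
  drawN <- function() max(5L, min(200L, round(rlnorm(1, log(medianN), 0.4))))
  switch(
    id,
    single_healthy = list(n = drawN()),
    patients_controls_total = {
      n1 <- drawN()
      n2 <- drawN()
      list(n1 = n1, n2 = n2)
    },
    word_count = list(n = sample(3:20, 1)),
    age_mean_sd = list(n = drawN(),
                       ageMean = round(runif(1, 19, 70), 1),
                       ageSd = round(runif(1, 1, 12), 1)),
    age_range = {
      lo <- sample(18:40, 1)
      list(n = drawN(), ageMin = lo, ageMax = lo + sample(5:30, 1))
    },
    sex_counts = {
      n <- drawN()
      f <- sample(0:n, 1)
      list(n = n, nFemale = f, nMale = n - f)
    },
    stop(sprintf("unknown template '%s'", id))
  )
}

#' Specification of a synthetic corpus
#'
#' @param nArticles number of articles to generate
#' @param seed RNG seed; generation is fully deterministic given it
#' @param tableDialectMix probability that an article's coordinate
#'   table uses the XHTML dialect (else OASIS)
#' @param termEffects list of term-location couplings, each
#'   `list(term =, focus = c(x, y, z) mm, pPeak =, baseline =)`: an
#'   article mentioning the term places each peak near the focus with
#'   probability `pPeak`, a non-mentioning article with probability
#'   `baseline`, otherwise uniformly in-grid
#' @param pTermMention probability that an article mentions each term
#' @param demographicsTemplates template ids to draw from
#' @param peakNoiseSd mm noise around a focus peak
#' @param medianN median of the log-normal sample-size distribution
#' @param pMni probability that an article reports MNI coordinates
#' @return list of class `CorpusSpec`
#' @export
corpusSpec <- function(nArticles, seed = 0L, tableDialectMix = 0.5,
                       termEffects = list(
                         list(term = "pain", focus = c(2, -18, 44),
                              pPeak = 0.9, baseline = 0.1)
                       ),
                       pTermMention = 0.5,
                       demographicsTemplates = allTemplateIds,
                       peakNoiseSd = 5, medianN = 25, pMni = 0.8) {
  stopifnot(nArticles >= 1,
            tableDialectMix >= 0, tableDialectMix <= 1,
            pTermMention >= 0, pTermMention <= 1, peakNoiseSd >= 0)
  for (eff in termEffects) {
    stopifnot(length(eff$focus) == 3L,
              eff$pPeak >= 0, eff$pPeak <= 1,
              eff$baseline >= 0, eff$baseline <= 1)
    g <- defaultGrid()
    ijk <- worldToVoxel(g, matrix(eff$focus, 1))
    if (!all(inGrid(g, ijk)))
      stop(sprintf("focus of term '%s' is outside the default grid",
                   eff$term))
  }
  stopifnot(all(demographicsTemplates %in% allTemplateIds))
  structure(
    list(nArticles = as.integer(nArticles), seed = as.integer(seed),
         tableDialectMix = tableDialectMix, termEffects = termEffects,
         pTermMention = pTermMention,
         demographicsTemplates = demographicsTemplates,
         peakNoiseSd = peakNoiseSd, medianN = medianN, pMni = pMni),
    class = "CorpusSpec"
  )
}

fmtCoord <- function(v) sprintf("%d", as.integer(v))

xhtmlCoordTable <- function(peaks) {
  rows <- vapply(seq_len(nrow(peaks)), function(i) sprintf(
    "<tr><td>Region %d</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td></tr>",
    i, fmtCoord(peaks$x[i]), fmtCoord(peaks$y[i]), fmtCoord(peaks$z[i]),
    peaks$t[i]), character(1))
  paste0(
    "<table-wrap id=\"tbl1\"><label>Table 1</label>",
    "<caption><p>Peak activation coordinates.</p></caption>",
    "<table><thead><tr><th>Region</th><th>x</th><th>y</th><th>z</th>",
    "<th>t</th></tr></thead><tbody>",
    paste(rows, collapse = ""),
    "</tbody></table></table-wrap>"
  )
}

oasisCoordTable <- function(peaks) {
  rows <- vapply(seq_len(nrow(peaks)), function(i) sprintf(
    paste0("<row><entry>Region %d</entry><entry>%s</entry>",
           "<entry>%s</entry><entry>%s</entry><entry>%s</entry></row>"),
    i, fmtCoord(peaks$x[i]), fmtCoord(peaks$y[i]), fmtCoord(peaks$z[i]),
    peaks$t[i]), character(1))
  paste0(
    "<table-wrap id=\"tbl1\"><label>Table 1</label>",
    "<caption><p>Peak activation coordinates.</p></caption>",
    "<table><tgroup cols=\"5\">",
    paste(sprintf("<colspec colname=\"c%d\"/>", 1:5), collapse = ""),
    "<thead><row><entry>Region</entry><entry>x</entry><entry>y</entry>",
    "<entry>z</entry><entry>t</entry></row></thead><tbody>",
    paste(rows, collapse = ""),
    "</tbody></tgroup></table></table-wrap>"
  )
}

syntheticArticleXml <- function(pmcid, year, demoSentence, distractor,
                                termSentence, spaceSentence, tableXml) {
  paste0(
    "<article><front><article-meta>",
    "<article-id pub-id-type=\"pmcid\">", pmcid, "</article-id>",
    "<title-group><article-title>A synthetic neuroimaging study (",
    pmcid, ")</article-title></title-group>",
    "<contrib-group><contrib contrib-type=\"author\"><name>",
    "<surname>Doe</surname><given-names>J.</given-names>",
    "</name></contrib></contrib-group>",
    "<pub-date pub-type=\"ppub\"><year>", year, "</year></pub-date>",
    "<abstract><p>", termSentence, " We report peak coordinates.</p>",
    "</abstract>",
    "</article-meta></front><body>",
    "<sec><title>Methods</title><p>", demoSentence, " ", distractor,
    "</p></sec>",
    "<sec><title>Results</title><p>", termSentence, " ", spaceSentence,
    "</p>", tableXml, "</sec>",
    "</body></article>"
  )
}

#' Generate a synthetic article set with a ground-truth ledger
#'
#' Writes article-set XML batches in the same layout the download
#' client produces (`dir/articlesets/batch_<index>.xml`) so the
#' pipeline runs unmodified from the extraction step, plus the ledger
#' as CSV and JSON under `dir/ground_truth/`. Generation is
#' deterministic given the spec's seed.
#'
#' @param spec a [corpusSpec()]
#' @param dir output directory
#' @return (invisibly) the ledger: list with `articles` (pmcid, year,
#'   true_sample_size, single_group, template, space, dialect, terms),
#'   `coords` (pmcid, x, y, z), and `expectedMentions` (per-article
#'   expected parses)
#' @export
generateCorpus <- function(spec, dir) {
  stopifnot(inherits(spec, "CorpusSpec"))
  withSeed(spec$seed, {
    grid <- defaultGrid()
    lo <- grid@origin + 2
    hi <- grid@origin + (grid@shape - 1L) * grid@voxelSize - 2
    articleRows <- vector("list", spec$nArticles)
    coordRows <- vector("list", spec$nArticles)
    mentionRows <- vector("list", spec$nArticles)
    xmls <- character(spec$nArticles)
    for (i in seq_len(spec$nArticles)) {
      pmcid <- sprintf("PMC%07d", 1000000L + i)
      year <- sample(2005:2024, 1)
      template <- sample(spec$demographicsTemplates, 1)
      params <- sampleTemplateParams(template, spec$medianN)
      demo <- sentenceTemplates(template, params)
      distractor <- sprintf("Participants viewed %d images during scanning.",
                            sample(c(60L, 120L, 240L), 1))
      mentioned <- vapply(spec$termEffects, function(eff)
        runif(1) < spec$pTermMention, logical(1))
      terms <- vapply(spec$termEffects, `[[`, character(1), "term")[mentioned]
      termSentence <- if (length(terms))
        sprintf("This study investigates %s using fMRI.",
                paste(terms, collapse = " and "))
      else "This study investigates brain function using fMRI."
      space <- if (runif(1) < spec$pMni) "MNI" else "TAL"
      spaceSentence <- if (space == "MNI")
        "Coordinates are reported in MNI space."
      else "Coordinates are reported in Talairach space."
      nPeaks <- sample(3:8, 1)
      peaks <- matrix(NA_real_, 0L, 3L)
      addPeak <- function(p) {
        p <- pmax(pmin(p, hi), lo)
        if (all(p == 0)) p[1] <- 4
        if (!any(apply(peaks, 1, function(q) all(q == p))))
          peaks <<- rbind(peaks, p)
      }
      # study-level coupling: a study places one peak near each term's
      # focus with probability pPeak (term mentioned) or baseline (not);
      # all remaining peaks are uniform in-grid
      for (j in seq_along(spec$termEffects)) {
        eff <- spec$termEffects[[j]]
        pFocus <- if (mentioned[j]) eff$pPeak else eff$baseline
        if (nrow(peaks) < nPeaks && runif(1) < pFocus)
          addPeak(round(eff$focus + rnorm(3, 0, spec$peakNoiseSd)))
      }
      while (nrow(peaks) < nPeaks) addPeak(round(runif(3, lo, hi)))
      peaksDf <- data.frame(x = peaks[, 1], y = peaks[, 2], z = peaks[, 3],
                            t = sprintf("%.1f", runif(nPeaks, 2, 6)))
      dialect <- if (runif(1) < spec$tableDialectMix) "xhtml" else "oasis"
      tableXml <- if (dialect == "xhtml") xhtmlCoordTable(peaksDf)
      else oasisCoordTable(peaksDf)
      xmls[i] <- syntheticArticleXml(pmcid, year, demo$sentence, distractor,
                                     termSentence, spaceSentence, tableXml)
      articleRows[[i]] <- data.frame(
        pmcid = pmcid, year = year, true_sample_size = demo$total,
        single_group = demo$singleGroup, template = template,
        space = space, dialect = dialect,
        terms = paste(terms, collapse = ","), stringsAsFactors = FALSE
      )
      coordRows[[i]] <- data.frame(pmcid = pmcid, x = peaksDf$x,
                                   y = peaksDf$y, z = peaksDf$z,
                                   stringsAsFactors = FALSE)
      em <- demo$mentions
      em$pmcid <- pmcid
      mentionRows[[i]] <- em
    }
    ledger <- list(
      articles = do.call(rbind, articleRows),
      coords = do.call(rbind, coordRows),
      expectedMentions = do.call(rbind, mentionRows)
    )
    asDir <- file.path(dir, "articlesets")
    if (!dir.exists(asDir)) dir.create(asDir, recursive = TRUE)
    batchStarts <- seq(1L, spec$nArticles, by = 500L)
    for (b in seq_along(batchStarts)) {
      idx <- batchStarts[b]:min(spec$nArticles, batchStarts[b] + 499L)
      con <- file(file.path(asDir, sprintf("batch_%05d.xml", b - 1L)),
                  open = "wb")
      writeBin(charToRaw(paste0("<pmc-articleset>",
                                paste(xmls[idx], collapse = ""),
                                "</pmc-articleset>")), con)
      close(con)
    }
    gtDir <- file.path(dir, "ground_truth")
    if (!dir.exists(gtDir)) dir.create(gtDir, recursive = TRUE)
    writeCsv(ledger$articles, file.path(gtDir, "articles.csv"))
    writeCsv(ledger$coords, file.path(gtDir, "coordinates.csv"))
    jsonlite::write_json(ledger$articles, file.path(gtDir, "ledger.json"),
                         digits = NA)
    invisible(ledger)
  })
}
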