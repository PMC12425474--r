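#' Tokenize text for featurization
#'
#' Lowercases, strips punctuation, and splits on whitespace.
#'
#' @param text a character scalar
#' @return character vector of tokens
#' @export
tokenize <- function(text) {
  t <- tolower(text)
  t <- gsub("[^a-z0-9 ]", " ", t)
  toks <- strsplit(trimws(gsub(" +", " ", t)), " ", fixed = TRUE)[[1]]
  toks[nzchar(toks)]
}

articleTokenStream <- function(articleText) {
  tokenize(paste(articleText$title,
                 paste(articleText$keywords, collapse = " "),
                 articleText$abstract, articleText$body, sep = " "))
}

defaultStopwords <- function() {
  f <- system.file("extdata", "stopwords.txt", package = "pmcmeta")
  if (nzchar(f)) readLines(f, encoding = "UTF-8") else character()
}

#' Build a corpus vocabulary
#'
#' In the absence of a user-supplied vocabulary, uses the corpus's own
#' unigrams seen in at least `minDf` articles, minus a small stop-word
#' list. A vocabulary file (one lowercase term per line; phrases as
#' space-separated tokens) overrides this.
#'
#' @param corpus output of [readCorpus()]
#' @param minDf minimum document frequency (default 2)
#' @param stopwords terms to exclude
#' @param vocabularyFile optional path to a term-per-line file
#' @return character vector of unique terms
#' @export
buildVocabulary <- function(corpus, minDf = 2L,
                            stopwords = defaultStopwords(),
                            vocabularyFile = NULL) {
  if (!is.null(vocabularyFile)) {
    terms <- readLines(vocabularyFile, encoding = "UTF-8")
    terms <- trimws(tolower(terms))
    return(unique(terms[nzchar(terms)]))
  }
  dfCount <- new.env(parent = emptyenv())
  for (a in corpus) {
    toks <- unique(articleTokenStream(a$text))
    for (tk in toks)
      assign(tk, (dfCount[[tk]] %||% 0L) + 1L, envir = dfCount)
  }
  terms <- ls(dfCount)
  dfs <- vapply(terms, function(tk) dfCount[[tk]], integer(1))
  terms <- terms[dfs >= minDf]
  sort(setdiff(terms, stopwords))
}

#' Count vocabulary-term occurrences in one article
#'
#' Counts over the lowercased, punctuation-stripped token stream of
#' title + keywords + abstract + body. Phrase terms are matched as runs
#' of consecutive tokens; overlapping matches of the same phrase are
#' counted non-overlapping, left to right. Each term is counted
#' independently (a token consumed by a phrase still counts for its
#' unigram).
#'
#' @param articleText an `ArticleText`, or a raw character scalar
#' @param vocabulary character vector of terms
#' @return integer count vector, one entry per vocabulary term
#' @export
countTerms <- function(articleText, vocabulary) {
  toks <- if (is.character(articleText)) tokenize(articleText)
  else articleTokenStream(articleText)
  counts <- integer(length(vocabulary))
  if (length(toks) == 0L) return(counts)
  tokTab <- table(toks)
  for (i in seq_along(vocabulary)) {
    parts <- strsplit(vocabulary[i], " ", fixed = TRUE)[[1]]
    if (length(parts) == 1L) {
      counts[i] <- if (parts %in% names(tokTab))
        as.integer(tokTab[[parts]]) else 0L
    } else {
      k <- length(parts)
      j <- 1L
      n <- 0L
      while (j + k - 1L <= length(toks)) {
        if (all(toks[j:(j + k - 1L)] == parts)) {
          n <- n + 1L
          j <- j + k  # non-overlapping, left to right
        } else j <- j + 1L
      }
      counts[i] <- n
    }
  }
  counts
}

#' TF-IDF weighting of a count matrix
#'
#' weight(d, t) = count(d, t) * idf(t) with the smoothed inverse
#' document frequency idf(t) = ln((1 + N) / (1 + df(t))) + 1, where N is
#' the number of articles and df(t) the number of articles containing t;
#' rows are then L2-normalized (all-zero rows stay zero).
#'
#' @param counts articles x terms matrix (dense or sparse) of
#'   non-negative integers
#' @param pmcids row identifiers
#' @param terms column terms
#' @return a [DocTermMatrix-class]
#' @export
tfidfMatrix <- function(counts, pmcids, terms) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  n <- nrow(counts)
  df <- Matrix::colSums(counts > 0)
  idf <- log((1 + n) / (1 + df)) + 1
  w <- counts %*% Matrix::Diagonal(x = idf)
  nrm <- sqrt(Matrix::rowSums(w^2))
  scale <- ifelse(nrm > 0, 1 / nrm, 0)
  w <- Matrix::Diagonal(x = scale) %*% w
  new("DocTermMatrix", pmcids = as.character(pmcids),
      terms = as.character(terms),
      weights = methods::as(w, "CsparseMatrix"),
      rawCounts = counts, idf = as.numeric(idf))
}

#' Build the document-term matrix of a corpus
#'
#' @param corpus output of [readCorpus()]
#' @param vocabulary character vector of terms (default: built with
#'   [buildVocabulary()])
#' @return a [DocTermMatrix-class]
#' @export
corpusTfidf <- function(corpus, vocabulary = buildVocabulary(corpus)) {
  counts <- do.call(rbind, lapply(corpus, function(a)
    countTerms(a$text, vocabulary)))
  if (is.null(counts)) counts <- matrix(0L, 0L, length(vocabulary))
  tfidfMatrix(counts, names(corpus), vocabulary)
}

#' Write a document-term matrix to disk
#'
#' Writes the weights in MatrixMarket (MTX) format plus
#' `vocabulary.csv` (term, df) and `pmcids.csv` (row order).
#'
#' @param dtm a [DocTermMatrix-class]
#' @param dir output directory
#' @export
writeDocTermMatrix <- function(dtm, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(dtm@weights, file.path(dir, "tfidf.mtx"))
  writeCsv(data.frame(term = dtm@terms,
                      df = Matrix::colSums(dtm@rawCounts > 0)),
           file.path(dir, "vocabulary.csv"))
  writeCsv(data.frame(pmcid = dtm@pmcids), file.path(dir, "pmcids.csv"))
  invisible(dir)
}
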