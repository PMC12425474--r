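# Participant-group extraction: a deterministic, grammar-style scanner.
# A mention is a participant count adjacent to a group noun, optionally
# preceded by adjectives; details (age, sex counts) in a following
# parenthetical or clause of the same sentence attach to the nearest
# preceding mention. String matching and hard-coded rules only - no
# statistical learning.

groupNouns <- c("participants", "subjects", "patients", "controls",
                "volunteers", "individuals", "adults", "children")

diseaseAdjectives <- c(
  "depressed", "schizophrenic", "autistic", "epileptic", "aphasic",
  "bipolar", "demented", "parkinsonian", "adhd", "asd", "mdd", "ocd",
  "ptsd"
)

plainAdjectives <- c("healthy", "right-handed", "left-handed", "adult",
                     "young", "elderly", "male", "female", "control")

onesWords <- c(one = 1, two = 2, three = 3, four = 4, five = 5, six = 6,
               seven = 7, eight = 8, nine = 9)
teenWords <- c(ten = 10, eleven = 11, twelve = 12, thirteen = 13,
               fourteen = 14, fifteen = 15, sixteen = 16, seventeen = 17,
               eighteen = 18, nineteen = 19)
tensWords <- c(twenty = 20, thirty = 30, forty = 40, fifty = 50,
               sixty = 60, seventy = 70, eighty = 80, ninety = 90)

# "twenty-five" -> 25; "seven" -> 7; NA when not a number word
wordToNumber <- function(w) {
  w <- tolower(w)
  if (w %in% names(onesWords)) return(unname(onesWords[w]))
  if (w %in% names(teenWords)) return(unname(teenWords[w]))
  parts <- strsplit(w, "-", fixed = TRUE)[[1]]
  if (parts[1] %in% names(tensWords)) {
    v <- unname(tensWords[parts[1]])
    if (length(parts) == 1L) return(v)
    if (length(parts) == 2L && parts[2] %in% names(onesWords))
      return(v + unname(onesWords[parts[2]]))
  }
  NA_real_
}

wordNumberRx <- paste0(
  "(?:", paste(names(tensWords), collapse = "|"), ")",
  "(?:-(?:", paste(names(onesWords), collapse = "|"), "))?",
  "|", paste(c(names(teenWords), names(onesWords)), collapse = "|")
)

# integers may carry comma thousand-separators
integerRx <- "\\d{1,3}(?:,\\d{3})+|\\d+"

mentionRx <- sprintf(
  "(?i)\\b(?:n\\s*=\\s*(%s)|(%s)|(%s))\\s+((?:(?:%s)\\s+)*)(%s)\\b",
  integerRx, integerRx, wordNumberRx,
  paste(c(plainAdjectives, diseaseAdjectives), collapse = "|"),
  paste(groupNouns, collapse = "|")
)

parseIntegerToken <- function(s) as.numeric(gsub(",", "", s))

# Sentence boundaries with 0-based character offsets.
splitSentences <- function(text) {
  if (!nzchar(text))
    return(data.frame(start = integer(), end = integer(),
                      sentence = character(), stringsAsFactors = FALSE))
  ends <- gregexpr("[.!?](?=\\s|$)", text, perl = TRUE)[[1]]
  if (ends[1] == -1L) ends <- integer()
  bounds <- unique(c(as.integer(ends), nchar(text)))
  starts0 <- c(0L, bounds[-length(bounds)])
  out <- data.frame(start = starts0, end = bounds, stringsAsFactors = FALSE)
  out$sentence <- substring(text, out$start + 1L, out$end)
  # trim leading whitespace, keeping offsets honest
  lead <- nchar(out$sentence) - nchar(sub("^\\s+", "", out$sentence))
  out$start <- out$start + lead
  out$sentence <- substring(text, out$start + 1L, out$end)
  out[nzchar(trimws(out$sentence)), , drop = FALSE]
}

emptyMentions <- function() {
  data.frame(start = integer(), end = integer(), count = numeric(),
             noun = character(), status = character(),
             age_mean = numeric(), age_sd = numeric(), age_min = numeric(),
             age_max = numeric(), n_female = numeric(), n_male = numeric(),
             sentence_index = integer(), stringsAsFactors = FALSE)
}

mentionStatus <- function(adjectives, noun) {
  adjectives <- tolower(adjectives)
  noun <- tolower(noun)
  if (noun == "patients" || any(adjectives %in% diseaseAdjectives))
    return("patients")
  if (noun == "controls" || "healthy" %in% adjectives) return("healthy")
  "unknown"
}

numRx <- "\\d+(?:\\.\\d+)?"

attachDetails <- function(mentions, sentence, sentStart, sentIdx) {
  inSent <- which(mentions$sentence_index == sentIdx)
  if (length(mentions$start) == 0L || length(inSent) == 0L) return(mentions)
  nearest <- function(pos0) {
    cand <- inSent[mentions$start[inSent] < pos0]
    if (length(cand) == 0L) return(NA_integer_)
    cand[which.max(mentions$start[cand])]
  }
  apply1 <- function(rx, fields) {
    m <- gregexpr(rx, sentence, perl = TRUE)[[1]]
    if (m[1] == -1L) return()
    for (k in seq_along(m)) {
      pos0 <- sentStart + m[k] - 1L
      i <- nearest(pos0)
      if (is.na(i)) next
      sub <- substring(sentence, m[k], m[k] + attr(m, "match.length")[k] - 1L)
      g <- regmatches(sub, regexec(rx, sub, perl = TRUE))[[1]]
      for (f in seq_along(fields)) {
        val <- as.numeric(g[f + 1L])
        if (is.na(mentions[[fields[f]]][i]))
          mentions[[fields[f]]][i] <<- val
      }
    }
  }
  # mean age 24.5 +/- 3.2 years  |  aged 24.5 +/- 3.2
  apply1(sprintf(
    "(?i)(?:mean age|aged)\\s*(?:of\\s+|:\\s*)?(%s)\\s*(?:±|\\+/-)\\s*(%s)(?:\\s*years)?",
    numRx, numRx), c("age_mean", "age_sd"))
  # aged 18-35 years | age range 18 to 35
  apply1(sprintf(
    "(?i)(?:aged|age range:?)\\s*(?:of\\s+)?(%s)\\s*(?:–|-|to)\\s*(%s)(?:\\s*years)?",
    numRx, numRx), c("age_min", "age_max"))
  # mean age 24.5 years (no sd)
  apply1(sprintf(
    "(?i)mean age\\s*(?:of\\s+|:\\s*)?(%s)(?:\\s*years)?(?!\\s*(?:±|\\+/-|–|-|to))",
    numRx), "age_mean")
  # 13 female / 13 females / 13 women / 13 F
  apply1("(?i)\\b(\\d+)\\s*(?:females?|women|F)\\b", "n_female")
  apply1("(?i)\\b(\\d+)\\s*(?:males?|men|M)\\b", "n_male")
  mentions
}

#' Parse participant-group mentions from text
#'
#' Deterministic left-to-right scan. A mention requires a count (an
#' integer, possibly with comma thousand-separators, a number word, or
#' an "n = 25" form) immediately followed by an optional adjective and a
#' group noun. Details in a following parenthetical or clause of the
#' same sentence (mean age with or without an sd, an age range, and sex
#' counts, including single-letter "13 F" forms) attach to the nearest
#' preceding mention. A count next to a non-group noun ("120 images")
#' is rejected.
#'
#' @param text the article text (or any text) to scan
#' @return data.frame, one row per mention: start, end (0-based,
#'   half-open character span into `text`), count, noun, status
#'   (patients/healthy/unknown), age_mean, age_sd, age_min, age_max,
#'   n_female, n_male, sentence_index
#' @export
parseGroupMentions <- function(text) {
  sentences <- splitSentences(text)
  mentions <- emptyMentions()
  for (si in seq_len(nrow(sentences))) {
    s <- sentences$sentence[si]
    s0 <- sentences$start[si]
    m <- gregexpr(mentionRx, s, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      for (k in seq_along(m)) {
        sub <- substring(s, m[k], m[k] + attr(m, "match.length")[k] - 1L)
        g <- regmatches(sub, regexec(mentionRx, sub, perl = TRUE))[[1]]
        count <- if (nzchar(g[2])) parseIntegerToken(g[2])
        else if (nzchar(g[3])) parseIntegerToken(g[3])
        else wordToNumber(g[4])
        if (is.na(count) || count <= 0) next
        adjectives <- tokenize(g[5])
        noun <- tolower(g[6])
        mentions <- rbind(mentions, data.frame(
          start = s0 + m[k] - 1L,
          end = s0 + m[k] - 1L + attr(m, "match.length")[k],
          count = count, noun = noun,
          status = mentionStatus(adjectives, noun),
          age_mean = NA_real_, age_sd = NA_real_, age_min = NA_real_,
          age_max = NA_real_, n_female = NA_real_, n_male = NA_real_,
          sentence_index = si, stringsAsFactors = FALSE
        ))
      }
    }
    mentions <- attachDetails(mentions, s, s0, si)
  }
  rownames(mentions) <- NULL
  mentions
}

#' Infer the participant group structure of an article
#'
#' Aggregates the group mentions of one article, applying in order:
#' (1) counts above 10,000 are dropped (accession numbers, stimulus
#' counts); (2) mentions with identical count and status within one
#' sentence are merged; (3) if one mention's count equals the sum of the
#' counts of at least two others, it is the study total and the others
#' are subgroups; (4) otherwise, with several mentions, the total is the
#' sum of the group counts; (5) a single remaining mention is the total,
#' and the structure is single-group. No mentions give a structure with
#' an absent total (a "no guess").
#'
#' @param mentions data.frame from [parseGroupMentions()]
#' @return list: `groups` (data.frame of resolved groups), `total`
#'   (numeric or NA), `singleGroup` (logical)
#' @export
inferGroupStructure <- function(mentions) {
  noGuess <- list(groups = emptyMentions(), total = NA_real_,
                  singleGroup = FALSE)
  if (nrow(mentions) == 0L) return(noGuess)
  m <- mentions[mentions$count <= 10000, , drop = FALSE]            # (1)
  if (nrow(m) == 0L) return(noGuess)
  key <- paste(m$count, m$status, m$sentence_index)                 # (2)
  m <- m[!duplicated(key), , drop = FALSE]
  if (nrow(m) >= 3L) {                                              # (3)
    for (i in seq_len(nrow(m))) {
      if (m$count[i] == sum(m$count[-i])) {
        groups <- m[-i, , drop = FALSE]
        rownames(groups) <- NULL
        return(list(groups = groups, total = m$count[i],
                    singleGroup = FALSE))
      }
    }
  }
  if (nrow(m) > 1L) {                                               # (4)
    rownames(m) <- NULL
    return(list(groups = m, total = sum(m$count), singleGroup = FALSE))
  }
  rownames(m) <- NULL                                               # (5)
  list(groups = m, total = m$count[1], singleGroup = TRUE)
}

#' Sample size of a group structure
#'
#' @param structure output of [inferGroupStructure()]
#' @return the study total, or NA for a "no guess"
#' @export
sampleSize <- function(structure) structure$total

#' Evaluate sample-size predictions against a truth table
#'
#' Error metrics are computed over the guessed cases only; `recall` is
#' the fraction of truth articles for which a guess was made. Truth
#' values of 0 are excluded from the percentage metrics with a warning.
#'
#' @param predictions named numeric vector (NA = no guess), names are
#'   pmcids
#' @param truth named numeric vector covering all prediction names
#' @return list: exact_match_rate, mape, median_abs_pct_error,
#'   median_abs_error, recall, median_pred, median_truth, n_guessed
#' @export
evaluateSampleSizes <- function(predictions, truth) {
  stopifnot(all(names(predictions) %in% names(truth)))
  guessed <- names(predictions)[!is.na(predictions)]
  recall <- length(guessed) / length(truth)
  p <- predictions[guessed]
  t <- truth[guessed]
  if (any(t == 0)) {
    warning("truth value 0 excluded from percentage metrics")
    pctKeep <- t != 0
  } else pctKeep <- rep(TRUE, length(t))
  pct <- abs(p[pctKeep] - t[pctKeep]) / t[pctKeep] * 100
  list(
    exact_match_rate = if (length(p)) mean(p == t) else NA_real_,
    mape = if (length(pct)) mean(pct) else NA_real_,
    median_abs_pct_error = if (length(pct)) median(pct) else NA_real_,
    median_abs_error = if (length(p)) median(abs(p - t)) else NA_real_,
    recall = recall,
    median_pred = if (length(p)) median(p) else NA_real_,
    median_truth = median(truth),
    n_guessed = length(guessed)
  )
}

#' Median sample size by publication year, with bootstrap CIs
#'
#' Restricted to single-group studies (multi-group totals conflate
#' designs). Per year, reports the median and a percentile bootstrap
#' 95% confidence interval; years with fewer than 3 records get the
#' median only.
#'
#' @param records data.frame with columns year, sample_size,
#'   single_group
#' @param nBoot bootstrap resamples (>= 100)
#' @param seed RNG seed for reproducible CIs
#' @return data.frame: year, n, median, ci_low, ci_high
#' @export
medianByYear <- function(records, nBoot = 1000L, seed = 0L) {
  stopifnot(nBoot >= 100L)
  records <- records[records$single_group & !is.na(records$sample_size), ,
                     drop = FALSE]
  years <- sort(unique(records$year))
  if (length(years) == 0L)
    return(data.frame(year = numeric(), n = integer(), median = numeric(),
                      ci_low = numeric(), ci_high = numeric()))
  withSeed(seed, {
    out <- lapply(years, function(y) {
      sizes <- records$sample_size[records$year == y]
      med <- median(sizes)
      if (length(sizes) < 3L)
        return(data.frame(year = y, n = length(sizes), median = med,
                          ci_low = NA_real_, ci_high = NA_real_))
      boots <- vapply(seq_len(nBoot), function(b)
        median(sample(sizes, replace = TRUE)), numeric(1))
      ci <- quantile(boots, c(0.025, 0.975), names = FALSE, type = 7)
      data.frame(year = y, n = length(sizes), median = med,
                 ci_low = ci[1], ci_high = ci[2])
    })
    do.call(rbind, out)
  })
}

#' Extract demographics for a whole corpus
#'
#' Parses group mentions in each article's abstract + body, infers the
#' group structure, and flattens everything into one CSV-ready table.
#'
#' @param corpus output of [readCorpus()]
#' @return data.frame: pmcid, group_index, count, status, age_mean,
#'   age_sd, age_min, age_max, n_female, n_male, total, single_group
#' @export
corpusDemographics <- function(corpus) {
  rows <- lapply(corpus, function(a) {
    txt <- paste(a$text$abstract, a$text$body, sep = "\n\n")
    st <- inferGroupStructure(parseGroupMentions(txt))
    g <- st$groups
    if (nrow(g) == 0L)
      return(data.frame(pmcid = a$metadata$pmcid, group_index = NA_integer_,
                        count = NA_real_, status = NA_character_,
                        age_mean = NA_real_, age_sd = NA_real_,
                        age_min = NA_real_, age_max = NA_real_,
                        n_female = NA_real_, n_male = NA_real_,
                        total = st$total, single_group = st$singleGroup,
                        stringsAsFactors = FALSE))
    data.frame(pmcid = a$metadata$pmcid, group_index = seq_len(nrow(g)) - 1L,
               count = g$count, status = g$status, age_mean = g$age_mean,
               age_sd = g$age_sd, age_min = g$age_min, age_max = g$age_max,
               n_female = g$n_female, n_male = g$n_male, total = st$total,
               single_group = st$singleGroup, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
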