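test_that("the grammar parses the canonical participant sentences", {
  m <- parseGroupMentions(
    "Twenty-five healthy participants (mean age 24.5 ± 3.2 years, 13 female) were scanned.")
  expect_identical(nrow(m), 1L)
  expect_identical(m$count, 25)
  expect_identical(m$status, "healthy")
  expect_identical(m$age_mean, 24.5)
  expect_identical(m$age_sd, 3.2)
  expect_identical(m$n_female, 13)

  m2 <- parseGroupMentions("We recruited 18 patients and 20 controls.")
  expect_identical(m2$count, c(18, 20))
  expect_identical(m2$status, c("patients", "healthy"))

  # a count adjacent to a non-group noun is rejected
  expect_identical(nrow(parseGroupMentions("Participants viewed 120 images.")),
                   0L)
})

test_that("n = forms, comma separators, ranges and sex letters are understood", {
  m <- parseGroupMentions("A sample of n = 25 participants was recruited.")
  expect_identical(m$count, 25)

  m2 <- parseGroupMentions("We scanned 1,024 subjects.")
  expect_identical(m2$count, 1024)

  m3 <- parseGroupMentions("12 patients aged 18–35 years were included.")
  expect_identical(m3$age_min, 18)
  expect_identical(m3$age_max, 35)

  m4 <- parseGroupMentions("We tested 30 participants (16 F, 14 M).")
  expect_identical(m4$n_female, 16)
  expect_identical(m4$n_male, 14)
})

test_that("mention spans re-slice the source to a reparseable string", {
  txt <- "Filler sentence first. We recruited 18 patients and 20 controls."
  m <- parseGroupMentions(txt)
  for (i in seq_len(nrow(m))) {
    slice <- substr(txt, m$start[i] + 1L, m$end[i])
    again <- parseGroupMentions(paste0(slice, "."))
    expect_identical(again$count, m$count[i])
    expect_identical(again$status, m$status[i])
  }
})

test_that("group-structure inference applies its rules in order", {
  # subgroup-sum rule: 38 = 18 + 20 marks the total
  st <- inferGroupStructure(parseGroupMentions(
    "We studied 38 subjects: 18 patients and 20 controls."))
  expect_identical(st$total, 38)
  expect_identical(nrow(st$groups), 2L)
  expect_false(st$singleGroup)
  expect_identical(st$total, sum(st$groups$count))  # conservation

  # single mention: its count is the total
  st2 <- inferGroupStructure(parseGroupMentions(
    "We recruited 25 healthy participants."))
  expect_identical(st2$total, 25)
  expect_true(st2$singleGroup)

  # identical count and status in one sentence merge
  st3 <- inferGroupStructure(parseGroupMentions(
    "The 12 patients were scanned twice, and the 12 patients returned."))
  expect_identical(st3$total, 12)
  expect_true(st3$singleGroup)

  # two distinct-status groups without a stated total are summed
  st4 <- inferGroupStructure(parseGroupMentions(
    "We compared 18 patients and 20 controls."))
  expect_identical(st4$total, 38)

  # counts above 10,000 are discarded
  st5 <- inferGroupStructure(parseGroupMentions(
    "The registry listed 123456 patients."))
  expect_true(is.na(st5$total))

  # no mentions: a no-guess
  expect_true(is.na(sampleSize(inferGroupStructure(parseGroupMentions("")))))
})

test_that("evaluation metrics reproduce hand-computed values", {
  pred <- c(a = 30, b = NA)
  truth <- c(a = 30, b = 40)
  m <- evaluateSampleSizes(pred, truth)
  expect_identical(m$exact_match_rate, 1)
  expect_identical(m$recall, 0.5)
  expect_identical(m$mape, 0)

  m2 <- evaluateSampleSizes(c(a = 33), c(a = 30))
  expect_equal(m2$mape, 10, tolerance = 1e-12)
  expect_equal(m2$median_abs_error, 3)

  ident <- setNames(c(10, 20, 30, 40, 50), letters[1:5])
  m3 <- evaluateSampleSizes(ident, ident)
  expect_identical(m3$exact_match_rate, 1)
  expect_identical(m3$mape, 0)
  expect_identical(m3$median_abs_pct_error, 0)
  expect_identical(m3$recall, 1)

  # a 10-item table with no-guesses and mixed errors, metrics by hand
  pred4 <- c(a = 20, b = 22, c = NA, d = 50, e = 10, f = NA, g = 40,
             h = 45, i = 30, j = 60)
  truth4 <- c(a = 20, b = 20, c = 35, d = 50, e = 20, f = 15, g = 40,
              h = 50, i = 30, j = 50)
  m4 <- evaluateSampleSizes(pred4, truth4)
  expect_identical(m4$recall, 0.8)
  expect_identical(m4$exact_match_rate, 0.5)  # a, d, g, i of 8 guessed
  # pct errors: 0, 10, 0, 50, 0, 10, 0, 20 -> mean 11.25, median 5
  expect_equal(m4$mape, 11.25, tolerance = 1e-12)
  expect_equal(m4$median_abs_pct_error, 5, tolerance = 1e-12)
  expect_warning(evaluateSampleSizes(c(a = 5), c(a = 0)), "0")
})

test_that("per-year medians filter to single-group studies with seeded CIs", {
  rec <- data.frame(year = 2020, sample_size = c(10, 20, 30),
                    single_group = TRUE)
  out <- medianByYear(rec, nBoot = 100, seed = 1)
  expect_identical(out$median, 20)
  expect_true(out$ci_low <= 20 && out$ci_high >= 20)

  multi <- data.frame(year = 2020, sample_size = c(10, 20, 30),
                      single_group = FALSE)
  expect_identical(nrow(medianByYear(multi, nBoot = 100, seed = 1)), 0L)

  # fewer than 3 records: median only
  two <- data.frame(year = 2021, sample_size = c(12, 18), single_group = TRUE)
  o2 <- medianByYear(two, nBoot = 100, seed = 1)
  expect_identical(o2$median, 15)
  expect_true(is.na(o2$ci_low))

  # same seed, same CI; the caller's RNG stream is untouched
  set.seed(99); before <- runif(1)
  a <- medianByYear(rec, nBoot = 200, seed = 5)
  b <- medianByYear(rec, nBoot = 200, seed = 5)
  expect_identical(a, b)
  set.seed(99)
  expect_identical(runif(1), before)
})

test_that("every generator template parses to exactly its expected mention", {
  set.seed(123)
  for (rep in 1:200) {
    id <- sample(pmcmeta:::allTemplateIds, 1)
    params <- sampleTemplateParams(id)
    tpl <- sentenceTemplates(id, params)
    m <- parseGroupMentions(tpl$sentence)
    expect_identical(nrow(m), nrow(tpl$mentions), label = tpl$sentence)
    expect_identical(m$count, tpl$mentions$count, label = tpl$sentence)
    expect_identical(m$status, tpl$mentions$status, label = tpl$sentence)
    for (f in c("age_mean", "age_sd", "age_min", "age_max",
                "n_female", "n_male"))
      expect_identical(m[[f]], tpl$mentions[[f]],
                       label = paste(tpl$sentence, f))
    st <- inferGroupStructure(m)
    expect_identical(st$total, as.numeric(tpl$total), label = tpl$sentence)
    expect_identical(st$singleGroup, tpl$singleGroup, label = tpl$sentence)
  }
})
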