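---
title: "pmcmeta: methods, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pmcmeta: methods, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

pmcmeta implements a full literature-mining pipeline for PubMed Central
full text: batched, resumable retrieval; JATS parsing; stereotactic
coordinate extraction; grammar-based participant-demographics
extraction; TF-IDF featurization; and voxelwise coordinate-based
meta-analysis. This vignette records the models, the tunable
parameters, and the design decisions behind them, in the spirit of a
methods section: what is computed, under which assumptions, and what
the test suite does and does not establish.

## Retrieval

The download client speaks the E-utilities vocabulary (E-Search with
`usehistory`, E-Fetch by `retstart`/`retmax`) through a *transport*
contract: a function from request parameters to a status code and a
body. Live HTTP is one implementation; the test suite uses scripted
transports exclusively, because the behaviors that matter — retries,
resume, rate limiting, validation of bodies that claim success but
carry an error message — are only testable with a controllable
counterpart.

Decisions where the protocol leaves room:

- **Batch size** 500 articles per E-Fetch; batches are the unit of
  retry and resume.
- **Retries**: 4 attempts per request with exponential backoff starting
  at 1 s. A batch is marked `done` only after its payload parses as an
  article set with no error element; `failed` batches do not abort the
  run and are reported at the end, so a long download survives
  transient outages.
- **Rate limits** default to the documented 3 requests/s without an API
  key and 10 with one, enforced over a sliding 1 s window; both are
  configurable. The key, when given, is attached to every request.
- **State** is one JSON file per download directory holding the history
  keys and per-batch status; it is rewritten after every batch, so an
  interrupted run resumes with only the missing batches.

## JATS parsing

Metadata is read with XPath; absent fields are `NA`, never empty
strings, and a missing PMCID is an error because it is the corpus key.
When several `pub-date` elements disagree, the publication year follows
print > electronic > collection precedence — a choice, since JATS
imposes none.

Text extraction reduces inline markup to its text, joins paragraphs
with blank lines, normalizes Unicode to NFKC and collapses whitespace.
Table contents are excluded from the running text and kept with the
table (caption and footnotes included), so terms in tables are not
double-counted by the featurizer.

JATS permits two table markups: the XHTML model (`tr`/`td` with
`colspan`/`rowspan`) and the OASIS exchange model (`row`/`entry` with
`namest`/`nameend`/`morerows`). Both are normalized to a rectangular
character grid, and a spanned value is **duplicated into every covered
cell** rather than left blank. The reason is downstream column
matching: coordinate columns must stay dense for header detection and
row parsing to line up. The invariant that both dialects produce
byte-identical grids and CSV for semantically identical tables is
enforced by paired fixtures in the test suite.

## Coordinate extraction

Column detection looks for `x`, `y`, `z` header tokens
(case-insensitive, decorations like "(mm)" or "-coord" stripped),
either as three adjacent columns in order or as one combined column
labelled with all three tokens ("x, y, z"). When no header row is
marked, the first body row is tried — real tables frequently omit
header markup. Numeric parsing accepts the ASCII hyphen, the Unicode
minus (U+2212), and the en-dash as negative signs; combined cells split
on comma, semicolon, or whitespace; a row with any unparseable member
is skipped rather than guessed.

Filtering keeps triplets with all |values| ≤ 150 mm (outside that is
outside any head) and drops the exact origin (0, 0, 0), a common table
artifact. Within one table, byte-identical repeated rows collapse to
one; distinct rows that happen to report the same peak are kept, as are
identical peaks across tables of one article — deduplicating those
would require contrast-level understanding the package does not claim.

The coordinate space is detected per article from cue-word counts:
Talairach cues ("talairach", "t88") versus MNI cues ("mni", "icbm");
the higher count wins, a tie with both present resolves to MNI (the
dominant convention in the modern literature), and no cues yield
UNKNOWN. Downstream analysis includes UNKNOWN-space records as-is while
preserving the label, and no Talairach-to-MNI conversion is applied;
users who need strict space separation can filter on the label.

## Text features

The document-term matrix uses smoothed TF-IDF:
idf(t) = ln((1 + N)/(1 + df(t))) + 1, weights = count × idf, rows
L2-normalized, computed over title + keywords + abstract + body. The
formula is fixed (rather than "some TF-IDF variant") so results are
bit-reproducible; a brute-force restatement of the same formula serves
as the oracle in the tests, with agreement to 1e-12. The default
vocabulary is the corpus's own unigrams with document frequency ≥ 2
minus a small stop-word list; a user vocabulary file (one term per
line, phrases allowed) overrides it. Phrase terms match as consecutive
token runs, counted non-overlapping left to right, and independently of
their constituent unigrams.

## Meta-analysis

**Grid.** The default spatial support is an MNI-like bounding box
(x ∈ [−90, 90], y ∈ [−126, 90], z ∈ [−72, 108] mm) at 4 mm isotropic
voxels — 116,380 voxels, which keeps every map, permutation test, and
ridge fit comfortable on a laptop; 2 mm is available by configuration.

**Study maps.** Binary maps mark every voxel whose center lies within
`radius` of a reported peak (default 10 mm — the conventional sphere
for this family of methods). Density maps are sums of isotropic
Gaussian kernels (default sigma 3.82 mm, the sd equivalent of a 9 mm
FWHM), each normalized to unit sum over an unbounded grid and truncated
at 6 sigma, so in-grid mass equals the interior peak count to about
1e-6 relative.

**Association test.** Per voxel, the 2×2 contingency of (term
present/absent) × (voxel active/inactive) over studies is tested with
the Pearson chi-square, *without* Yates continuity correction, p from
χ² with 1 df, and a z map signed by whether P(active | term) exceeds
P(active | no term). Voxels with a zero margin (active everywhere or
nowhere) get χ² = 0, p = 1. Multiplicity is controlled with
Benjamini–Hochberg at q = 0.01 by default. These choices are stated so
users can reconcile numbers with other implementations (some of which
apply the continuity correction).

A calibration note: the chi-square approximation is only trustworthy
where expected cell counts are adequate. The permutation-calibration
check in the test suite therefore measures the false-positive rate over
voxels where every expected 2×2 cell count is at least 5 (the textbook
adequacy rule). Outside that mask — voxels touched by a handful of
studies — the discrete statistic is strongly conservative, which is the
safe direction but makes a raw "5% of all voxels at p < 0.05"
expectation meaningless at desk-scale corpora.

**Ridge model.** The text-to-brain model is a deliberately simple
one-stage linear map: per-voxel ridge regression of the smoothed peak
maps on the TF-IDF features, solved in closed form from the normal
equations with the penalty (default 0.1) on all coefficients. Query
prediction tokenizes free text, builds its TF-IDF row with the
*training* idf, and returns the feature-weighted sum of coefficient
maps. This is a documented simplification of the multi-stage smoothing
models in the literature: the interface (text in, brain map out) is
the same, the vocabulary-smoothing machinery is out of scope.

## Participant demographics

The extractor is a two-step heuristic with no statistical learning.
Step one scans sentence by sentence for group mentions — a count
(digits with optional comma separators, a number word, or an
"n = 25" form) adjacent to a group noun (participants, subjects,
patients, controls, volunteers, individuals, adults, children),
optionally with adjectives. Details in the same sentence attach to the
nearest preceding mention: mean age with or without a ± sd, an age
range ("aged 18–35 years"), and sex counts including single-letter
"13 F" forms. Status is resolved by rule: noun "patients" or a disease
adjective → patients; "healthy" or noun "controls" → healthy;
otherwise unknown. Number words are recognized through ninety-nine
("twenty-five"); compound forms beyond twenty are needed in practice
because articles spell out sentence-initial counts.

Step two aggregates mentions into a group structure, applying in
order: (1) counts above 10,000 are dropped (accession numbers,
stimulus counts); (2) identical count-and-status mentions within one
sentence merge; (3) if one mention equals the sum of at least two
others, it is the stated total and the others are subgroups; (4)
otherwise the total is the sum of the group counts; (5) a single
remaining mention is a single-group study. No mentions produce a
"no guess", which feeds the recall metric rather than being silently
wrong.

Evaluation metrics are computed over guessed cases only (exact-match
rate, MAPE, median absolute percent error, median absolute error),
with recall reported as the fraction of truth articles that received a
guess; truth values of zero are excluded from percentage metrics with
a warning. Per-year medians are restricted to single-group studies —
multi-group totals conflate designs — with percentile bootstrap 95%
intervals (default 1,000 resamples) under an explicit seed; years with
fewer than 3 records report a median but no interval.

The grammar is a reconstruction: the scanner handles simple,
well-formed participant sentences and is expected to miss complex
phrasings (subordinate clauses, counts split across sentences,
exclusion bookkeeping). On real articles the honest expectation is
high precision on the sentences it does match and substantially
incomplete recall.

## The synthetic corpus

The generator emits JATS article sets in the same layout the download
client produces, with a complete ground-truth ledger: per article the
pmcid, year, planted sample size and group structure, planted space
cue, the table dialect used, mentioned terms, and every planted peak.
Defaults encode the study conditions used throughout the tests:
3–8 peaks per article; peak coordinates rounded to integer mm;
XHTML/OASIS dialect mix 0.5; sample sizes log-normal around a median
of 25 (right-skewed, as cohort sizes are) clamped to [5, 200];
participant sentences drawn from six templates (single group,
patients + controls + stated total, word-number counts, mean ± sd age,
age range, sex counts) plus distractor sentences that must *not*
parse; MNI cue planted with probability 0.8, Talairach otherwise.

Term–location coupling is **study-level**: an article mentioning the
term plants one peak at the focus plus isotropic noise (sd 5 mm) with
probability 0.9, a non-mentioning article with probability 0.1, and
all remaining peaks are uniform in-grid. The study-level formulation
matters: coupling every peak independently at 0.9 saturates activation
around the focus (essentially every term study hits it), producing a
plateau of statistically indistinguishable voxels in which no method
could single out the focus. The default focus (2, −18, 44) mm sits on
a voxel center of the default grid, as planted-signal validations
should align the signal with the analysis lattice.

What passing tests on this corpus establishes: the mechanics —
parsing, normalization, recovery, calibration, caching — are correct
under in-grammar text and well-formed tables. What they do not
establish: performance on real articles, whose tables are messier,
whose participant descriptions are frequently out of grammar, and
whose term–activation couplings are far weaker than the planted 0.9
vs 0.1 contrast.

## Problem sizes and numerical choices

The test suite and acceptance script run at deliberate desk scale:
200-article corpora for calibration and signal recovery, 50
permutations for the type-I check, 100 replicates × 1,000 resamples
for bootstrap coverage, 10 random 20 × 100 corpora for the chi-square
oracle, and 1,000 random vectors for the FDR oracle — a few minutes
end to end on one CPU. Numerical tolerances: chi-square and its
oracle agree to 1e-9; TF-IDF to 1e-12; kernel mass to 1e-6; NIfTI
round-trips at float precision. Ties in the space heuristic break
toward MNI; ties among candidate totals in rule (3) break toward the
first mention in document order; all generator formatting is
fixed-precision so corpora are byte-identical across platforms.

## Pipeline and caching

Each step writes to its own directory under a query-fingerprint root
and records a sentinel with a fingerprint of its parameters and a
fresh run id. A step re-runs iff its fingerprint changed; downstream
fingerprints chain the upstream run ids, so invalidation is
conservative: changing a parameter (or deleting a sentinel) re-runs
that step and everything after it, never anything before. Outputs are
deterministic, so interrupted or partially invalidated runs converge
to the same bytes as a clean run. Plugins register into an explicit
in-package registry (R has no entry-point packaging mechanism); a
plugin whose load hook throws is skipped with a warning and cannot
crash the host. The demographics step ships as the built-in
`participants` plugin.

## Known limitations

- Only PMC Open Access content is addressed; there is no publisher
  scraping and no PDF handling.
- Coordinate extraction reads tables only; peaks reported in running
  text are out of scope, as are effect sizes and cluster extents.
- No Talairach-to-MNI conversion; space labels are preserved instead.
- The demographics grammar is intentionally shallow (see above).
- The ridge text-to-brain model is a one-stage simplification.
- The chi-square test is asymptotic; at low study counts per voxel it
  is conservative rather than exact.
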