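mkPsms <- function(score, decoy, engine = "cometlike",
                   direction = "higher_better") {
  data.frame(spectrumId = sprintf("s%03d", seq_along(score)),
             peptide = sprintf("PEPTIDEK%03d", seq_along(score)),
             mods = "", score = score, decoy = decoy, engine = engine,
             scoreDirection = direction, stringsAsFactors = FALSE)
}

test_that("q-values on the T,T,D,T,D ranking match the threshold-sweep oracle", {
  d <- mkPsms(c(5, 4, 3, 2, 1), c(FALSE, FALSE, TRUE, FALSE, TRUE))
  r <- engineFdrScores(d)
  expect_equal(r$qValue, c(0, 0, 1/3, 1/3, 2/3))
  expect_equal(r$qValue,
               oracleQValues(d$score, d$decoy, lowerBetter = FALSE))
  ## anchors carry the q-values at the decoy ranks
  expect_equal(r$fdrScore[r$decoy], c(1/3, 2/3))
})

test_that("zero decoys give all-zero FDR scores; all decoys cap at 1", {
  r0 <- engineFdrScores(mkPsms(5:1, rep(FALSE, 5)))
  expect_true(all(r0$fdrScore == 0))
  r1 <- engineFdrScores(mkPsms(5:1, rep(TRUE, 5)))
  expect_true(all(r1$qValue <= 1))
  expect_true(all(r1$qValue >= 1))  # every prefix is pure decoy
})

test_that("FDR scores are non-decreasing along the engine ranking", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(20:200, 1L)
    d <- mkPsms(stats::rnorm(n), stats::runif(n) < 0.4)
    r <- engineFdrScores(d)
    expect_true(all(diff(r$fdrScore) >= -1e-12))
    expect_true(all(r$fdrScore >= 0 & r$fdrScore <= 1))
  }
})

test_that("q-values equal the brute-force sweep on random lists with ties", {
  set.seed(6)
  for (rep in 1:30) {
    n <- sample(10:150, 1L)
    score <- sample(seq_len(20L), n, replace = TRUE)  # many ties
    decoy <- stats::runif(n) < 0.35
    lower <- rep %% 2L == 0L
    d <- mkPsms(score, decoy,
                engine = if (lower) "msgflike" else "cometlike",
                direction = if (lower) "lower_better" else "higher_better")
    r <- engineFdrScores(d)
    expect_equal(r$qValue, oracleQValues(score, decoy, lower))
  }
})

test_that("lower-better scores rank e-value style engines correctly", {
  d <- mkPsms(c(1e-9, 1e-6, 1e-3, 1e-2, 1e-1),
              c(FALSE, FALSE, TRUE, FALSE, TRUE),
              engine = "msgflike", direction = "lower_better")
  r <- engineFdrScores(d)
  expect_identical(r$spectrumId, d$spectrumId)  # already sorted ascending
  expect_equal(r$qValue, c(0, 0, 1/3, 1/3, 2/3))
})

test_that("combined raw score is the mean of engine FDR scores", {
  mk <- function(engine, fdr) {
    data.frame(spectrumId = "s1", peptide = "PEP", mods = "",
               decoy = FALSE, engine = engine, fdrScore = fdr,
               stringsAsFactors = FALSE)
  }
  comb <- combinedFdr(list(cometlike = mk("cometlike", 0.002),
                           cruxlike = mk("cruxlike", 0.010),
                           msgflike = mk("msgflike", 0.006)))
  expect_equal(comb$combinedRaw, 0.006)
  expect_identical(comb$nEngines, 3L)
})

test_that("a partition without decoys yields all-zero combined FDR scores", {
  mkEng <- function(engine, n) {
    data.frame(spectrumId = sprintf("s%02d", seq_len(n)),
               peptide = sprintf("P%02dK", seq_len(n)), mods = "",
               decoy = FALSE, engine = engine,
               fdrScore = seq_len(n) / 100,
               stringsAsFactors = FALSE)
  }
  comb <- combinedFdr(list(cometlike = mkEng("cometlike", 12L),
                           cruxlike = mkEng("cruxlike", 12L)))
  expect_true(all(comb$combinedFdrScore == 0))
})

test_that("single-engine keys have undefined combined FDR scores", {
  one <- data.frame(spectrumId = "s1", peptide = "PEP", mods = "",
                    decoy = FALSE, engine = "cometlike", fdrScore = 0.004,
                    stringsAsFactors = FALSE)
  comb <- combinedFdr(list(cometlike = one))
  expect_true(is.na(comb$combinedFdrScore))
})

test_that("conflicting decoy flags across engines are library corruption", {
  a <- data.frame(spectrumId = "s1", peptide = "PEP", mods = "",
                  decoy = FALSE, engine = "cometlike", fdrScore = 0.004,
                  stringsAsFactors = FALSE)
  b <- a; b$decoy <- TRUE; b$engine <- "cruxlike"
  expect_error(combinedFdr(list(cometlike = a, cruxlike = b)),
               "inconsistent")
})

test_that("multistage filter applies the quoted rules exactly", {
  row <- function(minFdr, comb, nEng) {
    data.frame(spectrumId = "s1", peptide = "P", mods = "",
               decoy = FALSE, engineSet = "x", nEngines = nEng,
               minEngineFdr = minFdr, combinedRaw = comb,
               combinedFdrScore = comb, smallPartition = FALSE,
               stringsAsFactors = FALSE)
  }
  ## combined <= 0.01 rescues engines above 0.01 but within 0.05
  expect_identical(nrow(multistageFilter(row(0.02, 0.009, 2L),
                                         "reference")), 1L)
  ## a single engine at 0.004 passes reference but fails novel
  single <- row(0.004, NA_real_, 1L)
  expect_identical(nrow(multistageFilter(single, "reference")), 1L)
  expect_identical(nrow(multistageFilter(single, "novel")), 0L)
  ## the <= 0.05 safeguard overrides a good combined score
  expect_identical(nrow(multistageFilter(row(0.2, 0.008, 2L),
                                         "reference")), 0L)
})

test_that("the multistage filter is idempotent and reports unidentified spectra", {
  set.seed(8)
  n <- 60L
  d <- data.frame(spectrumId = sprintf("s%03d", seq_len(n)),
                  peptide = sprintf("P%03dK", seq_len(n)), mods = "",
                  decoy = stats::runif(n) < 0.3,
                  engineSet = sample(c("a", "a;b"), n, replace = TRUE),
                  nEngines = 1L, minEngineFdr = stats::runif(n) * 0.2,
                  combinedRaw = NA_real_,
                  combinedFdrScore = NA_real_, smallPartition = FALSE,
                  stringsAsFactors = FALSE)
  d$nEngines[d$engineSet == "a;b"] <- 2L
  d$combinedFdrScore[d$nEngines == 2L] <-
    stats::runif(sum(d$nEngines == 2L)) * 0.05
  once <- multistageFilter(d, "reference")
  twice <- multistageFilter(once, "reference")
  strip <- function(x) { attr(x, "unidentifiedSpectra") <- NULL; x }
  expect_identical(strip(once), strip(twice))
  expect_setequal(c(once$spectrumId, attr(once, "unidentifiedSpectra")),
                  d$spectrumId)
})

test_that("PSM ingest keeps one best hit per spectrum, dialect-aware", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(spectrum_id = c("s1", "s1", "s2"),
               peptide = c("AAK", "CCK", "DDK"),
               mods = c("", "", ""),
               score = c(3.0, 2.5, 1.0),
               decoy = c(FALSE, TRUE, FALSE)),
    tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  d <- readPsmTable(tsv, "cometlike")
  expect_identical(nrow(d), 2L)
  expect_identical(d$peptide[d$spectrumId == "s1"], "AAK")
  ## e-value dialect: lower is better
  utils::write.table(
    data.frame(spectrum = c("s1", "s1"), sequence = c("AAK", "CCK"),
               evalue = c(1e-9, 1e-3), label = c("0", "0")),
    tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  d2 <- readPsmTable(tsv, "msgflike")
  expect_identical(d2$peptide, "AAK")
  expect_identical(d2$scoreDirection, "lower_better")
})
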