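mkBlock <- function(refText, qryText, refStart0 = 100L,
                    refSrc = "ref.c1", qrySrc = "lyr.s1") {
  data.frame(
    src = c(refSrc, qrySrc),
    start = c(refStart0, 0L),
    size = c(nchar(gsub("-", "", refText, fixed = TRUE)),
             nchar(gsub("-", "", qryText, fixed = TRUE))),
    strand = "+",
    srcSize = c(10000L, nchar(gsub("-", "", qryText, fixed = TRUE))),
    text = c(refText, qryText), stringsAsFactors = FALSE)
}

mkMaf <- function(...) structure(list(...), class = "MafAlignment")

test_that("MAF files round-trip through the reader and writer", {
  maf <- mkMaf(mkBlock("ATGGCC", "A-GGCC"),
               mkBlock("TTTAAA", "TTTAAA", refStart0 = 500L))
  path <- withr::local_tempfile(fileext = ".maf")
  writeMaf(maf, path)
  back <- readMaf(path)
  expect_length(back, 2L)
  for (i in 1:2) {
    a <- maf[[i]]; b <- back[[i]]
    rownames(a) <- rownames(b) <- NULL
    expect_identical(a, b)
  }
  ## size/text inconsistency is rejected
  bad <- mkMaf(mkBlock("ATGGCC", "AGGCC-"))
  bad[[1L]]$size[[2L]] <- 6L
  writeMaf(bad, path)
  expect_error(readMaf(path), "size mismatch")
})

test_that("the aligned query sequence is read from the TIS column onward", {
  tis <- GenomicRanges::GRanges("c1", IRanges::IRanges(101, 103),
                                strand = "+")
  maf <- mkMaf(mkBlock("ATGGCC", "ATGGCC"))
  expect_identical(alignedSequenceAt(maf, "ref", tis, "lyr"), "ATGGCC")
  ## gaps in the query are removed
  maf2 <- mkMaf(mkBlock("ATGGCC", "A-TGGC"))
  expect_identical(alignedSequenceAt(maf2, "ref", tis, "lyr"), "ATGGC")
  ## reference insertion columns shift but do not corrupt the parse
  maf3 <- mkMaf(mkBlock("AT-GGCC", "ATCGGCC"))
  expect_identical(alignedSequenceAt(maf3, "ref", tis, "lyr"), "ATCGGCC")
  ## a TIS outside every block is uncovered
  far <- GenomicRanges::GRanges("c1", IRanges::IRanges(901, 903),
                                strand = "+")
  expect_true(is.na(alignedSequenceAt(maf, "ref", far, "lyr")))
  ## covering block without the query row
  solo <- maf
  solo[[1L]] <- solo[[1L]][1L, ]
  expect_true(is.na(alignedSequenceAt(solo, "ref", tis, "lyr")))
})

test_that("column mapping equals a naive per-column walk on random blocks", {
  set.seed(19)
  for (rep in 1:20) {
    n <- sample(30:120, 1L)
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    qry <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    ## sprinkle gaps into both rows (never both at one column)
    gapR <- stats::runif(n) < 0.08
    gapQ <- stats::runif(n) < 0.08 & !gapR
    ref[gapR] <- "-"; qry[gapQ] <- "-"
    refText <- paste(ref, collapse = "")
    qryText <- paste(qry, collapse = "")
    nRefBases <- sum(!gapR)
    if (nRefBases < 5L) next
    off <- sample(seq_len(nRefBases - 1L), 1L)
    tis <- GenomicRanges::GRanges(
      "c1", IRanges::IRanges(100L + off, 102L + off), strand = "+")
    maf <- mkMaf(mkBlock(refText, qryText))
    got <- alignedSequenceAt(maf, "ref", tis, "lyr")
    ## oracle: walk columns counting reference bases
    ## the TIS first base (1-based 100 + off) is the off-th reference
    ## base of the block (the block starts at 0-based 100)
    seen <- 0L; col <- NA_integer_
    for (j in seq_len(n)) {
      if (ref[[j]] != "-") seen <- seen + 1L
      if (seen == off && ref[[j]] != "-") { col <- j; break }
    }
    exp <- gsub("-", "", paste(qry[col:n], collapse = ""), fixed = TRUE)
    expect_identical(got, exp)
  }
})

test_that("start-codon status partitions canonical / near-cognate / absent", {
  expect_identical(startCodonStatus("ATGGCA"), "canonical")
  expect_identical(startCodonStatus("CTGGCA"), "near_cognate")
  expect_identical(startCodonStatus("CCGGCA"), "absent")
  expect_identical(startCodonStatus("AT"), "absent")
  nearAll <- c("CTG", "GTG", "TTG", "AAG", "ACG", "AGG", "ATA", "ATC",
               "ATT")
  for (cod in nearAll)
    expect_identical(startCodonStatus(paste0(cod, "AAA")), "near_cognate")
  ## restricted near-cognate set
  expect_identical(startCodonStatus("TTGAAA", nearCognate = "cug_gug"),
                   "absent")
  expect_identical(startCodonStatus("GTGAAA", nearCognate = "cug_gug"),
                   "near_cognate")
})

test_that("orthologous peptide requires min length before a stop or block edge", {
  enc <- function(aa) c(A = "GCT", D = "GAT", K = "AAA")[aa]
  nt25 <- paste0("ATG", paste(rep(enc("A"), 24L), collapse = ""), "TAA")
  r <- orthologousPeptide(nt25, 25L)
  expect_true(r$flag)
  expect_identical(nchar(r$sequence), 25L)
  ## stop at codon 4 with min 8
  ntStop <- paste0("ATG", enc("A"), enc("D"), "TAAGCTGCTGCTGCTGCT")
  r2 <- orthologousPeptide(ntStop, 8L)
  expect_false(r2$flag)
  expect_identical(r2$sequence, "MAD")
  ## block edge truncation at codon 6 of min 8
  ntEdge <- paste0("ATG", paste(rep(enc("K"), 5L), collapse = ""))
  r3 <- orthologousPeptide(ntEdge, 8L)
  expect_false(r3$flag)
  expect_identical(r3$sequence, "MKKKKK")
  ## near-cognate start is decoded to Met
  expect_identical(substr(orthologousPeptide(
    paste0("CTG", enc("A"), enc("A")), 2L)$sequence, 1L, 1L), "M")
})

test_that("planted conservation fates are recovered exactly", {
  sg <- synthGenome(nOrfs = 24L, contigLen = 60000L, seed = 33L)
  tis <- truthTis(sg$truth)
  fates <- rep(c("keep", "near_cognate", "destroy", "unaligned"),
               length.out = length(tis))
  sm <- synthMaf(sg$genome, tis,
                 list(lyr = list(subRate = 0.02, gapRate = 0.01,
                                 fate = fates)),
                 seed = 34L)
  res <- conservationResults(sm$maf, "ref", tis, "lyr", minLenAa = 8L)
  exp <- ifelse(fates == "unaligned", "unaligned",
         ifelse(fates == "destroy", "absent",
         ifelse(fates == "near_cognate", "near_cognate",
                ifelse(sg$truth$startCodon == "ATG", "canonical",
                       "near_cognate"))))
  expect_identical(res$startStatus, exp)
  expect_identical(res$aligned, fates != "unaligned")
  ## ortho-peptide only ever true on a conserved start
  expect_true(all(res$startStatus[res$orthoPeptide] %in%
                    c("canonical", "near_cognate")))
  ## an identical ortholog always encodes the peptide
  smId <- synthMaf(sg$genome, tis,
                   list(ident = list(subRate = 0, gapRate = 0,
                                     fate = "keep")),
                   seed = 35L)
  resId <- conservationResults(smId$maf, "ref", tis, "ident",
                               minLenAa = 8L)
  expect_true(all(resId$orthoPeptide))
})
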