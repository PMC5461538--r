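mkGenome <- function(...) {
  s <- c(...)
  g <- Biostrings::DNAStringSet(s)
  names(g) <- if (is.null(names(s)))
    sprintf("c%d", seq_along(s)) else names(s)
  g
}

test_that("a hand-walked ORF is found and the 8-aa boundary is enforced", {
  ## ATG at 3, eight sense codons, TGA: protein MAAAAAAA
  g <- mkGenome(c1 = "AAATGGCCGCAGCTGCCGCTGCAGCTTGAAA")
  o <- sixFrameOrfs(g, startCodons = "ATG")
  expect_identical(unname(orfProtein(o)), "MAAAAAAA")
  tis <- unlist(orfTis(o))
  expect_identical(GenomicRanges::start(tis), 3L)
  ## deleting one codon leaves 7 aa: below the minimum, nothing emitted
  g7 <- mkGenome(c1 = "AAATGGCCGCAGCTGCCGCTGCAGTGAAA")
  expect_length(sixFrameOrfs(g7, startCodons = "ATG"), 0L)
})

test_that("minus-strand near-cognate ORFs are found with correct coordinates", {
  fwd <- paste0("GTG", strrep("GCA", 7L), "TAA")
  g <- mkGenome(c1 = paste0("TT", oracleRevComp(fwd), "CC"))
  o <- sixFrameOrfs(g)
  keep <- orfStartCodon(o) == "GTG" &
    as.character(GenomicRanges::strand(unlist(orfTis(o)))) == "-"
  expect_true(any(keep))
  expect_identical(unname(orfProtein(o[which(keep)])), "MAAAAAAA")
})

test_that("ORFs truncated by the contig end are not emitted", {
  ## start + sense codons but no stop before the end
  g <- mkGenome(c1 = paste0("ATG", strrep("GCA", 10L)))
  expect_length(sixFrameOrfs(g, startCodons = "ATG"), 0L)
})

test_that("six-frame enumeration equals the brute-force oracle on random contigs", {
  set.seed(71)
  for (rep in 1:25) {
    seqStr <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                    collapse = "")
    g <- mkGenome(cR = seqStr)
    got <- sixFrameOrfs(g)
    exp <- oracleSixFrame("cR", seqStr)
    expect_setequal(orfSetKeys(got),
                    orfKey(exp$contig, exp$strand, exp$gStart, exp$gEnd,
                           exp$protein))
  }
})

test_that("every emitted protein starts with M and has no stop character", {
  sg <- synthGenome(nOrfs = 10L, contigLen = 20000L, seed = 13L)
  o <- sixFrameOrfs(sg$genome)
  p <- orfProtein(o)
  expect_true(all(startsWith(p, "M")))
  expect_false(any(grepl("*", p, fixed = TRUE)))
})

test_that("adding near-cognate starts never decreases the ORF count", {
  sg <- synthGenome(nOrfs = 5L, contigLen = 10000L, seed = 17L)
  nAtg <- length(sixFrameOrfs(sg$genome, startCodons = "ATG"))
  nAll <- length(sixFrameOrfs(sg$genome))
  expect_gte(nAll, nAtg)
})

test_that("downstream-AUG children are M-suffixes sharing the parent's stop", {
  ## parent MAAAAAAAM AAAAAAA: internal ATG at codon 9
  fwd <- paste0("ATG", strrep("GCA", 7L), "ATG", strrep("GCA", 7L), "TAA")
  g <- mkGenome(c1 = fwd)
  parents <- sixFrameOrfs(g, startCodons = "ATG")
  parent <- parents[which.max(nchar(orfProtein(parents)))]
  kids <- downstreamStartOrfs(parent)
  expect_length(kids, 1L)
  expect_identical(unname(orfProtein(kids)), "MAAAAAAA")
  expect_identical(kids@parentOrfId, orfId(parent))
  ## same stop: location ends coincide
  expect_identical(GenomicRanges::end(unlist(orfLocation(kids))),
                   GenomicRanges::end(unlist(orfLocation(parent))))
  ## child tis sits 8 codons into the parent
  expect_identical(
    GenomicRanges::start(unlist(orfTis(kids))),
    GenomicRanges::start(unlist(orfTis(parent))) + 24L)
})

test_that("internal near-cognate codons do not nucleate children", {
  fwd <- paste0("ATG", strrep("GCA", 7L), "CTG", strrep("GCA", 7L), "TAA")
  g <- mkGenome(c1 = fwd)
  parents <- sixFrameOrfs(g, startCodons = "ATG")
  parent <- parents[which.max(nchar(orfProtein(parents)))]
  expect_length(downstreamStartOrfs(parent), 0L)
})

test_that("children shorter than the minimum length are suppressed", {
  fwd <- paste0("ATG", strrep("GCA", 7L), "ATG", strrep("GCA", 4L), "TAA")
  g <- mkGenome(c1 = fwd)
  parents <- sixFrameOrfs(g, startCodons = "ATG")
  parent <- parents[which.max(nchar(orfProtein(parents)))]
  expect_length(downstreamStartOrfs(parent), 0L)
})

test_that("children are protein suffixes beginning at M (property over a genome)", {
  sg <- synthGenome(nOrfs = 10L, contigLen = 20000L, seed = 29L)
  o6 <- sixFrameOrfs(sg$genome)
  kids <- downstreamStartOrfs(o6)
  if (length(kids) > 0L) {
    pp <- orfProtein(o6)
    for (k in seq_len(length(kids))) {
      parent <- pp[[kids@parentOrfId[[k]]]]
      kid <- kids@protein[[k]]
      expect_true(startsWith(kid, "M"))
      expect_identical(substr(parent, nchar(parent) - nchar(kid) + 1L,
                              nchar(parent)), kid)
    }
  }
})

test_that("model ORFs translate spliced CDS and map junction residues", {
  set.seed(41)
  seqStr <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE),
                  collapse = "")
  g <- mkGenome(cX = seqStr)
  ## junction interrupts codon 10: exon1 = 28 nt, exon2 = 32 nt
  cds <- GenomicRanges::GRanges(
    "cX", IRanges::IRanges(c(101, 201), c(128, 232)), strand = "+")
  m <- GeneModel("tx1", exons = cds, cds = cds)
  mo <- suppressWarnings(modelOrfs(list(m), g))
  if (length(mo) == 1L) {
    expWhole <- translateCds(paste0(substr(seqStr, 101, 128),
                                    substr(seqStr, 201, 232)),
                             complete = FALSE)
    expect_identical(unname(orfProtein(mo)),
                     substr(expWhole, 1L, nchar(expWhole)))
    r10 <- peptideGenomicLocation(mo, 1L, 10L, 10L)
    expect_length(r10, 2L)
    expect_identical(GenomicRanges::start(r10), c(128L, 201L))
  } else {
    ## random CDS hit an internal stop: the model must be skipped
    expect_length(mo, 0L)
  }
})

test_that("minus-strand model tis is the 3'-most genomic codon of the CDS", {
  g <- mkGenome(cX = strrep("ACGT", 200L))
  cds <- GenomicRanges::GRanges(
    "cX", IRanges::IRanges(c(301, 401), c(330, 430)), strand = "-")
  m <- GeneModel("tx2", exons = cds, cds = cds)
  mo <- modelOrfs(list(m), g)
  tis <- unlist(orfTis(mo))
  expect_identical(GenomicRanges::start(tis), 428L)
  expect_identical(GenomicRanges::end(tis), 430L)
})

test_that("single-exon models reproduce the six-frame product", {
  sg <- synthGenome(nOrfs = 12L, contigLen = 30000L, seed = 2L)
  mo <- modelOrfs(sg$models, sg$genome)
  o6 <- sixFrameOrfs(sg$genome)
  expect_true(all(orfProtein(mo) %in% orfProtein(o6)))
  expect_true(all(orfOrigin(mo) == "predicted_model"))
})
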