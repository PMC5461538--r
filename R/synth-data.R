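#' @include conservation.R
NULL

.SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                         c("TAA", "TAG", "TGA"))

#' Simulate a genome with planted ORFs and annotation
#'
#' Generates i.i.d. background sequence and plants non-overlapping ORFs
#' (start codon, stop-free body, delineating stop codon) on random
#' strands. A configurable fraction of starts is near-cognate (CTG/GTG)
#' and, with probability `contextBias`, the five bases 5' of the start
#' codon are set to A (the A-rich context favouring translation
#' initiation in plants). Each planted ORF is assigned an annotation
#' fate: wrapped in a protein-coding, transposable-element or
#' pseudogene gene model (emitted as GFF3-style models), or left
#' unannotated (a novel TIS in intergenic space). The ground truth of
#' every plant is returned for downstream precision/recall checks.
#'
#' @param nContigs,contigLen genome shape (default 1 x 100 kb).
#' @param nOrfs number of planted ORFs (default 50).
#' @param startCodonMix named probabilities over start codons
#'   (default 70% ATG, 15% CTG, 15% GTG).
#' @param contextBias probability of planting an A-rich -5..-1 context
#'   (default 0.7).
#' @param categoryMix named probabilities over annotation fates
#'   `protein_coding`, `te`, `pseudogene`, `none`.
#' @param proteinLen range of planted protein lengths in aa.
#' @param seed RNG seed; generation is byte-deterministic given it.
#' @return list with `genome` (`DNAStringSet`), `models` (list of
#'   [GeneModel-class], the annotated subset), and `truth`
#'   (`data.frame`: contig, strand, start/end of the coding span,
#'   `tisFirstBase`, `startCodon`, `protein`, `category`, `aRich`).
#' @export
synthGenome <- function(nContigs = 1L, contigLen = 100000L, nOrfs = 50L,
                        startCodonMix = c(ATG = 0.7, CTG = 0.15,
                                          GTG = 0.15),
                        contextBias = 0.7,
                        categoryMix = c(protein_coding = 0.3, te = 0.2,
                                        pseudogene = 0.1, none = 0.4),
                        proteinLen = c(10L, 25L), seed = 1L) {
  stopifnot(nContigs >= 1L, contigLen >= 200L, nOrfs >= 0L)
  .withSeed(seed, {
    contigs <- lapply(seq_len(nContigs), function(i)
      paste(sample(c("A", "C", "G", "T"), contigLen, replace = TRUE),
            collapse = ""))
    names(contigs) <- sprintf("chr%d", seq_len(nContigs))
    perContig <- diff(round(seq(0, nOrfs, length.out = nContigs + 1L)))
    truth <- list()
    models <- list()
    for (ci in seq_len(nContigs)) {
      n <- perContig[[ci]]
      if (n == 0L) next
      ## one slot per ORF: equal segments, random offset inside
      segLen <- contigLen %/% n
      maxAa <- proteinLen[[2L]]
      need <- 3L * maxAa + 3L + 12L          # codon span + margins
      if (segLen < need + 20L)
        stop("planted ORFs do not fit the contig")
      seqChars <- strsplit(contigs[[ci]], "")[[1L]]
      for (k in seq_len(n)) {
        lenAa <- sample(proteinLen[[1L]]:proteinLen[[2L]], 1L)
        span <- 3L * lenAa + 3L               # incl. stop
        lo <- (k - 1L) * segLen + 10L
        s <- lo + sample.int(segLen - span - 20L, 1L)
        std <- sample(c("+", "-"), 1L)
        startCodon <- sample(names(startCodonMix), 1L,
                             prob = startCodonMix)
        body <- sample(.SENSE_CODONS, lenAa - 1L, replace = TRUE)
        stopCodon <- sample(.STOPS, 1L)
        orfNt <- paste(c(startCodon, body, stopCodon), collapse = "")
        aRich <- stats::runif(1) < contextBias
        if (std == "+") {
          seqChars[s:(s + span - 1L)] <- strsplit(orfNt, "")[[1L]]
          if (aRich) seqChars[(s - 5L):(s - 1L)] <- "A"
          gStart <- s; gEnd <- s + span - 4L   # coding span sans stop
          tisFirst <- s
        } else {
          rc <- as.character(reverseComplement(DNAString(orfNt)))
          seqChars[s:(s + span - 1L)] <- strsplit(rc, "")[[1L]]
          ## -5..-1 in transcript space lie genomically 3' of the span
          if (aRich) seqChars[(s + span):(s + span + 4L)] <- "T"
          gStart <- s + 3L; gEnd <- s + span - 1L
          tisFirst <- s + span - 1L
        }
        category <- sample(names(categoryMix), 1L, prob = categoryMix)
        protein <- paste0("M", translateCds(
          paste(body, collapse = ""), startIsInitiator = FALSE,
          complete = TRUE))
        truth[[length(truth) + 1L]] <- data.frame(
          contig = names(contigs)[[ci]], strand = std,
          start = gStart, end = gEnd, tisFirstBase = tisFirst,
          startCodon = startCodon, protein = protein,
          category = category, aRich = aRich, stringsAsFactors = FALSE)
        if (category != "none") {
          mid <- sprintf("%s.m%d", names(contigs)[[ci]],
                         length(truth))
          exon <- GRanges(names(contigs)[[ci]],
                          IRanges(ifelse(std == "+", gStart, gStart - 3L),
                                  ifelse(std == "+", gEnd + 3L, gEnd)),
                          strand = std)
          bt <- c(protein_coding = "protein_coding",
                  te = "transposable_element",
                  pseudogene = "pseudogene")[[category]]
          models[[length(models) + 1L]] <- GeneModel(
            modelId = mid, geneId = paste0(mid, "g"), biotype = bt,
            source = "reference", exons = exon,
            cds = if (bt == "protein_coding") exon else GRanges())
        }
      }
      contigs[[ci]] <- paste(seqChars, collapse = "")
    }
    genome <- DNAStringSet(unlist(contigs))
    names(genome) <- names(contigs)
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame()
    list(genome = genome, models = models, truth = truth)
  })
}

#' Write synthetic gene models as GFF3
#'
#' Emits gene/mRNA/exon/CDS (or pseudogene / transposable-element gene)
#' features with Parent linkage, consumable by [loadGeneModels()].
#'
#' @param models list of [GeneModel-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeModelsGff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    ex <- modelExons(m)
    cds <- modelCds(m)
    ctg <- as.character(seqnames(ex))[1L]
    std <- as.character(strand(ex))[1L]
    lo <- min(start(ex)); hi <- max(end(ex))
    geneType <- switch(geneBiotype(m),
                       protein_coding = "gene",
                       transposable_element = "transposable_element_gene",
                       pseudogene = "pseudogene", "gene")
    txType <- if (geneBiotype(m) == "pseudogene")
      "pseudogenic_transcript" else "mRNA"
    gid <- m@geneId
    lines <- c(lines,
      sprintf("%s\tsynth\t%s\t%d\t%d\t.\t%s\t.\tID=%s", ctg, geneType,
              lo, hi, std, gid),
      sprintf("%s\tsynth\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s", ctg,
              txType, lo, hi, std, modelId(m), gid))
    for (j in seq_along(ex))
      lines <- c(lines, sprintf(
        "%s\tsynth\texon\t%d\t%d\t.\t%s\t.\tParent=%s", ctg,
        start(ex)[j], end(ex)[j], std, modelId(m)))
    for (j in seq_along(cds))
      lines <- c(lines, sprintf(
        "%s\tsynth\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s", ctg,
        start(cds)[j], end(cds)[j], std, modelId(m)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate multi-engine PSM tables with known error structure
#'
#' Emulates the target-decoy score mixture underlying FDR estimation:
#' correct matches are drawn from library targets with a high-scoring
#' distribution; incorrect matches split evenly between targets and
#' decoys with a null distribution. Engines observe correlated but
#' jittered scores (XCorr-like, higher-better, for the comet/crux
#' dialects; e-value-like, lower-better, for the MS-GF+ dialect) and
#' drop PSMs independently at `dropout`, creating engine-set
#' partitions. The truth labels permit exact realized-FDP computation
#' at any threshold.
#'
#' @param library a [PeptideLibrary-class].
#' @param nSpectra number of spectra (default 20000).
#' @param fracIncorrect fraction of incorrect matches in [0, 1].
#' @param dropout per-engine missing-report probability.
#' @param scoreModels list with `correctMean`, `incorrectMean`, `sd`
#'   of the latent quality scale.
#' @param seed RNG seed.
#' @return list with `tables` (named list of per-engine data.frames in
#'   the [readPsmTable()] layout) and `truth` (`data.frame`:
#'   `spectrumId`, `peptide`, `decoy`, `correct`).
#' @export
synthPsmTables <- function(library, nSpectra = 20000L,
                           fracIncorrect = 0.3, dropout = 0.15,
                           scoreModels = list(correctMean = 3.6,
                                              incorrectMean = 1.3,
                                              sd = 0.45),
                           seed = 1L) {
  if (fracIncorrect < 0 || fracIncorrect > 1)
    stop("fracIncorrect must be in [0, 1]")
  tgt <- targets(library)$sequence
  dec <- decoys(library)$sequence
  stopifnot(length(tgt) > 0L, length(dec) > 0L)
  .withSeed(seed, {
    correct <- stats::runif(nSpectra) >= fracIncorrect
    fromDecoy <- !correct & stats::runif(nSpectra) < 0.5
    peptide <- ifelse(fromDecoy, sample(dec, nSpectra, replace = TRUE),
                      sample(tgt, nSpectra, replace = TRUE))
    latent <- ifelse(correct, scoreModels$correctMean,
                     scoreModels$incorrectMean) +
      stats::rnorm(nSpectra, 0, scoreModels$sd)
    mods <- sample(c("nterm:acetyl:42.011", "nterm:d3acetyl:47.036", ""),
                   nSpectra, replace = TRUE, prob = c(0.4, 0.3, 0.3))
    spectrumId <- sprintf("spec%06d", seq_len(nSpectra))
    mkEngine <- function(engine) {
      keep <- stats::runif(nSpectra) >= dropout
      noise <- stats::rnorm(nSpectra, 0, 0.18)
      score <- if (engine == "msgflike")
        10^(-(2.5 * (latent + noise) - 1.5)) else latent + noise
      data.frame(spectrum_id = spectrumId[keep],
                 peptide = peptide[keep], mods = mods[keep],
                 score = signif(score[keep], 7L),
                 decoy = fromDecoy[keep], stringsAsFactors = FALSE)
    }
    tables <- lapply(stats::setNames(.ENGINES, .ENGINES), mkEngine)
    list(tables = tables,
         truth = data.frame(spectrumId = spectrumId, peptide = peptide,
                            decoy = fromDecoy, correct = correct,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate MAF alignments with planted start-codon fates
#'
#' For every TIS and every configured species, one alignment block
#' covering the TIS region is generated: the reference row is the
#' genome sequence, the query row a mutated copy with the planted fate
#' applied to the start codon — `keep` (unchanged), `near_cognate`
#' (ATG to CTG), `destroy` (start replaced by CCG), or `unaligned` (no
#' block emitted). Substitutions and query-side deletion gaps are
#' introduced at the configured rates outside the start codon.
#'
#' @param genome named `DNAStringSet`.
#' @param tis `GRanges` of start codons.
#' @param speciesConfigs named list; per species a list with `subRate`,
#'   `gapRate` and `fate` (single value or vector along `tis`).
#' @param refSpecies name of the reference species in block sources.
#' @param flank5,flank3 bases kept 5' and 3' of the TIS first base on
#'   the forward strand (defaults 15 / 90).
#' @param seed RNG seed.
#' @return list with `maf` (a `MafAlignment`) and `truth`
#'   (`data.frame`: tis index, species, fate).
#' @export
synthMaf <- function(genome, tis, speciesConfigs, refSpecies = "ref",
                     flank5 = 15L, flank3 = 90L, seed = 1L) {
  .withSeed(seed, {
    blocks <- list()
    truth <- list()
    for (i in seq_along(tis)) {
      ctg <- as.character(seqnames(tis))[i]
      std <- as.character(strand(tis))[i]
      L <- length(genome[[ctg]])
      ## transcript-downstream flank must cover the coding region:
      ## genomically rightward on '+', leftward on '-'
      if (std == "-") {
        lo <- max(1L, start(tis)[i] - flank3)
        hi <- min(L, end(tis)[i] + flank5)
      } else {
        lo <- max(1L, start(tis)[i] - flank5)
        hi <- min(L, end(tis)[i] + flank3)
      }
      refSeq <- as.character(subseq(genome[[ctg]], lo, hi))
      codonCols <- (start(tis)[i]:end(tis)[i]) - lo + 1L
      for (sp in names(speciesConfigs)) {
        cfg <- speciesConfigs[[sp]]
        fate <- if (length(cfg$fate) > 1L) cfg$fate[[i]] else cfg$fate
        truth[[length(truth) + 1L]] <- data.frame(
          tis = i, species = sp, fate = fate, stringsAsFactors = FALSE)
        if (fate == "unaligned") next
        q <- strsplit(refSeq, "")[[1L]]
        subHere <- stats::runif(length(q)) < (cfg$subRate %||% 0.03)
        subHere[codonCols] <- FALSE
        q[subHere] <- vapply(q[subHere], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
        ## apply the fate in transcript space
        codon <- paste(q[codonCols], collapse = "")
        if (std == "-")
          codon <- as.character(reverseComplement(DNAString(codon)))
        newCodon <- switch(fate, keep = codon,
                           near_cognate = "CTG", destroy = "CCG")
        if (std == "-")
          newCodon <- as.character(reverseComplement(DNAString(newCodon)))
        q[codonCols] <- strsplit(newCodon, "")[[1L]]
        gapHere <- stats::runif(length(q)) < (cfg$gapRate %||% 0.01)
        gapHere[codonCols] <- FALSE
        q[gapHere] <- "-"
        qText <- paste(q, collapse = "")
        qSize <- nchar(gsub("-", "", qText, fixed = TRUE))
        blocks[[length(blocks) + 1L]] <- data.frame(
          src = c(paste0(refSpecies, ".", ctg),
                  paste0(sp, ".", ctg, "_scaffold")),
          start = c(lo - 1L, 0L),
          size = c(nchar(refSeq), qSize),
          strand = c("+", "+"),
          srcSize = c(L, qSize),
          text = c(refSeq, qText), stringsAsFactors = FALSE)
      }
    }
    list(maf = structure(blocks, class = "MafAlignment"),
         truth = do.call(rbind, truth))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
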