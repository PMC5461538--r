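#' @include genome-io.R
NULL

.STOPS <- c("TAA", "TAG", "TGA")

## translate a vector of codons; stops -> "*", fuzzy -> "X"
.codonsToAa <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  aa
}

#' Enumerate six-frame ORFs with canonical and near-cognate starts
#'
#' Scans both strands of every contig in all three reading frames. Every
#' occurrence of a start codon that is followed, in frame, by a stop
#' codon within the contig defines one ORF running from that start
#' through the last sense codon (getorf-like "every start" semantics;
#' nested ORFs sharing a stop are each emitted). Near-cognate starts
#' (CUG/GUG by default) are decoded to initiator Met, so every emitted
#' protein begins with M. ORFs whose frame runs off the contig end
#' without a stop codon are not emitted.
#'
#' @param genome named `DNAStringSet` (see [loadGenome()]).
#' @param startCodons admissible start codons; default
#'   `c("ATG","CTG","GTG")`.
#' @param minAa minimum protein length in amino acids, stop excluded
#'   (default 8, i.e. a 24-nt coding span).
#' @param everyStart emit one ORF per qualifying start (default). With
#'   `FALSE`, only the 5'-most start per stop codon is kept.
#' @return an [OrfSet-class] with origin `"six_frame"`.
#' @export
sixFrameOrfs <- function(genome, startCodons = c("ATG", "CTG", "GTG"),
                         minAa = 8L, everyStart = TRUE) {
  recs <- list()
  for (ctg in names(genome)) {
    fwd <- as.character(genome[[ctg]])
    L <- nchar(fwd)
    for (std in c("+", "-")) {
      s <- if (std == "+") fwd else
        as.character(reverseComplement(DNAString(fwd)))
      for (f in 0:2) {
        nCodon <- (L - f) %/% 3L
        if (nCodon < minAa + 1L) next
        cs <- f + 3L * (seq_len(nCodon) - 1L) + 1L
        codons <- substring(s, cs, cs + 2L)
        stopIdx <- which(codons %in% .STOPS)
        startIdx <- which(codons %in% startCodons)
        if (length(stopIdx) == 0L || length(startIdx) == 0L) next
        nxt <- findInterval(startIdx, stopIdx) + 1L
        ok <- nxt <= length(stopIdx)
        startIdx <- startIdx[ok]
        stopOf <- stopIdx[nxt[ok]]
        len <- stopOf - startIdx
        ok <- len >= minAa
        startIdx <- startIdx[ok]; stopOf <- stopOf[ok]
        if (!everyStart && length(startIdx)) {
          keep <- !duplicated(stopOf)   # startIdx ascending => 5'-most first
          startIdx <- startIdx[keep]; stopOf <- stopOf[keep]
        }
        if (length(startIdx) == 0L) next
        aaStr <- paste(.codonsToAa(codons), collapse = "")
        prot <- paste0("M", substring(aaStr, startIdx + 1L, stopOf - 1L))
        sb <- cs[startIdx]             # strand coords of start codon base 1
        se <- cs[stopOf] - 1L          # strand coords of ORF last base
        if (std == "+") {
          gStart <- sb; gEnd <- se
          tStart <- sb; tEnd <- sb + 2L
        } else {
          gStart <- L - se + 1L; gEnd <- L - sb + 1L
          tStart <- L - (sb + 2L) + 1L; tEnd <- L - sb + 1L
        }
        recs[[length(recs) + 1L]] <- data.frame(
          contig = ctg, strand = std, frame = f,
          gStart = gStart, gEnd = gEnd, tStart = tStart, tEnd = tEnd,
          startCodon = substring(s, sb, sb + 2L), protein = prot,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(recs) == 0L) return(OrfSet())
  d <- do.call(rbind, recs)
  ids <- sprintf("%s:%d-%d:%s:f%d", d$contig, d$gStart, d$gEnd,
                 d$strand, d$frame)
  tis <- GRanges(d$contig, IRanges(d$tStart, d$tEnd), strand = d$strand)
  loc <- GRanges(d$contig, IRanges(d$gStart, d$gEnd), strand = d$strand)
  OrfSet(orfId = ids, origin = rep("six_frame", nrow(d)),
         startCodon = d$startCodon, frame = as.integer(d$frame),
         protein = d$protein, parentOrfId = rep("", nrow(d)),
         tis = methods::as(tis, "GRangesList"),
         location = methods::as(loc, "GRangesList"))
}

#' Truncated ORFs from downstream AUG start codons
#'
#' For each six-frame parent ORF, every internal in-frame ATG nucleates
#' a child ORF sharing the parent's stop codon. Only ATG nucleates
#' children (near-cognate codons do not re-initiate downstream).
#' Because only ATG encodes Met, internal Met residues of the parent
#' protein mark the internal in-frame ATGs exactly.
#'
#' @param orfs an [OrfSet-class] of origin `"six_frame"`.
#' @param minAa minimum child protein length (default 8).
#' @return an `OrfSet` with origin `"downstream_aug"`; empty when no
#'   internal ATG qualifies.
#' @export
downstreamStartOrfs <- function(orfs, minAa = 8L) {
  if (length(orfs) && !all(orfOrigin(orfs) == "six_frame"))
    stop("downstreamStartOrfs expects six-frame parents")
  out <- list()
  for (k in seq_len(length(orfs))) {
    prot <- orfs@protein[[k]]
    n <- nchar(prot)
    mPos <- which(strsplit(prot, "")[[1L]] == "M")
    mPos <- mPos[mPos > 1L & (n - mPos + 1L) >= minAa]
    if (length(mPos) == 0L) next
    loc <- orfs@location[[k]]
    std <- as.character(strand(loc))[1L]
    for (i in mPos) {
      off <- 3L * (i - 1L)
      if (std == "+") {
        ts <- start(loc) + off
        tisGr <- GRanges(seqnames(loc), IRanges(ts, ts + 2L), strand = std)
        locGr <- GRanges(seqnames(loc), IRanges(ts, end(loc)), strand = std)
      } else {
        te <- end(loc) - off
        tisGr <- GRanges(seqnames(loc), IRanges(te - 2L, te), strand = std)
        locGr <- GRanges(seqnames(loc), IRanges(start(loc), te),
                         strand = std)
      }
      out[[length(out) + 1L]] <- list(
        id = sprintf("%s:d%d", orfs@orfId[[k]], i),
        parent = orfs@orfId[[k]],
        frame = orfs@frame[[k]],
        protein = substr(prot, i, n),
        tis = tisGr, loc = locGr)
    }
  }
  if (length(out) == 0L) return(OrfSet())
  OrfSet(
    orfId = vapply(out, `[[`, character(1), "id"),
    origin = rep("downstream_aug", length(out)),
    startCodon = rep("ATG", length(out)),
    frame = vapply(out, `[[`, integer(1), "frame"),
    protein = vapply(out, `[[`, character(1), "protein"),
    parentOrfId = vapply(out, `[[`, character(1), "parent"),
    tis = GRangesList(lapply(out, `[[`, "tis")),
    location = GRangesList(lapply(out, `[[`, "loc")))
}

## genomic interval(s) of CDS bases ntStart..ntEnd (transcript coords)
.txSpanToGenome <- function(positions, ntStart, ntEnd) {
  pos <- positions[ntStart:ntEnd]
  brk <- c(TRUE, abs(diff(pos)) != 1L)
  grp <- cumsum(brk)
  starts <- tapply(pos, grp, min)
  ends <- tapply(pos, grp, max)
  IRanges(as.integer(starts), as.integer(ends))
}

#' ORFs of spliced gene models
#'
#' One ORF per model carrying CDS, translated with the first codon
#' decoded to initiator Met. The coding span is kept as the (possibly
#' spliced) list of genomic CDS intervals, so that peptides spanning
#' splice junctions can be placed back onto the genome (see
#' [peptideGenomicLocation()]). Models whose CDS contains an internal
#' stop codon are skipped with a warning.
#'
#' @param models list of [GeneModel-class] objects.
#' @param genome named `DNAStringSet`.
#' @return an [OrfSet-class] with origin `"predicted_model"`.
#' @export
modelOrfs <- function(models, genome) {
  out <- list()
  for (m in models) {
    if (length(modelCds(m)) == 0L) next
    nt <- splicedCdsSequence(m, genome)
    prot <- tryCatch(translateCds(nt, startIsInitiator = TRUE),
                     error = function(e) e)
    if (inherits(prot, "error")) {
      warning("skipping model ", modelId(m), ": ",
              conditionMessage(prot))
      next
    }
    if (nchar(prot) == 0L) next
    pos <- cdsGenomicPositions(m)
    cds <- modelCds(m)
    ctg <- as.character(seqnames(cds))[1L]
    std <- as.character(strand(cds))[1L]
    tisIr <- .txSpanToGenome(pos, 1L, 3L)
    out[[length(out) + 1L]] <- list(
      id = paste0("model:", modelId(m)),
      protein = prot,
      tis = GRanges(ctg, tisIr, strand = std),
      loc = GRanges(ctg, IRanges(start(cds), end(cds)), strand = std))
  }
  if (length(out) == 0L) return(OrfSet())
  OrfSet(
    orfId = vapply(out, `[[`, character(1), "id"),
    origin = rep("predicted_model", length(out)),
    startCodon = vapply(out, function(o) NA_character_, character(1)),
    frame = rep(NA_integer_, length(out)),
    protein = vapply(out, `[[`, character(1), "protein"),
    parentOrfId = rep("", length(out)),
    tis = GRangesList(lapply(out, `[[`, "tis")),
    location = GRangesList(lapply(out, `[[`, "loc")))
}

#' Genomic placement of a peptide within an ORF
#'
#' Maps residues `resStart..resEnd` of the ORF's protein back to
#' genomic interval(s); a peptide spanning a splice junction yields
#' more than one interval.
#'
#' @param orfs an [OrfSet-class].
#' @param i index (or orfId) of one ORF.
#' @param resStart,resEnd residue span (1-based, inclusive).
#' @return a `GRanges`.
#' @export
peptideGenomicLocation <- function(orfs, i, resStart, resEnd) {
  if (is.character(i)) i <- match(i, orfs@orfId)
  loc <- orfs@location[[i]]
  pos <- unlist(lapply(seq_along(loc), function(j) {
    if (as.character(strand(loc)[j]) == "-")
      seq(end(loc)[j], start(loc)[j]) else seq(start(loc)[j], end(loc)[j])
  }))
  ir <- .txSpanToGenome(pos, 3L * resStart - 2L, 3L * resEnd)
  GRanges(as.character(seqnames(loc))[1L], ir,
          strand = as.character(strand(loc))[1L])
}

#' Export ORF proteins as FASTA / TIS codons as BED
#'
#' @param orfs an [OrfSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeOrfFasta <- function(orfs, path) {
  aa <- AAStringSet(orfs@protein)
  names(aa) <- paste0(orfs@orfId, " origin=", orfs@origin,
                      " start_codon=", orfs@startCodon)
  writeXStringSet(aa, path)
  invisible(path)
}

#' @rdname writeOrfFasta
#' @export
writeTisBed <- function(orfs, path) {
  tis <- unlist(orfs@tis)
  names(tis) <- rep(orfs@orfId, lengths(orfs@tis))
  writeBed(tis, path)
}
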