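## Independent brute-force oracles used by unit and acceptance tests.
## These deliberately avoid the package's own code paths: translation
## goes through seqinr, ORF enumeration is a naive per-position codon
## walk, digestion enumerates every substring, and q-values come from
## an explicit threshold sweep.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

.oracleStops <- c("TAA", "TAG", "TGA")

oracleRevComp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = "")
}

oracleTranslate <- function(nt) {
  ## seqinr is an independent codon table implementation
  toupper(paste(seqinr::translate(strsplit(tolower(nt), "")[[1L]]),
                collapse = ""))
}

## enumerate every (strand, frame, start) by naive walking; returns a
## data.frame keyed like sixFrameOrfs output
oracleSixFrame <- function(contig, seqStr,
                           starts = c("ATG", "CTG", "GTG"), minAa = 8L) {
  out <- list()
  L <- nchar(seqStr)
  for (std in c("+", "-")) {
    s <- if (std == "+") seqStr else oracleRevComp(seqStr)
    for (f in 0:2) {
      p <- f + 1L
      while (p + 2L <= L) {
        codon <- substr(s, p, p + 2L)
        if (codon %in% starts) {
          ## walk to the next in-frame stop
          q <- p + 3L
          stopAt <- NA_integer_
          while (q + 2L <= L) {
            if (substr(s, q, q + 2L) %in% .oracleStops) {
              stopAt <- q
              break
            }
            q <- q + 3L
          }
          if (!is.na(stopAt) && (stopAt - p) / 3L >= minAa) {
            aa <- oracleTranslate(substr(s, p, stopAt - 1L))
            aa <- paste0("M", substr(aa, 2L, nchar(aa)))
            gs <- if (std == "+") p else L - (stopAt - 1L) + 1L
            ge <- if (std == "+") stopAt - 1L else L - p + 1L
            out[[length(out) + 1L]] <- data.frame(
              contig = contig, strand = std, frame = f,
              gStart = gs, gEnd = ge, protein = aa,
              stringsAsFactors = FALSE)
          }
        }
        p <- p + 3L
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(), strand = character(),
               frame = integer(), gStart = integer(), gEnd = integer(),
               protein = character(), stringsAsFactors = FALSE)
}

orfKey <- function(contig, strand, gStart, gEnd, protein)
  paste(contig, strand, gStart, gEnd, protein, sep = "|")

orfSetKeys <- function(orfs) {
  loc <- unlist(orfLocation(orfs))
  orfKey(as.character(seqnames(loc)), as.character(strand(loc)),
         start(loc), end(loc), orfProtein(orfs))
}

## quadratic digestion oracle: every substring from position 1 (and 2
## after iMet excision) is tested against the cleavage rule directly
oracleNtPeptides <- function(protein, side, residues, maxMissed,
                             lenMin = 8L, lenMax = 30L) {
  res <- strsplit(protein, "")[[1L]]
  n <- length(res)
  starts <- 1L
  if (n >= 2L && res[[2L]] %in% c("A","C","G","P","S","T","V"))
    starts <- c(1L, 2L)
  peps <- character()
  for (p in starts) {
    for (e in p:min(n, p + lenMax - 1L)) {   # longer can never pass the gate
      validEnd <- if (side == "after")
        (res[[e]] %in% residues) || e == n
      else
        (e < n && res[[e + 1L]] %in% residues) || e == n
      if (!validEnd) next
      missed <- if (side == "after")
        sum(res[p:e][-length(res[p:e])] %in% residues)
      else
        sum(res[seq(p + 1L, e)[seq_len(max(0L, e - p))]] %in% residues)
      if (missed > maxMissed) next
      pep <- paste(res[p:e], collapse = "")
      if (nchar(pep) < lenMin || nchar(pep) > lenMax) next
      if (grepl("X", pep, fixed = TRUE)) next
      peps <- c(peps, pep)
    }
  }
  unique(peps)
}

## full library oracle: digest every protein, deduplicate, subtract
## references by I/L-collapsed substring matching
oracleLibraryTargets <- function(proteins, side, residues, maxMissed,
                                 refProteins = character(),
                                 lenMin = 8L, lenMax = 30L) {
  peps <- unique(unlist(lapply(proteins, oracleNtPeptides, side = side,
                               residues = residues,
                               maxMissed = maxMissed,
                               lenMin = lenMin, lenMax = lenMax)))
  if (length(refProteins)) {
    collapse <- function(x) chartr("I", "L", x)
    refs <- collapse(refProteins)
    hit <- vapply(collapse(peps), function(p)
      any(vapply(refs, function(r) grepl(p, r, fixed = TRUE),
                 logical(1))), logical(1))
    peps <- peps[!hit]
  }
  sort(peps)
}

## threshold-sweep q-value oracle: explicit per-rank counting and
## explicit min-over-suffix, no cumsum/cummin
oracleQValues <- function(score, decoy, lowerBetter) {
  sgn <- if (lowerBetter) 1 else -1
  ord <- order(sgn * score, decoy)
  dec <- decoy[ord]
  n <- length(dec)
  fdr <- vapply(seq_len(n), function(i)
    sum(dec[seq_len(i)]) / max(1, sum(!dec[seq_len(i)])), numeric(1))
  q <- vapply(seq_len(n), function(i) min(fdr[i:n]), numeric(1))
  pmin(q, 1)
}

## truth-aware TIS GRanges of a synthGenome() result
truthTis <- function(truth) {
  GRanges(truth$contig,
          IRanges(ifelse(truth$strand == "-", truth$tisFirstBase - 2L,
                         truth$tisFirstBase),
                  ifelse(truth$strand == "-", truth$tisFirstBase,
                         truth$tisFirstBase + 2L)),
          strand = truth$strand)
}

## build a genome whose TIS contexts reproduce a prescribed integer
## percent composition at every scored position (100 sites)
contextGenomeFromPercents <- function(percents) {
  ## percents: list pos -> named vector c(A=,C=,G=,T=) summing to 100
  nSites <- 100L
  ctxs <- matrix("", nrow = nSites, ncol = 9L)
  for (j in seq_len(9L)) {
    p <- percents[[j]]
    ctxs[, j] <- sample(rep(names(p), times = p))
  }
  spacer <- strrep("C", 30L)
  body <- apply(ctxs, 1L, paste, collapse = "")
  seqStr <- paste0(spacer,
                   paste(body, collapse = spacer), spacer)
  g <- DNAStringSet(c(chrC = seqStr))
  starts <- 30L + (seq_len(nSites) - 1L) * (9L + 30L) + 6L
  tis <- GRanges("chrC", IRanges(starts, starts + 2L), strand = "+")
  list(genome = g, tis = tis)
}
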