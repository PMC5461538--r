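#' @include nt-annotation.R
NULL

.CTX_ROWS <- c("-5", "-4", "-3", "-2", "-1", "+1", "+2", "+3", "+4")
.SCORED_POS <- c("-5", "-4", "-3", "-2", "-1", "+4")

#' Extract the -5..+4 sequence context of start codons
#'
#' Returns, for each TIS, the 9-mer covering positions -5..-1 (the five
#' bases 5' of the start codon) and +1..+4 (the start codon and the
#' following base), strand-aware. Position +1 is the first base of the
#' start codon; there is no position 0. Sites whose window exceeds the
#' contig yield `NA`.
#'
#' @param genome named `DNAStringSet`.
#' @param tis `GRanges` of start codons (3 nt, stranded).
#' @return character vector of 9-mers (or `NA`).
#' @export
tisContext <- function(genome, tis) {
  ctg <- as.character(seqnames(tis))
  std <- as.character(strand(tis))
  vapply(seq_along(tis), function(i) {
    L <- length(genome[[ctg[[i]]]])
    if (std[[i]] == "-") {
      lo <- start(tis)[i] - 1L; hi <- end(tis)[i] + 5L
      if (lo < 1L || hi > L) return(NA_character_)
      as.character(reverseComplement(DNAString(
        as.character(subseq(genome[[ctg[[i]]]], lo, hi)))))
    } else {
      lo <- start(tis)[i] - 5L; hi <- end(tis)[i] + 1L
      if (lo < 1L || hi > L) return(NA_character_)
      as.character(subseq(genome[[ctg[[i]]]], lo, hi))
    }
  }, character(1))
}

#' Build the TIS nucleotide frequency matrix
#'
#' Computes percent nucleotide frequencies at positions -5..-1, +1..+4
#' around annotated start codons. TIS sharing an identical genomic
#' locus (contig, first base, strand) — e.g. alternative transcripts of
#' one gene starting at the same codon — are counted once. Sites whose
#' context window exceeds the contig are skipped with a warning.
#' Percents are rounded to the nearest integer by default, matching the
#' integer arithmetic of the summed context score.
#'
#' @param tis `GRanges` of start codons (one per transcript; redundancy
#'   is collapsed internally).
#' @param genome named `DNAStringSet`.
#' @param round round percents to integers (default `TRUE`).
#' @return a [TisFrequencyMatrix-class].
#' @export
buildFrequencyMatrix <- function(tis, genome, round = TRUE) {
  if (length(tis) == 0L) stop("empty TIS list")
  std <- as.character(strand(tis))
  firstBase <- ifelse(std == "-", end(tis), start(tis))
  key <- paste(as.character(seqnames(tis)), firstBase, std)
  tis <- tis[!duplicated(key)]
  ctx <- tisContext(genome, tis)
  if (anyNA(ctx)) {
    warning("skipping ", sum(is.na(ctx)),
            " TIS whose -5..+4 window exceeds the contig")
    ctx <- ctx[!is.na(ctx)]
  }
  if (length(ctx) == 0L) stop("no TIS with a complete context window")
  mat <- do.call(rbind, strsplit(ctx, ""))
  freq <- t(apply(mat, 2L, function(col) {
    cnt <- table(factor(col, levels = c("A", "C", "G", "T")))
    pct <- 100 * as.vector(cnt) / sum(cnt)
    if (round) round(pct) else pct
  }))
  dimnames(freq) <- list(.CTX_ROWS, c("A", "C", "G", "T"))
  new("TisFrequencyMatrix", freq = freq,
      nSites = length(ctx))
}

#' Score a TIS sequence context
#'
#' The context score sums the (percent) frequencies of the nucleotides
#' observed at positions -5..-1 and +4 of a TIS context; the start
#' codon itself (+1..+3) never contributes, so the score is invariant
#' to the start codon identity. Scores range 0-600. For proteins
#' starting with consecutive methionines, the caller passes the context
#' of the first start codon only; contexts of peptides mapping to
#' multiple genomic loci should not be scored.
#'
#' @param context a 9-mer (-5..+4; see [tisContext()]); longer strings
#'   are used through position +4.
#' @param matrix a [TisFrequencyMatrix-class].
#' @return numeric score; `NA` with a warning if an N occupies a scored
#'   position.
#' @examples
#' ## with the genome-wide frequencies printed for Arabidopsis,
#' ## scoreContext("AAAAAATGG", m) == 33 + 45 + 49 + 42 + 43 + 54
#' @export
scoreContext <- function(context, matrix) {
  if (length(context) > 1L)
    return(vapply(context, scoreContext, numeric(1), matrix = matrix,
                  USE.NAMES = FALSE))
  if (is.na(context) || nchar(context) < 9L)
    stop("context must supply positions -5..+4 (>= 9 nt)")
  nts <- strsplit(toupper(context), "")[[1L]][c(1:5, 9L)]
  if (any(!nts %in% c("A", "C", "G", "T"))) {
    warning("N (or non-ACGT) at a scored context position")
    return(NA_real_)
  }
  sum(freqMatrix(matrix)[cbind(.SCORED_POS, nts)])
}

#' Highest-scoring context of a frequency matrix
#'
#' Reconstructs the argmax context (the most frequent base at each
#' scored position, with the start codon fixed to ATG and the
#' tie-break alphabetical) and its score, which equals the sum of the
#' per-position maxima.
#'
#' @param matrix a [TisFrequencyMatrix-class].
#' @return list with `context` (9-mer) and `score`.
#' @export
bestContext <- function(matrix) {
  f <- freqMatrix(matrix)
  pick <- colnames(f)[apply(f[.SCORED_POS, , drop = FALSE], 1L,
                            which.max)]
  ctx <- paste0(paste(pick[1:5], collapse = ""), "ATG", pick[[6L]])
  list(context = ctx, score = sum(apply(f[.SCORED_POS, ], 1L, max)))
}

#' Write a frequency matrix as TSV
#'
#' @param matrix a [TisFrequencyMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFrequencyMatrix <- function(matrix, path) {
  d <- data.frame(position = rownames(freqMatrix(matrix)),
                  freqMatrix(matrix), check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
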