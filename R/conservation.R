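#' @include maf-io.R
NULL

## all nine single-substitution neighbors of ATG
.NEAR_COGNATE_ALL <- c("CTG", "GTG", "TTG", "AAG", "ACG", "AGG",
                       "ATA", "ATC", "ATT")

.mafSpecies <- function(src) sub("\\..*$", "", src)
.mafContig <- function(src) sub("^[^.]*\\.", "", src)

#' Query-species sequence aligned at a TIS
#'
#' Locates the alignment column of the TIS first base in the reference
#' row of the first block (by reference coordinate) covering it, and
#' returns the query row from that column onward with gaps removed.
#' For a minus-strand TIS the columns from the block start to the TIS
#' first base are taken and reverse-complemented, so the returned
#' sequence always reads 5'-to-3' in TIS orientation. Returns `NA`
#' when no block covers the TIS or the block lacks the reference or
#' query row.
#'
#' @param maf a `MafAlignment` (see [readMaf()]); row sources are
#'   `species.contig`.
#' @param refSpecies reference species name.
#' @param tis a length-1 `GRanges` of the start codon (stranded).
#' @param querySpecies aligned species name.
#' @return gapless nucleotide string, or `NA`.
#' @export
alignedSequenceAt <- function(maf, refSpecies, tis, querySpecies) {
  stopifnot(length(tis) == 1L)
  ctg <- as.character(seqnames(tis))
  std <- as.character(strand(tis))
  firstBase <- if (std == "-") end(tis) else start(tis)
  for (b in maf) {
    isRef <- .mafSpecies(b$src) == refSpecies & .mafContig(b$src) == ctg
    if (!any(isRef)) next
    ref <- b[which(isRef)[[1L]], ]
    if (ref$strand != "+") next          # reference rows are forward
    if (firstBase - 1L < ref$start ||
        firstBase - 1L >= ref$start + ref$size) next
    qIdx <- which(.mafSpecies(b$src) == querySpecies)
    if (length(qIdx) == 0L) return(NA_character_)
    qry <- b[qIdx[[1L]], ]
    chars <- strsplit(ref$text, "")[[1L]]
    notGap <- chars != "-"
    ## column of the TIS first base in the reference row
    offset <- firstBase - ref$start      # 1-based among ungapped bases
    col <- which(cumsum(notGap) == offset & notGap)[[1L]]
    qchars <- strsplit(qry$text, "")[[1L]]
    if (std == "-") {
      s <- paste(qchars[seq_len(col)], collapse = "")
      s <- gsub("-", "", s, fixed = TRUE)
      if (nchar(s) == 0L) return("")
      return(as.character(reverseComplement(DNAString(s))))
    } else {
      s <- paste(qchars[col:length(qchars)], collapse = "")
      return(gsub("-", "", s, fixed = TRUE))
    }
  }
  NA_character_
}

#' Start-codon status of an aligned sequence
#'
#' Classifies the first three nucleotides: ATG is canonical; any of the
#' nine single-substitution neighbors of ATG (CTG, GTG, TTG, AAG, ACG,
#' AGG, ATA, ATC, ATT) is near-cognate; anything else — including a
#' sequence shorter than 3 nt — is absent. `nearCognate = "cug_gug"`
#' restricts the near-cognate set to CTG/GTG.
#'
#' @param querySeq gapless nucleotide string (as from
#'   [alignedSequenceAt()]).
#' @param nearCognate `"all"` (default) or `"cug_gug"`.
#' @return `"canonical"`, `"near_cognate"` or `"absent"`.
#' @export
startCodonStatus <- function(querySeq, nearCognate = c("all", "cug_gug")) {
  nearCognate <- match.arg(nearCognate)
  if (is.na(querySeq) || nchar(querySeq) < 3L) return("absent")
  codon <- toupper(substr(querySeq, 1L, 3L))
  set <- if (nearCognate == "all") .NEAR_COGNATE_ALL else c("CTG", "GTG")
  if (codon == "ATG") "canonical"
  else if (codon %in% set) "near_cognate"
  else "absent"
}

#' Orthologous N-terminal peptide coding capacity
#'
#' Translates the aligned query sequence in frame 0 from the conserved
#' start codon (initiator decoded to Met) until a stop codon or the end
#' of the aligned sequence. The flag is `TRUE` iff at least `minLenAa`
#' residues are produced before any stop — the minimum being the length
#' of the identified peptide, or of its first-exon part when the
#' peptide spans a splice junction (supplied by the caller). An ORF
#' truncated at the block edge thus counts as not encoding the peptide.
#'
#' @param querySeq gapless nucleotide string starting at the conserved
#'   start codon.
#' @param minLenAa required residue count.
#' @return list with `flag` and `sequence` (the translated prefix).
#' @export
orthologousPeptide <- function(querySeq, minLenAa) {
  nCodon <- nchar(querySeq) %/% 3L
  if (nCodon == 0L) return(list(flag = FALSE, sequence = ""))
  s <- substr(querySeq, 1L, 3L * nCodon)
  aa <- translateCds(s, startIsInitiator = TRUE, complete = FALSE)
  list(flag = nchar(aa) >= minLenAa, sequence = aa)
}

#' Start-codon conservation verdict for a set of TIS
#'
#' Runs [alignedSequenceAt()], [startCodonStatus()] and
#' [orthologousPeptide()] for every TIS against one query species.
#'
#' @param maf a `MafAlignment`.
#' @param refSpecies,querySpecies species names as in the MAF sources.
#' @param tis `GRanges` of start codons.
#' @param minLenAa integer vector (recycled) of required orthologous
#'   peptide lengths.
#' @param nearCognate near-cognate codon set, see [startCodonStatus()].
#' @return `data.frame`: one row per TIS with `species`, `aligned`,
#'   `startStatus` (`canonical`/`near_cognate`/`absent`/`unaligned`),
#'   `orthoPeptide`, `orthoSequence`.
#' @export
conservationResults <- function(maf, refSpecies, tis, querySpecies,
                                minLenAa,
                                nearCognate = c("all", "cug_gug")) {
  nearCognate <- match.arg(nearCognate)
  minLenAa <- rep_len(minLenAa, length(tis))
  rows <- lapply(seq_along(tis), function(i) {
    qseq <- alignedSequenceAt(maf, refSpecies, tis[i], querySpecies)
    if (is.null(qseq) || is.na(qseq))
      return(data.frame(species = querySpecies, aligned = FALSE,
                        startStatus = "unaligned", orthoPeptide = FALSE,
                        orthoSequence = "", stringsAsFactors = FALSE))
    status <- startCodonStatus(qseq, nearCognate)
    if (status == "absent")
      return(data.frame(species = querySpecies, aligned = TRUE,
                        startStatus = "absent", orthoPeptide = FALSE,
                        orthoSequence = "", stringsAsFactors = FALSE))
    op <- orthologousPeptide(qseq, minLenAa[[i]])
    data.frame(species = querySpecies, aligned = TRUE,
               startStatus = status, orthoPeptide = op$flag,
               orthoSequence = op$sequence, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
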