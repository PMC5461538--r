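#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end strand width
#' @importFrom IRanges IRanges
NULL

#' Gene model: one transcript with exon and CDS structure
#'
#' A `GeneModel` holds one transcript-level model: its exons and coding
#' intervals as [GenomicRanges::GRanges] in genomic coordinates (1-based,
#' inclusive), a biotype, and whether the model comes from reference
#' annotation or an ab initio predictor. Exons and CDS are stored sorted
#' 5'-to-3' in transcript orientation, i.e. by decreasing genomic
#' coordinate for minus-strand models.
#'
#' @slot modelId transcript/model identifier.
#' @slot geneId parent gene identifier.
#' @slot biotype one of `"protein_coding"`, `"pseudogene"`,
#'   `"transposable_element"`, `"other"`.
#' @slot source `"reference"` or `"predicted"`.
#' @slot exons exon intervals (`GRanges`).
#' @slot cds coding intervals (`GRanges`); may be empty for non-coding
#'   models.
#' @exportClass GeneModel
setClass("GeneModel",
  representation(
    modelId = "character",
    geneId = "character",
    biotype = "character",
    source = "character",
    exons = "GRanges",
    cds = "GRanges"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  if (length(object@modelId) != 1L || !nzchar(object@modelId))
    msg <- c(msg, "modelId must be a single non-empty string")
  if (!object@biotype %in% c("protein_coding", "pseudogene",
                             "transposable_element", "other"))
    msg <- c(msg, "unknown biotype")
  if (!object@source %in% c("reference", "predicted"))
    msg <- c(msg, "source must be 'reference' or 'predicted'")
  if (length(object@exons) > 1L) {
    st <- as.character(strand(object@exons))
    ir <- IRanges(start(object@exons), end(object@exons))
    if (length(IRanges::reduce(ir)) != length(ir))
      msg <- c(msg, "exons must be non-overlapping")
    ord <- if (all(st == "-")) order(-start(object@exons)) else
      order(start(object@exons))
    if (!identical(ord, seq_along(ir)))
      msg <- c(msg, "exons must be sorted 5'->3' in transcript orientation")
  }
  if (length(msg)) msg else TRUE
})

#' Protease digestion rule
#'
#' Cleavage specificity used when extracting N-terminal peptides. The
#' four built-in specs follow the N-terminomics protocol in which lysine
#' side chains are acetylated, so trypsin behaves as ArgC (cleavage
#' after Arg only).
#'
#' @slot name one of `"argc_trypsin"`, `"gluc"`, `"chymotrypsin"`,
#'   `"aspn"`.
#' @slot cleaveSide `"after"` (C-terminal to the residue) or `"before"`.
#' @slot residues amino acids defining the cleavage site.
#' @slot maxMissed missed cleavages allowed when building the
#'   N-terminal peptide library.
#' @exportClass ProteaseSpec
setClass("ProteaseSpec",
  representation(
    name = "character",
    cleaveSide = "character",
    residues = "character",
    maxMissed = "integer"
  )
)

setValidity("ProteaseSpec", function(object) {
  msg <- character()
  if (!object@cleaveSide %in% c("after", "before"))
    msg <- c(msg, "cleaveSide must be 'after' or 'before'")
  if (length(object@residues) < 1L ||
      !all(object@residues %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
    msg <- c(msg, "residues must be standard amino acids")
  if (object@maxMissed < 0L) msg <- c(msg, "maxMissed must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Set of open reading frames
#'
#' Vector-like container for candidate translation products: six-frame
#' ORFs (canonical and near-cognate starts), downstream-AUG truncations
#' thereof, and ORFs of spliced gene models. Each element carries its
#' protein sequence (always starting with Met, since near-cognate start
#' codons are decoded to initiator Met), the start codon identity, the
#' genomic interval(s) of the coding span, and the start-codon (TIS)
#' interval.
#'
#' @slot orfId unique identifier per ORF.
#' @slot origin `"six_frame"`, `"downstream_aug"`, or
#'   `"predicted_model"`.
#' @slot startCodon the 3-mer at the TIS (e.g. `"ATG"`, `"CTG"`).
#' @slot frame reading frame 0/1/2 on the ORF's strand (`NA` for
#'   spliced models).
#' @slot protein amino-acid sequence, first residue `M`.
#' @slot parentOrfId parent ORF for downstream-AUG truncations, else
#'   `""`.
#' @slot tis `GRangesList`, the genomic footprint of the start codon
#'   (one range, or two when the codon spans a splice junction).
#' @slot location `GRangesList`, genomic interval(s) of the coding span
#'   (start codon through last sense codon).
#' @exportClass OrfSet
setClass("OrfSet",
  representation(
    orfId = "character",
    origin = "character",
    startCodon = "character",
    frame = "integer",
    protein = "character",
    parentOrfId = "character",
    tis = "GRangesList",
    location = "GRangesList"
  )
)

setValidity("OrfSet", function(object) {
  n <- length(object@orfId)
  msg <- character()
  lens <- c(length(object@origin), length(object@startCodon),
            length(object@frame), length(object@protein),
            length(object@parentOrfId), length(object@tis),
            length(object@location))
  if (!all(lens == n)) msg <- c(msg, "slot lengths differ")
  if (n > 0L) {
    if (!all(substr(object@protein, 1L, 1L) == "M"))
      msg <- c(msg, "every ORF protein must start with M")
    if (any(grepl("*", object@protein, fixed = TRUE)))
      msg <- c(msg, "ORF proteins must not contain stop characters")
    if (!all(object@origin %in% c("six_frame", "downstream_aug",
                                  "predicted_model")))
      msg <- c(msg, "unknown origin")
    if (anyDuplicated(object@orfId)) msg <- c(msg, "orfId must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Protease-specific N-terminal peptide target-decoy library
#'
#' Result of [buildLibrary()]: the non-redundant set of candidate
#' protein N-terminal peptides (8-30 aa by default) for one protease,
#' after subtraction of the reference proteome and contaminants with
#' Ile/Leu treated as equivalent, together with one reversed-sequence
#' decoy per target.
#'
#' The `peptides` slot is a [S4Vectors::DataFrame] with columns
#' `sequence`, `startPosition` (1, or 2 after initiator-Met excision),
#' `imetRemoved`, `missedCleavages`, `ctermIsProteinEnd`, `decoy`,
#' `orfIds` (`;`-joined provenance) and `tisSites` (`;`-joined
#' `contig:start-end:strand` start-codon loci).
#'
#' @slot protease the [ProteaseSpec-class] used for digestion.
#' @slot peptides `DataFrame` of targets and decoys (see Details).
#' @slot provenance list of build parameters and input digests.
#' @exportClass PeptideLibrary
setClass("PeptideLibrary",
  representation(
    protease = "ProteaseSpec",
    peptides = "DataFrame",
    provenance = "list"
  )
)

setValidity("PeptideLibrary", function(object) {
  p <- object@peptides
  need <- c("sequence", "startPosition", "imetRemoved", "missedCleavages",
            "ctermIsProteinEnd", "decoy", "orfIds", "tisSites")
  msg <- character()
  if (!all(need %in% colnames(p)))
    msg <- c(msg, paste("peptides must have columns:",
                        paste(need, collapse = ", ")))
  if (nrow(p) > 0L && all(need %in% colnames(p))) {
    tgt <- p$sequence[!p$decoy]
    dec <- p$sequence[p$decoy]
    if (anyDuplicated(tgt)) msg <- c(msg, "duplicate target sequences")
    if (length(intersect(tgt, dec)))
      msg <- c(msg, "targets and decoys must be disjoint by sequence")
  }
  if (length(msg)) msg else TRUE
})

#' TIS sequence-context frequency matrix
#'
#' Integer-percent nucleotide frequencies at positions -5..-1 and
#' +1..+4 around annotated start codons (position +1 is the first base
#' of the start codon; there is no position 0). Basis of the TIS
#' context score, which sums the percent frequencies of the bases
#' observed at -5..-1 and +4.
#'
#' @slot freq 9 x 4 integer matrix; rows `-5`..`-1`, `+1`..`+4`,
#'   columns A, C, G, T (percent, rounded to nearest integer).
#' @slot nSites number of non-redundant TIS the matrix was built from.
#' @exportClass TisFrequencyMatrix
setClass("TisFrequencyMatrix",
  representation(freq = "matrix", nSites = "integer")
)

setValidity("TisFrequencyMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@freq), c(9L, 4L)))
    msg <- c(msg, "freq must be a 9 x 4 matrix")
  if (!identical(colnames(object@freq), c("A", "C", "G", "T")))
    msg <- c(msg, "freq columns must be A, C, G, T")
  if (!identical(rownames(object@freq),
                 c("-5", "-4", "-3", "-2", "-1", "+1", "+2", "+3", "+4")))
    msg <- c(msg, "freq rows must be -5..-1, +1..+4")
  if (length(object@nSites) != 1L || object@nSites <= 0L)
    msg <- c(msg, "nSites must be a single positive count")
  rs <- rowSums(object@freq)
  if (length(msg) == 0L && !all(rs >= 99 & rs <= 101))
    msg <- c(msg, "per-position percents must sum to 100 +/- 1")
  if (length(msg)) msg else TRUE
})
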