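#' @include psm-fdr.R
NULL

#' Catalog of N-terminomics modifications
#'
#' The fixed/variable modification set of the N-terminal COFRADIC
#' protocol: free alpha-amines are blocked in vitro with trideutero
#' (13C2D3) acetyl (+47.04 Da), distinguishing them from in vivo
#' N-terminal acetylation (+42.01 Da); lysines are trideutero-acetylated
#' (fixed), cysteines carbamidomethylated (fixed), methionines oxidized
#' (fixed in the searches), and N-terminal Gln may cyclize to
#' pyroglutamate (-17.03 Da).
#'
#' @return `data.frame` with columns `name`, `delta`, `site`, `fixed`.
#' @export
modificationCatalog <- function() {
  data.frame(
    name = c("d3acetyl", "d3acetyl", "acetyl", "carbamidomethyl",
             "oxidation", "pyroglu"),
    delta = c(47.04, 47.04, 42.01, 57.02, 15.99, -17.03),
    site = c("nterm", "lysine", "nterm", "cysteine", "methionine",
             "glutamine_nterm"),
    fixed = c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

## parse a mods string: ';'-joined entries "pos:name:delta", where pos
## is "nterm" or a residue index
.parseMods <- function(mods) {
  if (is.na(mods) || !nzchar(mods)) return(NULL)
  parts <- strsplit(strsplit(mods, ";", fixed = TRUE)[[1L]], ":",
                    fixed = TRUE)
  data.frame(
    pos = vapply(parts, `[[`, character(1), 1L),
    name = vapply(parts, `[[`, character(1), 2L),
    delta = as.numeric(vapply(parts, `[[`, character(1), 3L)),
    stringsAsFactors = FALSE)
}

#' Classify the N-terminal modification state of a PSM
#'
#' An N-terminal mass delta within +/- 0.02 Da of +42.01 is in vivo
#' acetylation, of +47.04 in vitro (trideutero) acetylation, of -17.03
#' pyroglutamate formation of N-terminal Gln; a PSM without an
#' N-terminal modification is free. Two N-terminal modifications on one
#' PSM, or an out-of-catalog N-terminal delta, raise an error.
#'
#' @param mods modification string (`;`-joined `pos:name:delta` entries,
#'   `pos` = `"nterm"` or a residue index), or `""`/`NA` for none.
#' @param tolerance Da tolerance for delta matching (default 0.02).
#' @return one of `"in_vivo_acetyl"`, `"in_vitro_acetyl"`, `"pyroglu"`,
#'   `"free"`.
#' @examples
#' classifyNtModification("nterm:acetyl:42.011")   # in_vivo_acetyl
#' classifyNtModification("nterm:d3acetyl:47.036") # in_vitro_acetyl
#' classifyNtModification("")                      # free
#' @export
classifyNtModification <- function(mods, tolerance = 0.02) {
  if (length(mods) > 1L)
    return(vapply(mods, classifyNtModification, character(1),
                  tolerance = tolerance, USE.NAMES = FALSE))
  m <- .parseMods(mods)
  nt <- if (is.null(m)) m else m[m$pos == "nterm", , drop = FALSE]
  if (is.null(nt) || nrow(nt) == 0L) return("free")
  if (nrow(nt) > 1L) stop("two N-terminal modifications on one PSM")
  d <- nt$delta
  if (abs(d - 42.01) <= tolerance) return("in_vivo_acetyl")
  if (abs(d - 47.04) <= tolerance) return("in_vitro_acetyl")
  if (abs(d + 17.03) <= tolerance) return("pyroglu")
  stop("N-terminal mass delta ", d, " not in the modification catalog")
}

#' N-terminal methionine excision (NME) compliance
#'
#' Methionine aminopeptidases remove the initiator Met when residue 2
#' has a small gyration radius (Ala, Cys, Gly, Pro, Ser, Thr, Val). An
#' observed N terminus is NME-compliant iff it starts at position 2
#' with such a residue, or retains the initiator Met (position 1) when
#' residue 2 is not in that set.
#'
#' @param startPosition 1 (iMet retained) or 2 (iMet removed);
#'   vectorized.
#' @param residue2 the protein's residue at position 2 (single letter).
#' @return logical vector.
#' @examples
#' nmeCompliance(1, "D")  # TRUE: Met retained before Asp
#' nmeCompliance(2, "A")  # TRUE: Met excised before Ala
#' nmeCompliance(1, "A")  # FALSE
#' @export
nmeCompliance <- function(startPosition, residue2) {
  stopifnot(all(startPosition %in% c(1L, 2L)))
  small <- toupper(residue2) %in% .SMALL_GYRATION
  ifelse(startPosition == 2L, small, !small)
}

#' Categorize a TIS relative to gene annotation
#'
#' Overlap of the 3-nt start-codon interval with any annotated
#' transcript footprint (strand-agnostic by default: an antisense TIS
#' inside a gene span still counts as intragenic). When models of
#' several biotypes overlap, the priority is protein_coding >
#' transposable_element > pseudogene. A TIS overlapping nothing (or
#' only models of biotype `"other"`) is intergenic.
#'
#' @param tis `GRanges` of start codons (3 nt each).
#' @param models list of [GeneModel-class] objects.
#' @param strandAgnostic ignore strand when testing overlap (default
#'   `TRUE`).
#' @param footprint `"transcript"` (span of the exons, introns
#'   included; default) or `"exon"` (exon bases only).
#' @param genome optional `DNAStringSet` for bounds checking; a TIS off
#'   its contig raises an error.
#' @return character vector: `"intergenic"`,
#'   `"protein_coding_overlap"`, `"te_overlap"` or
#'   `"pseudogene_overlap"`.
#' @export
categorizeTis <- function(tis, models, strandAgnostic = TRUE,
                          footprint = c("transcript", "exon"),
                          genome = NULL) {
  footprint <- match.arg(footprint)
  if (!is.null(genome)) {
    ctg <- as.character(seqnames(tis))
    bad <- !(ctg %in% names(genome)) |
      end(tis) > BiocGenerics::width(genome)[match(ctg, names(genome))] |
      start(tis) < 1L
    if (any(bad)) stop("TIS off contig: ",
                       paste(which(bad), collapse = ", "))
  }
  spans <- lapply(models, function(m) {
    ex <- modelExons(m)
    gr <- if (footprint == "transcript") range(ex) else ex
    S4Vectors::mcols(gr)$biotype <- geneBiotype(m)
    gr
  })
  cat <- rep("intergenic", length(tis))
  if (length(spans)) {
    ann <- suppressWarnings(do.call(c, unname(spans)))
    hits <- GenomicRanges::findOverlaps(
      tis, ann, ignore.strand = strandAgnostic)
    if (length(hits)) {
      bt <- S4Vectors::mcols(ann)$biotype[S4Vectors::subjectHits(hits)]
      prio <- c(protein_coding = 1L, transposable_element = 2L,
                pseudogene = 3L, other = 4L)
      best <- tapply(prio[bt], S4Vectors::queryHits(hits), min)
      lab <- c("protein_coding_overlap", "te_overlap",
               "pseudogene_overlap", "intergenic")
      cat[as.integer(names(best))] <- lab[best]
    }
  }
  cat
}

#' Match TIS against ribosome-profiling TIS calls
#'
#' A TIS is ribo-seq supported iff a called initiation site exists on
#' the same contig and strand within `toleranceNt` of the TIS first
#' base (the 5'-most transcribed base: genomic start on `+`, genomic
#' end on `-`).
#'
#' @param tis `GRanges` of start codons.
#' @param calls `data.frame` with columns `contig`, `position` (first
#'   base of the called start codon, 1-based) and `strand`.
#' @param toleranceNt matching window in nt (default 0 = exact).
#' @return logical vector along `tis`.
#' @export
matchRiboseqTis <- function(tis, calls, toleranceNt = 0L) {
  std <- as.character(strand(tis))
  firstBase <- ifelse(std == "-", end(tis), start(tis))
  ctg <- as.character(seqnames(tis))
  vapply(seq_along(tis), function(i) {
    any(calls$contig == ctg[[i]] & calls$strand == std[[i]] &
          abs(calls$position - firstBase[[i]]) <= toleranceNt)
  }, logical(1))
}

#' Spectral-correlation threshold filter
#'
#' Novel PSMs are filtered by comparing their predicted-vs-observed
#' spectrum correlation with the median correlation of database
#' annotated N-terminal peptides in the same stratum, strata being
#' (tryptic or not, precursor charge). A novel PSM is high iff its
#' correlation is greater than or equal to the stratum median; a
#' peptide is high iff at least one of its PSMs is. A novel PSM whose
#' stratum has no annotated support gets `NA` with a warning.
#'
#' @param annotated `data.frame` of annotated-peptide PSMs with columns
#'   `corr`, `tryptic` (logical), `charge`.
#' @param novel `data.frame` of novel PSMs with columns `peptide`,
#'   `corr`, `tryptic`, `charge`.
#' @return list with `psms` (the `novel` table plus a `high` column)
#'   and `peptides` (`data.frame` of `peptide`, `ms2pipHigh`).
#' @export
ms2pipThreshold <- function(annotated, novel) {
  key <- function(d) paste(d$tryptic, d$charge)
  med <- tapply(annotated$corr, key(annotated), stats::median)
  k <- key(novel)
  m <- med[k]
  if (any(is.na(m)))
    warning("no annotated PSMs in stratum(s): ",
            paste(unique(k[is.na(m)]), collapse = ", "))
  novel$high <- as.vector(novel$corr >= m)
  pep <- tapply(novel$high, novel$peptide, function(x)
    any(x %in% TRUE))
  list(psms = novel,
       peptides = data.frame(peptide = names(pep),
                             ms2pipHigh = as.logical(pep),
                             row.names = NULL,
                             stringsAsFactors = FALSE))
}
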