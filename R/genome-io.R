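#' @include methods.R
#' @importFrom Biostrings DNAStringSet DNAString readBStringSet
#'   writeXStringSet translate reverseComplement subseq AAStringSet
#'   readAAStringSet GENETIC_CODE
#' @importFrom rtracklayer import export
NULL

## The coordinate model throughout the package is 1-based inclusive
## (GFF convention); BED export converts to 0-based half-open via
## rtracklayer.

#' Load a genome FASTA
#'
#' Reads a (multi-)FASTA nucleotide file into a named
#' [Biostrings::DNAStringSet]. Sequences are uppercased and any IUPAC
#' ambiguity code other than A/C/G/T is mapped to N. Record order is
#' preserved; sequence names are truncated at the first whitespace.
#'
#' @param path path to a FASTA file.
#' @return a `DNAStringSet`, one element per record.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgtRa"), fa)
#' loadGenome(fa)  # ACGTNA
#' @export
loadGenome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  firstLines <- readLines(path, n = 50L)
  firstLines <- firstLines[nzchar(trimws(firstLines))]
  if (length(firstLines) == 0L || !startsWith(firstLines[[1L]], ">"))
    stop("malformed FASTA (", path, "): line 1 does not start with '>'")
  raw <- readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(raw))
  if (any(nchar(seqs) == 0L)) stop("empty sequence record in ", path)
  seqs <- gsub("[^ACGT]", "N", seqs)
  out <- DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write contigs to FASTA
#'
#' @param genome a named `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenome <- function(genome, path) {
  writeXStringSet(genome, path)
  invisible(path)
}

.biotypeFromType <- function(type) {
  type <- as.character(type)
  ifelse(grepl("transposable_element", type), "transposable_element",
  ifelse(grepl("pseudogen", type), "pseudogene",
  ifelse(type %in% c("gene", "protein_coding_gene"), "protein_coding",
         "other")))
}

#' Load gene models from GFF3 or GTF
#'
#' Parses transcript-level gene models with exon/CDS structure into a
#' list of [GeneModel-class] objects. The biotype is taken from the
#' parent gene's feature type (e.g. `transposable_element_gene`,
#' `pseudogene`) or, if present, from a `biotype`/`gene_biotype`
#' attribute; unrecognized types map to `"other"` and plain `gene`
#' features to `"protein_coding"`.
#'
#' @param path GFF3 or GTF file.
#' @param dialect `"gff3"` or `"gtf"`.
#' @param source `"reference"` or `"predicted"` (e.g. ab initio gene
#'   finder output), recorded on every model.
#' @param genome optional `DNAStringSet`; when supplied, model
#'   coordinates are checked against contig bounds.
#' @return a list of `GeneModel` objects, one per transcript.
#' @export
loadGeneModels <- function(path, dialect = c("gff3", "gtf"),
                           source = "reference", genome = NULL) {
  dialect <- match.arg(dialect)
  gr <- rtracklayer::import(path, format = ifelse(dialect == "gff3",
                                                  "gff3", "gtf"))
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)

  if (dialect == "gff3") {
    id <- as.character(md$ID)
    parent <- vapply(md$Parent, function(p)
      if (length(p)) as.character(p)[[1L]] else NA_character_, character(1))
    isTx <- type %in% c("mRNA", "transcript", "pseudogenic_transcript")
    txIds <- id[isTx]
    txParent <- stats::setNames(parent[isTx], txIds)
    geneRows <- grepl("gene", type) | type == "pseudogene"
    geneType <- stats::setNames(type[geneRows], id[geneRows])
    biotypeAttr <- if ("biotype" %in% colnames(md)) md$biotype
      else if ("gene_biotype" %in% colnames(md)) md$gene_biotype else NULL
    partParent <- parent
  } else {
    txAttr <- as.character(md$transcript_id)
    geneAttr <- as.character(md$gene_id)
    isTx <- type == "transcript"
    txIds <- unique(txAttr[type %in% c("exon", "CDS", "transcript")])
    txIds <- txIds[!is.na(txIds)]
    txParent <- stats::setNames(
      geneAttr[match(txIds, txAttr)], txIds)
    geneType <- stats::setNames(type[type == "gene"],
                                geneAttr[type == "gene"])
    biotypeAttr <- if ("gene_biotype" %in% colnames(md)) md$gene_biotype
      else NULL
    partParent <- txAttr
  }

  pick <- function(what, tx) {
    sel <- type == what & !is.na(partParent) & partParent == tx
    sub <- gr[sel]
    sub[order(ifelse(as.character(strand(sub)) == "-", -1, 1) * start(sub))]
  }

  models <- vector("list", length(txIds))
  keep <- logical(length(txIds))
  for (k in seq_along(txIds)) {
    tx <- txIds[[k]]
    exons <- pick("exon", tx)
    cds <- pick("CDS", tx)
    if (length(exons) == 0L && length(cds) == 0L) next
    if (length(exons) == 0L) exons <- cds
    geneId <- txParent[[tx]]
    bt <- NA_character_
    if (!is.null(biotypeAttr)) {
      hit <- which(partParent == tx & !is.na(biotypeAttr))
      if (length(hit)) bt <- as.character(biotypeAttr[hit[[1L]]])
    }
    if (is.na(bt)) {
      gt <- if (!is.na(geneId) && geneId %in% names(geneType))
        geneType[[geneId]] else "gene"
      bt <- .biotypeFromType(gt)
    } else if (!bt %in% c("protein_coding", "pseudogene",
                          "transposable_element")) {
      bt <- "other"
    }
    if (!is.null(genome)) {
      for (piece in list(exons, cds)) {
        if (length(piece) == 0L) next
        ctg <- as.character(seqnames(piece))
        bad <- !(ctg %in% names(genome)) |
          end(piece) > BiocGenerics::width(genome)[match(ctg, names(genome))] |
          start(piece) < 1L
        if (any(bad))
          stop("model ", tx, ": coordinates outside contig bounds")
      }
    }
    models[[k]] <- GeneModel(modelId = tx,
                             geneId = if (is.na(geneId)) tx else geneId,
                             biotype = bt, source = source,
                             exons = exons, cds = cds)
    keep[[k]] <- TRUE
  }

  ## orphan CDS: CDS rows whose parent is not a known transcript
  cdsParents <- unique(partParent[type == "CDS"])
  orphans <- setdiff(cdsParents[!is.na(cdsParents)], txIds)
  if (dialect == "gff3" && length(orphans))
    warning("skipping CDS with unknown parent(s): ",
            paste(orphans, collapse = ", "))
  models[keep]
}

#' Translate a coding sequence
#'
#' Standard nuclear genetic code. A terminal stop codon (TAA/TAG/TGA)
#' is trimmed before translation. When `startIsInitiator` is `TRUE`,
#' the first codon is decoded to Met regardless of identity — canonical
#' and near-cognate start codons alike are decoded to initiator Met.
#' Codons containing N translate to X.
#'
#' @param cdsSeq nucleotide string (or `DNAString`), length divisible
#'   by 3 after trimming a terminal stop.
#' @param startIsInitiator force the first codon to Met.
#' @param complete assert that this is a complete CDS: an internal stop
#'   codon raises an error instead of truncating the translation.
#' @return amino-acid string.
#' @examples
#' translateCds("ATGGCTTAA")                  # "MA"
#' translateCds("CTGGCTTAA")                  # "MA" (near-cognate start)
#' translateCds("CTGGCTTAA", startIsInitiator = FALSE)  # "LA"
#' @export
translateCds <- function(cdsSeq, startIsInitiator = TRUE, complete = TRUE) {
  s <- toupper(as.character(cdsSeq))
  stops <- c("TAA", "TAG", "TGA")
  if (nchar(s) %% 3 == 0L && nchar(s) >= 3L &&
      substr(s, nchar(s) - 2L, nchar(s)) %in% stops)
    s <- substr(s, 1L, nchar(s) - 3L)
  if (nchar(s) %% 3 != 0L)
    stop("CDS length not divisible by 3")
  if (nchar(s) == 0L) return("")
  codons <- substring(s, seq(1L, nchar(s), by = 3L),
                      seq(3L, nchar(s), by = 3L))
  stopAt <- which(codons %in% stops)
  if (length(stopAt)) {
    if (complete)
      stop("internal stop codon at codon ", stopAt[[1L]])
    codons <- codons[seq_len(stopAt[[1L]] - 1L)]
    if (length(codons) == 0L) return("")
  }
  aa <- GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"   # ambiguity (N-containing) codons
  if (startIsInitiator) aa[[1L]] <- "M"
  paste(aa, collapse = "")
}

#' Spliced CDS nucleotide sequence of a gene model
#'
#' Concatenates the CDS pieces in transcript orientation
#' (reverse-complementing minus-strand pieces), yielding the mRNA-sense
#' coding sequence.
#'
#' @param model a [GeneModel-class] with CDS.
#' @param genome a `DNAStringSet`.
#' @return nucleotide string.
#' @export
splicedCdsSequence <- function(model, genome) {
  cds <- modelCds(model)
  if (length(cds) == 0L) stop("model ", modelId(model), " has no CDS")
  pieces <- vapply(seq_along(cds), function(i) {
    ctg <- as.character(seqnames(cds)[i])
    s <- as.character(subseq(genome[[ctg]], start(cds)[i], end(cds)[i]))
    if (as.character(strand(cds)[i]) == "-")
      s <- as.character(reverseComplement(DNAString(s)))
    s
  }, character(1))
  paste(pieces, collapse = "")
}

#' Genomic positions of a model's CDS, in transcript order
#'
#' Returns the genomic coordinate of every CDS base, ordered 5'-to-3'
#' along the transcript; residue i of the translation corresponds to
#' positions `3i-2 .. 3i` of this vector. Used to place peptides that
#' span splice junctions back onto the genome.
#'
#' @param model a [GeneModel-class] with CDS.
#' @return integer vector of genomic positions.
#' @export
cdsGenomicPositions <- function(model) {
  cds <- modelCds(model)
  unlist(lapply(seq_along(cds), function(i) {
    if (as.character(strand(cds)[i]) == "-")
      seq(end(cds)[i], start(cds)[i]) else seq(start(cds)[i], end(cds)[i])
  }))
}

#' Export genomic intervals as BED6
#'
#' Internally all coordinates are 1-based inclusive; BED output is
#' 0-based half-open (conversion handled by rtracklayer).
#'
#' @param gr a `GRanges` (names become BED names).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
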