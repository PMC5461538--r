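#' @include AllGenerics.R
NULL

## ---- GeneModel ----

#' Construct a GeneModel
#'
#' @param modelId,geneId identifiers.
#' @param biotype gene biotype (see [GeneModel-class]).
#' @param source `"reference"` or `"predicted"`.
#' @param exons,cds `GRanges` in genomic coordinates; they are re-sorted
#'   5'-to-3' in transcript orientation.
#' @return a [GeneModel-class] object.
#' @export
GeneModel <- function(modelId, geneId = modelId, biotype = "protein_coding",
                      source = "reference",
                      exons = GRanges(), cds = GRanges()) {
  sortTx <- function(gr) {
    if (length(gr) < 2L) return(gr)
    if (all(as.character(strand(gr)) == "-")) gr[order(-start(gr))]
    else gr[order(start(gr))]
  }
  new("GeneModel", modelId = modelId, geneId = geneId, biotype = biotype,
      source = source, exons = sortTx(exons), cds = sortTx(cds))
}

#' @rdname GeneModel-class
#' @export
setMethod("modelId", "GeneModel", function(x) x@modelId)

#' @rdname GeneModel-class
#' @export
setMethod("geneBiotype", "GeneModel", function(x) x@biotype)

#' @rdname GeneModel-class
#' @export
setMethod("modelExons", "GeneModel", function(x) x@exons)

#' @rdname GeneModel-class
#' @export
setMethod("modelCds", "GeneModel", function(x) x@cds)

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel", object@modelId, "(", object@biotype, ",",
      object@source, ")\n")
  cat("  exons:", length(object@exons), " cds:", length(object@cds), "\n")
})

## ---- ProteaseSpec ----

#' Built-in protease digestion rules
#'
#' Returns the cleavage rule for one of the four sequencing proteases
#' used in N-terminal COFRADIC experiments. Because lysines are
#' acetylated by the protocol, trypsin cleaves after Arg only (ArgC
#' behaviour). `maxMissed` is the missed-cleavage allowance used for
#' N-terminal peptide library construction; pass `reference = TRUE` for
#' the larger allowance used in standard (whole-proteome) searches.
#'
#' @param name one of `"argc_trypsin"`, `"gluc"`, `"chymotrypsin"`,
#'   `"aspn"`.
#' @param reference use the reference-search missed-cleavage allowance
#'   (2 for argc_trypsin, 3 otherwise) instead of the library allowance
#'   (0 for argc_trypsin, 1 otherwise).
#' @return a [ProteaseSpec-class].
#' @examples
#' proteaseSpec("argc_trypsin")
#' proteaseSpec("aspn", reference = TRUE)
#' @export
proteaseSpec <- function(name = c("argc_trypsin", "gluc", "chymotrypsin",
                                  "aspn"),
                         reference = FALSE) {
  name <- match.arg(name)
  tab <- list(
    argc_trypsin = list(side = "after", res = "R", lib = 0L, ref = 2L),
    gluc = list(side = "after", res = c("D", "E"), lib = 1L, ref = 3L),
    chymotrypsin = list(side = "after", res = c("F", "W", "Y", "L", "M"),
                        lib = 1L, ref = 3L),
    aspn = list(side = "before", res = "D", lib = 1L, ref = 3L)
  )[[name]]
  new("ProteaseSpec", name = name, cleaveSide = tab$side,
      residues = tab$res,
      maxMissed = if (reference) tab$ref else tab$lib)
}

setMethod("show", "ProteaseSpec", function(object) {
  cat("ProteaseSpec", object@name, ": cleave", object@cleaveSide,
      paste(object@residues, collapse = "/"),
      "; missed <=", object@maxMissed, "\n")
})

## ---- OrfSet ----

OrfSet <- function(orfId = character(), origin = character(),
                   startCodon = character(), frame = integer(),
                   protein = character(), parentOrfId = character(),
                   tis = GRangesList(), location = GRangesList()) {
  new("OrfSet", orfId = orfId, origin = origin, startCodon = startCodon,
      frame = frame, protein = protein, parentOrfId = parentOrfId,
      tis = tis, location = location)
}

#' @rdname OrfSet-class
#' @export
setMethod("orfId", "OrfSet", function(x) x@orfId)

#' @rdname OrfSet-class
#' @export
setMethod("orfProtein", "OrfSet", function(x)
  stats::setNames(x@protein, x@orfId))

#' @rdname OrfSet-class
#' @export
setMethod("orfOrigin", "OrfSet", function(x) x@origin)

#' @rdname OrfSet-class
#' @export
setMethod("orfStartCodon", "OrfSet", function(x) x@startCodon)

#' @rdname OrfSet-class
#' @export
setMethod("orfTis", "OrfSet", function(x)
  stats::setNames(x@tis, x@orfId))

#' @rdname OrfSet-class
#' @export
setMethod("orfLocation", "OrfSet", function(x)
  stats::setNames(x@location, x@orfId))

#' @rdname OrfSet-class
#' @export
setMethod("length", "OrfSet", function(x) length(x@orfId))

#' @rdname OrfSet-class
#' @param i index for subsetting.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "OrfSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@orfId)
  OrfSet(x@orfId[i], x@origin[i], x@startCodon[i], x@frame[i],
         x@protein[i], x@parentOrfId[i], x@tis[i], x@location[i])
})

#' Concatenate ORF sets
#'
#' @param x,... `OrfSet` objects.
#' @return a single `OrfSet`.
#' @export
setMethod("c", "OrfSet", function(x, ...) {
  all <- c(list(x), list(...))
  OrfSet(
    unlist(lapply(all, function(o) o@orfId)),
    unlist(lapply(all, function(o) o@origin)),
    unlist(lapply(all, function(o) o@startCodon)),
    unlist(lapply(all, function(o) o@frame)),
    unlist(lapply(all, function(o) o@protein)),
    unlist(lapply(all, function(o) o@parentOrfId)),
    do.call(c, lapply(all, function(o) o@tis)),
    do.call(c, lapply(all, function(o) o@location))
  )
})

setMethod("show", "OrfSet", function(object) {
  cat("OrfSet with", length(object), "ORFs\n")
  if (length(object)) {
    tab <- table(object@origin)
    cat("  origin:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
    tab <- table(object@startCodon)
    cat("  start codons:",
        paste(names(tab), tab, sep = "=", collapse = " "), "\n")
    cat("  protein length: ",
        paste(range(nchar(object@protein)), collapse = "-"), " aa\n",
        sep = "")
  }
})

## ---- PeptideLibrary ----

#' @rdname PeptideLibrary-class
#' @export
setMethod("targets", "PeptideLibrary", function(x)
  x@peptides[!x@peptides$decoy, , drop = FALSE])

#' @rdname PeptideLibrary-class
#' @export
setMethod("decoys", "PeptideLibrary", function(x)
  x@peptides[x@peptides$decoy, , drop = FALSE])

#' @rdname PeptideLibrary-class
#' @export
setMethod("proteaseOf", "PeptideLibrary", function(x) x@protease)

#' @rdname PeptideLibrary-class
#' @export
setMethod("length", "PeptideLibrary", function(x) nrow(x@peptides))

setMethod("show", "PeptideLibrary", function(object) {
  cat("PeptideLibrary (", object@protease@name, "): ",
      sum(!object@peptides$decoy), " targets + ",
      sum(object@peptides$decoy), " decoys\n", sep = "")
})

## ---- TisFrequencyMatrix ----

#' @rdname TisFrequencyMatrix-class
#' @export
setMethod("freqMatrix", "TisFrequencyMatrix", function(x) x@freq)

#' @rdname TisFrequencyMatrix-class
#' @export
setMethod("nSites", "TisFrequencyMatrix", function(x) x@nSites)

setMethod("show", "TisFrequencyMatrix", function(object) {
  cat("TisFrequencyMatrix from", object@nSites,
      "non-redundant TIS (percent)\n")
  print(object@freq)
})
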