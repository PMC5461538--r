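#' @include orf-discovery.R
NULL

.SMALL_GYRATION <- c("A", "C", "G", "P", "S", "T", "V")

## I/L are isobaric; collapse both to J for matching only
.collapseIL <- function(x) chartr("I", "L", x)

## deterministic RNG scope
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Candidate N-terminal peptides of one protein
#'
#' Applies a protease's cleavage rule to the protein N terminus: for
#' each missed-cleavage count k = 0..maxMissed, the peptide from the
#' start through the (k+1)-th cleavage boundary is emitted. If the
#' boundaries run out before the protein end, the remaining full-length
#' N-terminal peptide is emitted once, flagged `ctermIsProteinEnd` (this
#' admits short ORF products with no internal cleavage site). When
#' residue 2 has a small gyration radius (Ala, Cys, Gly, Pro, Ser, Thr
#' or Val), the same peptide set starting at position 2 — the initiator
#' Met excised — is additionally emitted. All peptides are
#' length-filtered and X-containing peptides are dropped.
#'
#' @param protein amino-acid string starting with M.
#' @param spec a [ProteaseSpec-class] (see [proteaseSpec()]).
#' @param lenMin,lenMax length bounds in amino acids (default 8-30).
#' @return `data.frame` with columns `sequence`, `startPosition`,
#'   `imetRemoved`, `missedCleavages`, `ctermIsProteinEnd`.
#' @examples
#' ntPeptidesForProtein("MAGTELLKSWVRDDK", proteaseSpec("argc_trypsin"))
#' @export
ntPeptidesForProtein <- function(protein, spec, lenMin = 8L, lenMax = 30L) {
  if (substr(protein, 1L, 1L) != "M")
    stop("protein does not start with M")
  res <- strsplit(protein, "")[[1L]]
  n <- length(res)
  rows <- list()
  starts <- 1L
  if (n >= 2L && res[[2L]] %in% .SMALL_GYRATION) starts <- c(1L, 2L)
  for (p in starts) {
    if (spec@cleaveSide == "after") {
      bnd <- which(res %in% spec@residues)
      bnd <- bnd[bnd >= p]
    } else {
      hit <- which(res %in% spec@residues)
      bnd <- hit[hit > p] - 1L
    }
    for (k in 0:spec@maxMissed) {
      if (k + 1L <= length(bnd)) {
        rows[[length(rows) + 1L]] <- list(
          sequence = paste(res[p:bnd[[k + 1L]]], collapse = ""),
          startPosition = p, imetRemoved = p == 2L,
          missedCleavages = k, ctermIsProteinEnd = bnd[[k + 1L]] == n)
      } else {
        if (length(bnd) == 0L || bnd[[length(bnd)]] != n)
          rows[[length(rows) + 1L]] <- list(
            sequence = paste(res[p:n], collapse = ""),
            startPosition = p, imetRemoved = p == 2L,
            missedCleavages = length(bnd), ctermIsProteinEnd = TRUE)
        break
      }
    }
  }
  d <- do.call(rbind, lapply(rows, as.data.frame))
  if (is.null(d)) d <- data.frame(sequence = character(),
                                  startPosition = integer(),
                                  imetRemoved = logical(),
                                  missedCleavages = integer(),
                                  ctermIsProteinEnd = logical())
  len <- nchar(d$sequence)
  d <- d[len >= lenMin & len <= lenMax &
           !grepl("X", d$sequence, fixed = TRUE), , drop = FALSE]
  rownames(d) <- NULL
  d
}

.readReferenceProteins <- function(referenceFastas) {
  unlist(lapply(referenceFastas, function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x))
      as.character(readAAStringSet(x))
    else as.character(x)
  }), use.names = FALSE)
}

#' Subtract reference proteome / contaminant matches
#'
#' A peptide is removed iff its sequence occurs as a substring of any
#' reference protein, with Ile and Leu treated as equivalent (they are
#' isobaric and indistinguishable by MS). Matching is
#' position-independent.
#'
#' @param peptides `data.frame` with a `sequence` column (as from
#'   [ntPeptidesForProtein()]).
#' @param referenceFastas character vector of FASTA paths and/or
#'   `AAStringSet`s (reference proteome, contaminants).
#' @return the retained rows of `peptides`.
#' @export
subtractReference <- function(peptides, referenceFastas) {
  refs <- .readReferenceProteins(referenceFastas)
  if (length(refs) == 0L) {
    warning("empty reference set: all peptides retained")
    return(peptides)
  }
  hay <- paste(.collapseIL(toupper(refs)), collapse = "\r")
  hit <- vapply(.collapseIL(peptides$sequence),
                function(p) grepl(p, hay, fixed = TRUE), logical(1),
                USE.NAMES = FALSE)
  peptides[!hit, , drop = FALSE]
}

.tisString <- function(gr) {
  paste(sprintf("%s:%d-%d:%s", as.character(seqnames(gr)),
                start(gr), end(gr), as.character(strand(gr))),
        collapse = "|")
}

.shuffleSeq <- function(s) {
  paste(sample(strsplit(s, "")[[1L]]), collapse = "")
}

#' Build a protease-specific N-terminal peptide target-decoy library
#'
#' Applies [ntPeptidesForProtein()] to every ORF protein, deduplicates
#' by exact sequence (merging ORF and TIS provenance), removes peptides
#' matching the reference proteome or contaminants
#' ([subtractReference()]), and creates one decoy per target by full
#' sequence reversal. A decoy whose I/L-collapsed sequence collides
#' with any target or reference substring is re-derived by seeded
#' shuffling (bounded attempts); an unresolved collision drops the
#' target-decoy pair with a warning. The build is deterministic given
#' inputs and `seed`.
#'
#' @param orfs an [OrfSet-class].
#' @param spec a [ProteaseSpec-class].
#' @param referenceFastas reference proteome / contaminant FASTAs (paths
#'   or `AAStringSet`s); empty vector retains all peptides (warning).
#' @param lenMin,lenMax peptide length bounds (default 8-30).
#' @param seed RNG seed for decoy collision resolution.
#' @return a [PeptideLibrary-class].
#' @export
buildLibrary <- function(orfs, spec, referenceFastas = character(),
                         lenMin = 8L, lenMax = 30L, seed = 1L) {
  pieces <- vector("list", length(orfs))
  for (k in seq_len(length(orfs))) {
    d <- ntPeptidesForProtein(orfs@protein[[k]], spec, lenMin, lenMax)
    if (nrow(d) == 0L) next
    d$orfIds <- orfs@orfId[[k]]
    d$tisSites <- .tisString(orfs@tis[[k]])
    pieces[[k]] <- d
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  emptyPep <- S4Vectors::DataFrame(
    sequence = character(), startPosition = integer(),
    imetRemoved = logical(), missedCleavages = integer(),
    ctermIsProteinEnd = logical(), decoy = logical(),
    orfIds = character(), tisSites = character())
  prov <- list(protease = spec@name, lenMin = lenMin, lenMax = lenMax,
               seed = seed, nOrfs = length(orfs),
               decoyScheme = "peptide-level reversal, seeded reshuffle on collision")
  if (length(pieces) == 0L)
    return(new("PeptideLibrary", protease = spec, peptides = emptyPep,
               provenance = prov))
  all <- do.call(rbind, pieces)
  ## deduplicate by exact sequence; deterministic representative
  all <- all[order(all$sequence, all$startPosition, all$imetRemoved,
                   all$missedCleavages), , drop = FALSE]
  first <- !duplicated(all$sequence)
  merged <- all[first, , drop = FALSE]
  merged$orfIds <- vapply(split(all$orfIds, all$sequence), function(x)
    paste(sort(unique(x)), collapse = ";"), character(1))[merged$sequence]
  merged$tisSites <- vapply(split(all$tisSites, all$sequence), function(x)
    paste(sort(unique(x)), collapse = ";"), character(1))[merged$sequence]
  if (length(referenceFastas))
    merged <- subtractReference(merged, referenceFastas)
  if (nrow(merged) == 0L)
    return(new("PeptideLibrary", protease = spec, peptides = emptyPep,
               provenance = prov))
  ## decoys by reversal, seeded reshuffle on collision
  refs <- .readReferenceProteins(referenceFastas)
  hay <- paste(.collapseIL(toupper(refs)), collapse = "\r")
  tgtSet <- .collapseIL(merged$sequence)
  collides <- function(s) {
    sj <- .collapseIL(s)
    sj %in% tgtSet || (nchar(hay) > 0L && grepl(sj, hay, fixed = TRUE))
  }
  dropIdx <- integer()
  decoySeq <- .withSeed(seed, vapply(seq_len(nrow(merged)), function(i) {
    s <- paste(rev(strsplit(merged$sequence[[i]], "")[[1L]]),
               collapse = "")
    tries <- 0L
    while (collides(s) && tries < 25L) {
      s <- .shuffleSeq(s)
      tries <- tries + 1L
    }
    if (collides(s)) NA_character_ else s
  }, character(1)))
  bad <- is.na(decoySeq) | duplicated(decoySeq)
  if (any(bad)) {
    warning("dropping ", sum(bad),
            " target-decoy pair(s): unresolved decoy collision")
    merged <- merged[!bad, , drop = FALSE]
    decoySeq <- decoySeq[!bad]
  }
  tgt <- S4Vectors::DataFrame(
    sequence = merged$sequence, startPosition = merged$startPosition,
    imetRemoved = merged$imetRemoved,
    missedCleavages = merged$missedCleavages,
    ctermIsProteinEnd = merged$ctermIsProteinEnd,
    decoy = FALSE, orfIds = merged$orfIds, tisSites = merged$tisSites)
  dec <- tgt
  dec$sequence <- decoySeq
  dec$decoy <- TRUE
  dec$orfIds <- ""
  dec$tisSites <- ""
  new("PeptideLibrary", protease = spec, peptides = rbind(tgt, dec),
      provenance = prov)
}

#' Write / read a peptide library as a target-decoy FASTA
#'
#' One record per target and decoy; decoy ids carry the `rev_` prefix
#' (mirroring reversed-sequence decoy naming). The header encodes
#' protease, start position, initiator-Met status, missed cleavages,
#' C-terminal flag and the start-codon locus list
#' (`contig:start-end:strand`, `;`-joined; `|`-joined when one codon
#' spans a splice junction), so that [readLibraryFasta()] reproduces
#' the library.
#'
#' @param library a [PeptideLibrary-class].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeLibraryFasta <- function(library, path) {
  p <- library@peptides
  ids <- sprintf("%sNtLib_%06d", ifelse(p$decoy, "rev_", ""),
                 seq_len(nrow(p)))
  hdr <- sprintf(
    "%s protease=%s pos=%d imet=%d mc=%d cterm=%d decoy=%d orfs=%s tis=%s",
    ids, library@protease@name, p$startPosition, as.integer(p$imetRemoved),
    p$missedCleavages, as.integer(p$ctermIsProteinEnd),
    as.integer(p$decoy),
    ifelse(nzchar(p$orfIds), p$orfIds, "."),
    ifelse(nzchar(p$tisSites), p$tisSites, "."))
  aa <- AAStringSet(p$sequence)
  names(aa) <- hdr
  writeXStringSet(aa, path)
  invisible(path)
}

#' @rdname writeLibraryFasta
#' @return for `readLibraryFasta`, the reconstructed
#'   [PeptideLibrary-class].
#' @export
readLibraryFasta <- function(path) {
  aa <- readAAStringSet(path)
  hdr <- names(aa)
  field <- function(key) sub(paste0(".*", key, "=(\\S+).*"), "\\1", hdr)
  protease <- unique(field("protease"))
  stopifnot(length(protease) == 1L)
  p <- S4Vectors::DataFrame(
    sequence = as.character(aa),
    startPosition = as.integer(field("pos")),
    imetRemoved = field("imet") == "1",
    missedCleavages = as.integer(field("mc")),
    ctermIsProteinEnd = field("cterm") == "1",
    decoy = field("decoy") == "1",
    orfIds = ifelse(field("orfs") == ".", "", field("orfs")),
    tisSites = ifelse(field("tis") == ".", "", field("tis")))
  new("PeptideLibrary", protease = proteaseSpec(protease), peptides = p,
      provenance = list(source = path))
}

#' Validate a peptide library against its construction rules
#'
#' Re-checks, over the whole library, the length bounds, X-freedom,
#' start-position/initiator-Met consistency, the protease C-terminal
#' rule (unless the peptide ends at the protein C terminus), and —
#' when references are given — that no target is an I/L-collapsed
#' substring of any reference protein.
#'
#' @param library a [PeptideLibrary-class].
#' @param referenceFastas optional references to re-check subtraction.
#' @param lenMin,lenMax expected length bounds.
#' @return `TRUE` invisibly; stops with a message on the first
#'   violation.
#' @export
validateLibrary <- function(library, referenceFastas = character(),
                            lenMin = 8L, lenMax = 30L) {
  p <- targets(library)
  spec <- library@protease
  len <- nchar(p$sequence)
  if (any(len < lenMin | len > lenMax))
    stop("length bound violated")
  if (any(grepl("X", p$sequence, fixed = TRUE)))
    stop("X-containing peptide in library")
  startsM <- substr(p$sequence, 1L, 1L) == "M"
  if (!all(startsM == (p$startPosition == 1L)))
    stop("startPosition/M consistency violated")
  if (!all(p$imetRemoved == (p$startPosition == 2L)))
    stop("imetRemoved flag inconsistent")
  notEnd <- !p$ctermIsProteinEnd
  if (any(notEnd)) {
    if (spec@cleaveSide == "after") {
      last <- substr(p$sequence[notEnd], nchar(p$sequence[notEnd]),
                     nchar(p$sequence[notEnd]))
      if (!all(last %in% spec@residues))
        stop("C-terminal residue violates cleave-after rule")
    }
    ## cleave-before: the rule concerns the residue following the
    ## peptide in the parent protein, not stored in the library
  }
  if (length(referenceFastas)) {
    kept <- subtractReference(as.data.frame(p), referenceFastas)
    if (nrow(kept) != nrow(p))
      stop("reference subtraction post-condition violated")
  }
  invisible(TRUE)
}
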