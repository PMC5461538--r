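#' @include ntpep-library.R
NULL

.ENGINES <- c("cometlike", "cruxlike", "msgflike")

.psmKey <- function(d) paste(d$spectrumId, d$peptide, d$mods, sep = "\r")

#' Read a per-engine PSM table
#'
#' Reads a tab-separated PSM export and normalizes it to the package's
#' column set, applying the engine dialect: XCorr-style scores
#' (`cometlike`, `cruxlike`) are higher-better, e-value-style scores
#' (`msgflike`) lower-better. Column aliases are accepted
#' (`spectrum`/`scan` for `spectrum_id`, `sequence` for `peptide`,
#' `modifications` for `mods`, `xcorr`/`evalue` for `score`,
#' `label`/`is_decoy` for `decoy`). Only the best hit per spectrum is
#' kept (direction-aware; target preferred on ties) — engines' internal
#' ranks beyond 1 are discarded at ingest.
#'
#' @param path TSV file with one PSM per row.
#' @param engine `"cometlike"`, `"cruxlike"` or `"msgflike"`.
#' @return `data.frame` with columns `spectrumId`, `peptide`, `mods`,
#'   `score`, `decoy`, `engine`, `scoreDirection`.
#' @export
readPsmTable <- function(path, engine = .ENGINES) {
  engine <- match.arg(engine)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  normalizePsms(d, engine)
}

#' @rdname readPsmTable
#' @param d an in-memory `data.frame` in any accepted dialect.
#' @export
normalizePsms <- function(d, engine = .ENGINES) {
  engine <- match.arg(engine)
  names(d) <- tolower(names(d))
  alias <- function(...) {
    for (a in c(...)) if (a %in% names(d)) return(d[[a]])
    NULL
  }
  out <- data.frame(
    spectrumId = as.character(alias("spectrum_id", "spectrum", "scan")),
    peptide = as.character(alias("peptide", "sequence")),
    mods = { m <- alias("mods", "modifications"); if (is.null(m)) ""
             else ifelse(is.na(m), "", as.character(m)) },
    score = as.numeric(alias("score", "xcorr", "evalue", "e_value")),
    decoy = { dd <- alias("decoy", "is_decoy", "label")
              if (is.logical(dd)) dd
              else dd %in% c("1", "TRUE", "true", "decoy", "-1") },
    stringsAsFactors = FALSE)
  if (any(is.na(out$score)) || any(!is.finite(out$score)))
    stop("non-finite PSM scores")
  out$engine <- engine
  out$scoreDirection <- ifelse(engine == "msgflike", "lower_better",
                               "higher_better")
  ## best hit per spectrum
  sgn <- ifelse(out$scoreDirection == "lower_better", 1, -1)
  out <- out[order(out$spectrumId, sgn * out$score, out$decoy), ,
             drop = FALSE]
  out <- out[!duplicated(out$spectrumId), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## core target-decoy FDR -> q-value -> interpolated FDR score, applied
## to PSMs already holding a ranking-compatible raw score
.fdrScoreCore <- function(score, decoy, lowerBetter) {
  n <- length(score)
  sgn <- if (lowerBetter) 1 else -1
  ord <- order(sgn * score, decoy)   # decoys after targets on ties
  dec <- decoy[ord]
  fdr <- cumsum(dec) / pmax(1, cumsum(!dec))
  q <- rev(cummin(rev(fdr)))
  q <- pmin(q, 1)
  ## anchors at decoy ranks carrying the (monotone) q-value there;
  ## linear interpolation in rank from a virtual (0, 0) anchor,
  ## constant after the last anchor
  anchorX <- which(dec)
  fs <- numeric(n)
  if (length(anchorX)) {
    anchorY <- q[anchorX]
    ## tie-average rank per raw-score tie group as interpolation query
    x <- stats::ave(seq_len(n), score[ord], FUN = mean)
    fs <- stats::approx(x = c(0, anchorX), y = c(0, anchorY), xout = x,
                        method = "linear", rule = 2)$y
  }
  list(order = ord, q = q, fdrScore = fs)
}

#' Engine-independent FDR scores for one engine's PSMs
#'
#' Ranks one engine's PSMs by raw score (direction-aware, decoys after
#' targets on ties), estimates the target-decoy FDR at each rank
#' (#decoys / max(1, #targets)), converts it to a q-value (the minimum
#' FDR at or beyond each rank, a non-decreasing step function), and
#' assigns each PSM an FDR score by linear interpolation in rank
#' between the decoy anchors — 0 before the first anchor, the last
#' anchor's q-value beyond it. The FDR score is a search-engine
#' independent score in [0, 1] usable across engines.
#'
#' @param psms `data.frame` as from [readPsmTable()] (one best PSM per
#'   spectrum).
#' @return the input with columns `fdrScore` and `qValue` appended,
#'   in ranking order.
#' @export
engineFdrScores <- function(psms) {
  if (nrow(psms) == 0L) {
    psms$fdrScore <- numeric(0)
    psms$qValue <- numeric(0)
    return(psms)
  }
  lowerBetter <- psms$scoreDirection[[1L]] == "lower_better"
  res <- .fdrScoreCore(psms$score, psms$decoy, lowerBetter)
  out <- psms[res$order, , drop = FALSE]
  out$qValue <- res$q
  out$fdrScore <- res$fdrScore
  rownames(out) <- NULL
  out
}

#' Combine engine FDR scores by engine-agreement partition
#'
#' Keys (spectrum, peptide, modifications) are matched across engines.
#' Each key's combined raw score is the arithmetic mean of its engine
#' FDR scores. Within each engine-set partition (the subset of engines
#' that reported the key), PSMs are re-ranked by combined raw score
#' (ascending, decoys after targets on ties) and the same
#' FDR/q-value/interpolation procedure is re-applied using the
#' target/decoy labels, yielding the combined FDR score. This corrects
#' for PSM sets shared between engines that contain no decoy hits of
#' their own. The combined FDR score is defined only for keys reported
#' by at least two engines.
#'
#' @param scoredList named list of per-engine outputs of
#'   [engineFdrScores()].
#' @return `data.frame`, one row per key: `spectrumId`, `peptide`,
#'   `mods`, `decoy`, `engineSet` (`;`-joined), `nEngines`,
#'   `minEngineFdr`, `combinedRaw`, `combinedFdrScore` (`NA` for
#'   single-engine keys), `smallPartition` (partition held < 10 PSMs).
#' @export
combinedFdr <- function(scoredList) {
  stopifnot(length(scoredList) >= 1L, !is.null(names(scoredList)))
  rows <- do.call(rbind, lapply(names(scoredList), function(e) {
    d <- scoredList[[e]]
    data.frame(spectrumId = d$spectrumId, peptide = d$peptide,
               mods = d$mods, decoy = d$decoy, engine = e,
               fdrScore = d$fdrScore, stringsAsFactors = FALSE)
  }))
  key <- .psmKey(rows)
  byKey <- split(seq_len(nrow(rows)), key)
  firstIdx <- vapply(byKey, `[[`, integer(1), 1L)
  decoyOk <- vapply(byKey, function(ii)
    length(unique(rows$decoy[ii])) == 1L, logical(1))
  if (!all(decoyOk))
    stop("inconsistent target/decoy flag across engines for key(s): ",
         paste(utils::head(names(byKey)[!decoyOk], 3L), collapse = ", "))
  out <- data.frame(
    spectrumId = rows$spectrumId[firstIdx],
    peptide = rows$peptide[firstIdx],
    mods = rows$mods[firstIdx],
    decoy = rows$decoy[firstIdx],
    engineSet = vapply(byKey, function(ii)
      paste(sort(rows$engine[ii]), collapse = ";"), character(1)),
    nEngines = lengths(byKey),
    minEngineFdr = vapply(byKey, function(ii)
      min(rows$fdrScore[ii]), numeric(1)),
    combinedRaw = vapply(byKey, function(ii)
      mean(rows$fdrScore[ii]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$combinedFdrScore <- NA_real_
  out$smallPartition <- FALSE
  for (part in unique(out$engineSet[out$nEngines >= 2L])) {
    ii <- which(out$engineSet == part)
    res <- .fdrScoreCore(out$combinedRaw[ii], out$decoy[ii],
                         lowerBetter = TRUE)
    out$combinedFdrScore[ii[res$order]] <- res$fdrScore
    out$smallPartition[ii] <- length(ii) < 10L
  }
  out
}

#' Multistage PSM filter
#'
#' Reference stage: a PSM is retained iff (its minimum engine FDR score
#' is at most 0.01 OR its combined FDR score is at most 0.01) AND at
#' least one engine gave it an FDR score of at most 0.05 (the safeguard
#' against combined partitions without decoys). Novel stage: the same,
#' plus the requirement of identification by at least two engines.
#'
#' The spectrum ids NOT retained at the reference stage — the
#' unidentified spectra handed to the novel search — are attached as
#' `attr(result, "unidentifiedSpectra")`.
#'
#' @param psms `data.frame` from [combinedFdr()].
#' @param stage `"reference"` or `"novel"`.
#' @param fdrMax main threshold (default 0.01).
#' @param safeguardMax per-engine safeguard threshold (default 0.05).
#' @return the retained rows; see Details for the attached attribute.
#' @export
multistageFilter <- function(psms, stage = c("reference", "novel"),
                             fdrMax = 0.01, safeguardMax = 0.05) {
  stage <- match.arg(stage)
  combOk <- !is.na(psms$combinedFdrScore) & psms$combinedFdrScore <= fdrMax
  keep <- (psms$minEngineFdr <= fdrMax | combOk) &
    psms$minEngineFdr <= safeguardMax
  if (stage == "novel") keep <- keep & psms$nEngines >= 2L
  refKeep <- (psms$minEngineFdr <= fdrMax | combOk) &
    psms$minEngineFdr <= safeguardMax
  out <- psms[keep, , drop = FALSE]
  attr(out, "unidentifiedSpectra") <-
    setdiff(unique(psms$spectrumId), unique(psms$spectrumId[refKeep]))
  out
}
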