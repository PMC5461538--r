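#' @include tis-context.R
NULL

## Minimal MAF (multiple alignment format) block reader/writer.
## A block is a data.frame of 's' rows: src ("species.contig"), start
## (0-based on the source strand), size (ungapped), strand, srcSize,
## text (gapped). The installed genomics stack offers no MAF parser,
## so this one is local to the package.

#' Read a MAF whole-genome alignment
#'
#' @param path MAF file.
#' @return object of class `MafAlignment`: a list of blocks, each a
#'   `data.frame` with columns `src`, `start`, `size`, `strand`,
#'   `srcSize`, `text`.
#' @export
readMaf <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && nrow(cur) > 0L) {
      if (length(unique(nchar(cur$text))) != 1L)
        stop("MAF block rows have unequal gapped lengths")
      blocks[[length(blocks) + 1L]] <<- cur
    }
    cur <<- NULL
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      flush()
      cur <- data.frame(src = character(), start = integer(),
                        size = integer(), strand = character(),
                        srcSize = integer(), text = character(),
                        stringsAsFactors = FALSE)
    } else if (startsWith(ln, "s ")) {
      f <- strsplit(trimws(ln), "\\s+")[[1L]]
      if (length(f) < 7L) stop("malformed MAF 's' line: ", ln)
      row <- data.frame(src = f[[2L]], start = as.integer(f[[3L]]),
                        size = as.integer(f[[4L]]), strand = f[[5L]],
                        srcSize = as.integer(f[[6L]]), text = f[[7L]],
                        stringsAsFactors = FALSE)
      ungapped <- nchar(gsub("-", "", row$text, fixed = TRUE))
      if (ungapped != row$size)
        stop("MAF row size mismatch for ", row$src)
      cur <- rbind(cur, row)
    }
  }
  flush()
  structure(blocks, class = "MafAlignment")
}

#' @rdname readMaf
#' @param maf a `MafAlignment`.
#' @param path output path.
#' @export
writeMaf <- function(maf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in maf) {
    writeLines("a score=0", con)
    writeLines(sprintf("s %s %d %d %s %d %s", b$src, b$start, b$size,
                       b$strand, b$srcSize, b$text), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @export
print.MafAlignment <- function(x, ...) {
  cat("MafAlignment with", length(x), "blocks\n")
  invisible(x)
}
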