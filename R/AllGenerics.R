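#' @include AllClasses.R
NULL

#' @rdname OrfSet-class
#' @param x,object an `OrfSet`.
#' @export
setGeneric("orfId", function(x) standardGeneric("orfId"))

#' @rdname OrfSet-class
#' @export
setGeneric("orfProtein", function(x) standardGeneric("orfProtein"))

#' @rdname OrfSet-class
#' @export
setGeneric("orfOrigin", function(x) standardGeneric("orfOrigin"))

#' @rdname OrfSet-class
#' @export
setGeneric("orfStartCodon", function(x) standardGeneric("orfStartCodon"))

#' @rdname OrfSet-class
#' @export
setGeneric("orfTis", function(x) standardGeneric("orfTis"))

#' @rdname OrfSet-class
#' @export
setGeneric("orfLocation", function(x) standardGeneric("orfLocation"))

#' @rdname PeptideLibrary-class
#' @param x a `PeptideLibrary`.
#' @export
setGeneric("targets", function(x) standardGeneric("targets"))

#' @rdname PeptideLibrary-class
#' @export
setGeneric("decoys", function(x) standardGeneric("decoys"))

#' @rdname PeptideLibrary-class
#' @export
setGeneric("proteaseOf", function(x) standardGeneric("proteaseOf"))

#' @rdname TisFrequencyMatrix-class
#' @param x a `TisFrequencyMatrix`.
#' @export
setGeneric("freqMatrix", function(x) standardGeneric("freqMatrix"))

#' @rdname TisFrequencyMatrix-class
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname GeneModel-class
#' @param x a `GeneModel`.
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))

#' @rdname GeneModel-class
#' @export
setGeneric("geneBiotype", function(x) standardGeneric("geneBiotype"))

#' @rdname GeneModel-class
#' @export
setGeneric("modelExons", function(x) standardGeneric("modelExons"))

#' @rdname GeneModel-class
#' @export
setGeneric("modelCds", function(x) standardGeneric("modelCds"))
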