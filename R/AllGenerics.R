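#' @rdname TranscriptModel-accessors
#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))

#' @rdname TranscriptModel-accessors
#' @export
setGeneric("geneName", function(x) standardGeneric("geneName"))

#' @rdname TranscriptModel-accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname TranscriptModel-accessors
#' @export
setGeneric("chrom", function(x) standardGeneric("chrom"))

#' @rdname TranscriptModel-accessors
#' @export
setGeneric("txStrand", function(x) standardGeneric("txStrand"))

#' @rdname TranscriptModel-accessors
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))

#' @rdname TranscriptModel-accessors
#' @export
setGeneric("mrnaLength", function(x) standardGeneric("mrnaLength"))

#' @rdname TranscriptModel-accessors
#' @export
setGeneric("isCoding", function(x) standardGeneric("isCoding"))

#' @rdname TranscriptModel-accessors
#' @export
setGeneric("cdsStartGenomic", function(x) standardGeneric("cdsStartGenomic"))

#' @rdname TranscriptModel-accessors
#' @export
setGeneric("cdsEndGenomic", function(x) standardGeneric("cdsEndGenomic"))

#' @rdname CohortLandscape-accessors
#' @export
setGeneric("patients", function(x) standardGeneric("patients"))

#' @rdname CohortLandscape-accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname ExclusivityResult-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname ExclusivityResult-accessors
#' @export
setGeneric("observedCoverage", function(x) standardGeneric("observedCoverage"))
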