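#' @rdname HaplotypePanel-accessors
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))

#' @rdname HaplotypePanel-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname HaplotypePanel-accessors
#' @export
setGeneric("haplotypeSample", function(x) standardGeneric("haplotypeSample"))

#' @rdname HaplotypePanel-accessors
#' @export
setGeneric("haplotypeSide", function(x) standardGeneric("haplotypeSide"))

#' @rdname HaplotypePanel-accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname HaplotypePanel-accessors
#' @export
setGeneric("populations<-", function(x, value) standardGeneric("populations<-"))

#' @rdname HaplotypePanel-accessors
#' @export
setGeneric("altFreq", function(x) standardGeneric("altFreq"))

#' @rdname RearrangedChromosome-accessors
#' @export
setGeneric("placements", function(x) standardGeneric("placements"))

#' @rdname RearrangedChromosome-accessors
#' @export
setGeneric("fragmentGaps", function(x) standardGeneric("fragmentGaps"))

#' @rdname RearrangedChromosome-accessors
#' @export
setGeneric("spanCoverage", function(x) standardGeneric("spanCoverage"))

#' @rdname jigsaw-accessors
#' @export
setGeneric("nAboveThreshold", function(x) standardGeneric("nAboveThreshold"))

#' @rdname jigsaw-accessors
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))

#' @rdname jigsaw-accessors
#' @export
setGeneric("reconstructionStatus", function(x) standardGeneric("reconstructionStatus"))
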