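#' @export
setGeneric("genotypes", function(x, ...) standardGeneric("genotypes"))

#' @export
setGeneric("phenotype", function(x, ...) standardGeneric("phenotype"))

#' @export
setGeneric("truthManifest",
    function(x, ...) standardGeneric("truthManifest"))

#' @export
setGeneric("truthManifest<-",
    function(x, value) standardGeneric("truthManifest<-"))

#' @export
setGeneric("featureIds", function(x, ...) standardGeneric("featureIds"))

#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @export
setGeneric("causalIds", function(x, ...) standardGeneric("causalIds"))

#' @export
setGeneric("effectStructure",
    function(x, ...) standardGeneric("effectStructure"))

#' @export
setGeneric("featureScores",
    function(x, ...) standardGeneric("featureScores"))

#' @export
setGeneric("rankedFeatures",
    function(x, ...) standardGeneric("rankedFeatures"))

#' @export
setGeneric("selectorMethod",
    function(x, ...) standardGeneric("selectorMethod"))

#' @export
setGeneric("penetranceTable",
    function(x, ...) standardGeneric("penetranceTable"))

#' @export
setGeneric("prevalence", function(x, ...) standardGeneric("prevalence"))

#' @export
setGeneric("heritability", function(x, ...) standardGeneric("heritability"))

#' @export
setGeneric("unionSet", function(x, ...) standardGeneric("unionSet"))

#' @export
setGeneric("intersectionSet",
    function(x, ...) standardGeneric("intersectionSet"))

#' @export
setGeneric("perMethodSets",
    function(x, ...) standardGeneric("perMethodSets"))
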