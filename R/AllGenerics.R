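#' @rdname accessors
#' @export
setGeneric("netGrowthRate", function(x) standardGeneric("netGrowthRate"))

#' @rdname accessors
#' @export
setGeneric("carryingCapacity", function(x) standardGeneric("carryingCapacity"))

#' @rdname accessors
#' @export
setGeneric("rateConstants", function(x) standardGeneric("rateConstants"))

#' @rdname accessors
#' @export
setGeneric("aggregationNumber",
           function(x) standardGeneric("aggregationNumber"))

#' @rdname accessors
#' @export
setGeneric("speciesAbundances",
           function(x) standardGeneric("speciesAbundances"))

#' @rdname accessors
#' @export
setGeneric("oligomerPool", function(x) standardGeneric("oligomerPool"))

#' @rdname accessors
#' @export
setGeneric("timeIndex", function(x) standardGeneric("timeIndex"))

#' @rdname accessors
#' @export
setGeneric("finalState", function(x) standardGeneric("finalState"))

#' @rdname accessors
#' @export
setGeneric("equilibriumKind", function(x) standardGeneric("equilibriumKind"))

#' @rdname accessors
#' @export
setGeneric("spectralRadius", function(x) standardGeneric("spectralRadius"))

#' @rdname accessors
#' @export
setGeneric("classification", function(x) standardGeneric("classification"))

#' @rdname accessors
#' @export
setGeneric("gershgorinCertified",
           function(x) standardGeneric("gershgorinCertified"))

#' @rdname accessors
#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))
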