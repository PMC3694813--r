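#' @rdname Trajectory-class
#' @param x a package object
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Trajectory-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname Trajectory-class
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname Trajectory-class
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname EssentialSpace-class
#' @param x a package object
#' @export
setGeneric("images", function(x) standardGeneric("images"))

#' @rdname EssentialSpace-class
#' @export
setGeneric("essentialCount", function(x) standardGeneric("essentialCount"))

#' @rdname EssentialSpace-class
#' @export
setGeneric("varianceFraction", function(x) standardGeneric("varianceFraction"))

#' @rdname CorrelationMap-class
#' @param x a package object
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname DomainPartition-class
#' @param x a package object
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))

#' @rdname DomainPartition-class
#' @export
setGeneric("domainLabels", function(x) standardGeneric("domainLabels"))
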