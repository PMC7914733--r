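#' @rdname FloorLayout-class
#' @param object a capgait object
#' @export
setGeneric("nModules", function(object) standardGeneric("nModules"))

#' @rdname FloorLayout-class
#' @export
setGeneric("nFields", function(object) standardGeneric("nFields"))

#' @rdname FloorLayout-class
#' @export
setGeneric("fieldTable", function(object) standardGeneric("fieldTable"))

#' @rdname FloorLayout-class
#' @export
setGeneric("moduleTable", function(object) standardGeneric("moduleTable"))

#' @rdname SensorState-class
#' @param object a capgait object
#' @export
setGeneric("stateEntries", function(object) standardGeneric("stateEntries"))

#' @rdname StateSeries-class
#' @param object a capgait object
#' @export
setGeneric("stateTimes", function(object) standardGeneric("stateTimes"))

#' @rdname StateSeries-class
#' @export
setGeneric("capacitanceMatrix", function(object) standardGeneric("capacitanceMatrix"))

#' @rdname StateSeries-class
#' @param i integer index of the state to extract
#' @export
setGeneric("stateAt", function(object, i) standardGeneric("stateAt"))

#' @rdname GridSpec-class
#' @param object a capgait object
#' @export
setGeneric("gridPoints", function(object) standardGeneric("gridPoints"))

#' @rdname GridSpec-class
#' @export
setGeneric("gridSize", function(object) standardGeneric("gridSize"))

#' @rdname LocalGrid-class
#' @param object a capgait object
#' @export
setGeneric("unroll", function(object) standardGeneric("unroll"))
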