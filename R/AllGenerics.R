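#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: photon counts, bin
#' width, identifiers and labels of a trace; change points, segment and level
#' summaries of a segmentation; family and parameters of a duration fit.
#'
#' @param object an S4 object from this package.
#' @return The slot value; see the class documentation for units.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("binTime", function(object) standardGeneric("binTime"))

#' @rdname accessors
#' @export
setGeneric("moleculeId", function(object) standardGeneric("moleculeId"))

#' @rdname accessors
#' @export
setGeneric("classLabel", function(object) standardGeneric("classLabel"))

#' @rdname accessors
#' @export
setGeneric("changePoints", function(object) standardGeneric("changePoints"))

#' @rdname accessors
#' @export
setGeneric("segmentMeans", function(object) standardGeneric("segmentMeans"))

#' @rdname accessors
#' @export
setGeneric("levelMeans", function(object) standardGeneric("levelMeans"))

#' @rdname accessors
#' @export
setGeneric("nIntensities", function(object) standardGeneric("nIntensities"))

#' @rdname accessors
#' @export
setGeneric("onLevels", function(object) standardGeneric("onLevels"))

#' @rdname accessors
#' @export
setGeneric("fitFamily", function(object) standardGeneric("fitFamily"))

#' @rdname accessors
#' @export
setGeneric("fitParams", function(object) standardGeneric("fitParams"))

#' @rdname accessors
#' @export
setGeneric("ksStat", function(object) standardGeneric("ksStat"))

#' @rdname accessors
#' @export
setGeneric("segments", function(object) standardGeneric("segments"))

#' @rdname accessors
#' @export
setGeneric("intervals", function(object) standardGeneric("intervals"))
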