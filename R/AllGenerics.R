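#' @rdname FCCohort-class
#' @param object,x an object.
#' @export
setGeneric("subjectIDs", function(x) standardGeneric("subjectIDs"))

#' @rdname FCCohort-class
#' @export
setGeneric("groups", function(x) standardGeneric("groups"))

#' @rdname FCCohort-class
#' @param id subject identifier.
#' @export
setGeneric("timeCourses", function(x, id) standardGeneric("timeCourses"))

#' @rdname FCCohort-class
#' @export
setGeneric("trueStates", function(x) standardGeneric("trueStates"))

#' @rdname slidingWindowFC
#' @export
setGeneric("slidingWindowFC",
    function(x, width = 25L, step = 2L, ...) standardGeneric("slidingWindowFC"))

#' @rdname StateModel-class
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' @rdname StateModel-class
#' @export
setGeneric("stateCentroids", function(x) standardGeneric("stateCentroids"))

#' @rdname StateModel-class
#' @export
setGeneric("sseCurve", function(x) standardGeneric("sseCurve"))

#' @rdname StateModel-class
#' @export
setGeneric("trainingLabels", function(x) standardGeneric("trainingLabels"))

#' @rdname fitStateModel
#' @export
setGeneric("fitStateModel",
    function(x, k, seed = 1L, nInit = 20L, maxIter = 300L)
        standardGeneric("fitStateModel"))

#' @rdname selectStatesElbow
#' @export
setGeneric("selectStatesElbow",
    function(x, kMin = 2L, kMax = 9L, seed = 1L, nInit = 20L, maxIter = 300L)
        standardGeneric("selectStatesElbow"))

#' @rdname assignStates
#' @export
setGeneric("assignStates",
    function(model, features) standardGeneric("assignStates"))

#' @rdname StateOccupancy-class
#' @export
setGeneric("occupancyMatrix", function(x) standardGeneric("occupancyMatrix"))

#' @rdname NetworkAtlas-class
#' @export
setGeneric("networkNames", function(x) standardGeneric("networkNames"))

#' @rdname NetworkAtlas-class
#' @export
setGeneric("networkMasks", function(x) standardGeneric("networkMasks"))
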