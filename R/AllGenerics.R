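# Accessor generics. Slot access from user code is discouraged; these are the
# supported surface.

#' @rdname accessors
#' @param x an eatr object.
#' @export
setGeneric("timeGrid", function(x) standardGeneric("timeGrid"))
#' @rdname accessors
#' @export
setGeneric("biasValues", function(x) standardGeneric("biasValues"))
#' @rdname accessors
#' @export
setGeneric("cvValues", function(x) standardGeneric("cvValues"))
#' @rdname accessors
#' @export
setGeneric("transitionTime", function(x) standardGeneric("transitionTime"))
#' @rdname accessors
#' @export
setGeneric("tMax", function(x) standardGeneric("tMax"))
#' @rdname accessors
#' @export
setGeneric("runLabel", function(x) standardGeneric("runLabel"))
#' @rdname accessors
#' @export
setGeneric("isCensored", function(x) standardGeneric("isCensored"))
#' @rdname accessors
#' @export
setGeneric("trajectories", function(x) standardGeneric("trajectories"))
#' @rdname accessors
#' @export
setGeneric("thermalBeta", function(x) standardGeneric("thermalBeta"))
#' @rdname accessors
#' @export
setGeneric("iterationLabel", function(x) standardGeneric("iterationLabel"))
#' @rdname accessors
#' @export
setGeneric("transitionTimes", function(x) standardGeneric("transitionTimes"))
#' @rdname accessors
#' @export
setGeneric("nTransitions", function(x) standardGeneric("nTransitions"))
#' @rdname accessors
#' @export
setGeneric("nCensored", function(x) standardGeneric("nCensored"))
#' @rdname accessors
#' @export
setGeneric("alphaValues", function(x) standardGeneric("alphaValues"))
#' @rdname accessors
#' @export
setGeneric("tauAccel", function(x) standardGeneric("tauAccel"))
#' @rdname accessors
#' @export
setGeneric("vMax", function(x) standardGeneric("vMax"))
#' @rdname accessors
#' @export
setGeneric("meanTauAccel", function(x) standardGeneric("meanTauAccel"))
#' @rdname accessors
#' @export
setGeneric("meanAlpha", function(x) standardGeneric("meanAlpha"))
#' @rdname accessors
#' @export
setGeneric("covTauAlpha", function(x) standardGeneric("covTauAlpha"))
#' @rdname accessors
#' @export
setGeneric("tauMFPT", function(x) standardGeneric("tauMFPT"))
#' @rdname accessors
#' @export
setGeneric("perRunTable", function(x) standardGeneric("perRunTable"))
#' @rdname accessors
#' @export
setGeneric("gammaHat", function(x) standardGeneric("gammaHat"))
#' @rdname accessors
#' @export
setGeneric("k0Hat", function(x) standardGeneric("k0Hat"))
#' @rdname accessors
#' @export
setGeneric("gammaCI", function(x) standardGeneric("gammaCI"))
#' @rdname accessors
#' @export
setGeneric("k0CI", function(x) standardGeneric("k0CI"))
#' @rdname accessors
#' @export
setGeneric("fitLogLik", function(x) standardGeneric("fitLogLik"))
#' @rdname accessors
#' @export
setGeneric("gammaProfile", function(x) standardGeneric("gammaProfile"))
#' @rdname accessors
#' @export
setGeneric("boundaryHit", function(x) standardGeneric("boundaryHit"))
#' @rdname accessors
#' @export
setGeneric("gammaIdentifiable", function(x) standardGeneric("gammaIdentifiable"))
#' @rdname accessors
#' @export
setGeneric("modelSpec", function(x) standardGeneric("modelSpec"))
#' @rdname accessors
#' @export
setGeneric("tauHat", function(x) standardGeneric("tauHat"))
#' @rdname accessors
#' @export
setGeneric("ksStat", function(x) standardGeneric("ksStat"))
#' @rdname accessors
#' @export
setGeneric("ksPValue", function(x) standardGeneric("ksPValue"))
#' @rdname accessors
#' @export
setGeneric("rescaledTimes", function(x) standardGeneric("rescaledTimes"))
#' @rdname accessors
#' @export
setGeneric("gammaPred1", function(x) standardGeneric("gammaPred1"))
#' @rdname accessors
#' @export
setGeneric("gammaPred2", function(x) standardGeneric("gammaPred2"))
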