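#' @name accessors
#' @title Accessors for exonforge classes
#' @description Slot accessors for the S4 containers: cleaning-ledger
#'   counts, candidate-set regions and ledger, probeset probes, and GGE
#'   decomposition components.
#' @param object an exonforge S4 object.
NULL

#' @rdname accessors
#' @export
setGeneric("inputCount", function(object) standardGeneric("inputCount"))
#' @rdname accessors
#' @export
setGeneric("keptCount", function(object) standardGeneric("keptCount"))
#' @rdname accessors
#' @export
setGeneric("removedCounts", function(object) standardGeneric("removedCounts"))
#' @rdname accessors
#' @export
setGeneric("regions", function(object) standardGeneric("regions"))
#' @rdname accessors
#' @export
setGeneric("ledger", function(object) standardGeneric("ledger"))
#' @rdname accessors
#' @export
setGeneric("estStatus", function(object) standardGeneric("estStatus"))
#' @rdname accessors
#' @export
setGeneric("probes", function(object) standardGeneric("probes"))
#' @rdname accessors
#' @export
setGeneric("isComplete", function(object) standardGeneric("isComplete"))
#' @rdname accessors
#' @export
setGeneric("genotypeScores", function(object) standardGeneric("genotypeScores"))
#' @rdname accessors
#' @export
setGeneric("environmentLoadings",
           function(object) standardGeneric("environmentLoadings"))
#' @rdname accessors
#' @export
setGeneric("singularValues", function(object) standardGeneric("singularValues"))
#' @rdname accessors
#' @export
setGeneric("varianceExplained",
           function(object) standardGeneric("varianceExplained"))

#' @rdname accessors
#' @export
setMethod("inputCount", "CleaningLedger", function(object) object@inputCount)
#' @rdname accessors
#' @export
setMethod("keptCount", "CleaningLedger", function(object) object@keptCount)
#' @rdname accessors
#' @export
setMethod("removedCounts", "CleaningLedger", function(object) object@removed)

#' @rdname accessors
#' @export
setMethod("regions", "CandidateSet", function(object) object@regions)
#' @rdname accessors
#' @export
setMethod("ledger", "CandidateSet", function(object) object@ledger)
#' @rdname accessors
#' @export
setMethod("estStatus", "CandidateSet", function(object) object@estStatus)

#' @rdname accessors
#' @export
setMethod("probes", "ProbeSet", function(object) object@probes)
#' @rdname accessors
#' @export
setMethod("isComplete", "ProbeSet", function(object) object@complete)

#' @rdname accessors
#' @export
setMethod("genotypeScores", "GGEResult", function(object) object@genotypeScores)
#' @rdname accessors
#' @export
setMethod("environmentLoadings", "GGEResult",
          function(object) object@environmentLoadings)
#' @rdname accessors
#' @export
setMethod("singularValues", "GGEResult", function(object) object@singularValues)
#' @rdname accessors
#' @export
setMethod("varianceExplained", "GGEResult",
          function(object) object@varianceExplained)
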