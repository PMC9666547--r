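## Accessor generics.  Slots are never touched directly by user code.

#' @name accessors
#' @title Accessors for dimernet data classes
#'
#' @description Small read-only accessors for the S4 containers: structure
#'   chain/residue information, alignment rows and organism tags, PSSM scores,
#'   feature tensors, distogram probability volumes, contact scores and
#'   ground-truth contacts.
#'
#' @param x an object of the documented class.
#' @param i residue position (for `atomCoords`).
#' @return The corresponding slot value; see each method.
NULL

#' @rdname accessors
#' @export
setGeneric("chainId", function(x) standardGeneric("chainId"))
#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))
#' @rdname accessors
#' @export
setGeneric("residueIndices", function(x) standardGeneric("residueIndices"))
#' @rdname accessors
#' @export
setGeneric("residueNames", function(x) standardGeneric("residueNames"))
#' @rdname accessors
#' @export
setGeneric("atomCoords", function(x, i) standardGeneric("atomCoords"))
#' @rdname accessors
#' @export
setGeneric("msaRows", function(x) standardGeneric("msaRows"))
#' @rdname accessors
#' @export
setGeneric("msaWidth", function(x) standardGeneric("msaWidth"))
#' @rdname accessors
#' @export
setGeneric("organismTags", function(x) standardGeneric("organismTags"))
#' @rdname accessors
#' @export
setGeneric("pssmScores", function(x) standardGeneric("pssmScores"))
#' @rdname accessors
#' @export
setGeneric("contactEntries", function(x) standardGeneric("contactEntries"))
#' @rdname accessors
#' @export
setGeneric("featureTensor", function(x) standardGeneric("featureTensor"))
#' @rdname accessors
#' @export
setGeneric("dimerKind", function(x) standardGeneric("dimerKind"))
#' @rdname accessors
#' @export
setGeneric("chainLengths", function(x) standardGeneric("chainLengths"))
#' @rdname accessors
#' @export
setGeneric("heavyProbs", function(x) standardGeneric("heavyProbs"))
#' @rdname accessors
#' @export
setGeneric("cbProbs", function(x) standardGeneric("cbProbs"))
#' @rdname accessors
#' @export
setGeneric("contactScores", function(x) standardGeneric("contactScores"))
#' @rdname accessors
#' @export
setGeneric("truthContacts", function(x) standardGeneric("truthContacts"))
#' @rdname accessors
#' @export
setGeneric("truthDistances", function(x) standardGeneric("truthDistances"))

#' @rdname accessors
setMethod("chainId", "MonomerStructure", function(x) x@chainId)
#' @rdname accessors
setMethod("nResidues", "MonomerStructure", function(x) length(x@atoms))
#' @rdname accessors
setMethod("residueIndices", "MonomerStructure", function(x) x@residueIndex)
#' @rdname accessors
setMethod("residueNames", "MonomerStructure", function(x) x@residueName)
#' @rdname accessors
setMethod("atomCoords", "MonomerStructure", function(x, i) x@atoms[[i]])

#' @rdname accessors
setMethod("msaRows", "MultipleSequenceAlignment", function(x) x@sequences)
#' @rdname accessors
setMethod("msaWidth", "MultipleSequenceAlignment",
          function(x) nchar(x@sequences[1L]))
#' @rdname accessors
setMethod("organismTags", "MultipleSequenceAlignment", function(x) x@organism)
#' @rdname accessors
setMethod("msaRows", "PairedMSA", function(x) x@sequences)
#' @rdname accessors
setMethod("msaWidth", "PairedMSA", function(x) nchar(x@sequences[1L]))

#' @rdname accessors
setMethod("pssmScores", "PositionSpecificScoringMatrix", function(x) x@scores)
#' @rdname accessors
setMethod("contactEntries", "RankedContactList", function(x) x@entries)

#' @rdname accessors
setMethod("featureTensor", "FeatureStack", function(x) x@tensor)
#' @rdname accessors
setMethod("dimerKind", "FeatureStack", function(x) x@dimerKind)
#' @rdname accessors
setMethod("chainLengths", "FeatureStack", function(x) x@lengths)
#' @rdname accessors
setMethod("chainLengths", "DistogramPrediction", function(x) x@lengths)

#' @rdname accessors
setMethod("heavyProbs", "DistogramPrediction", function(x) x@heavyProbs)
#' @rdname accessors
setMethod("cbProbs", "DistogramPrediction", function(x) x@cbProbs)

#' @rdname accessors
setMethod("contactScores", "ContactScoreMap", function(x) x@scores)
#' @rdname accessors
setMethod("truthContacts", "ContactGroundTruth", function(x) x@contacts)
#' @rdname accessors
setMethod("truthDistances", "ContactGroundTruth",
          function(x) x@minHeavyDistances)
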