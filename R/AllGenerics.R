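#' Accessor generics
#'
#' Small accessor family for the package's S4 result classes: slot access
#' stays behind functions so internal representations can evolve.
#'
#' @param x an object of the documented class.
#' @return The accessed component; see the method sections.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("directions", function(x) standardGeneric("directions"))
#' @rdname accessors
#' @export
setGeneric("ratesMatrix", function(x) standardGeneric("ratesMatrix"))
#' @rdname accessors
#' @export
setGeneric("standardizedValues",
           function(x) standardGeneric("standardizedValues"))
#' @rdname accessors
#' @export
setGeneric("tolranking", function(x) standardGeneric("tolranking"))
#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("indicatorWeights", function(x) standardGeneric("indicatorWeights"))
#' @rdname accessors
#' @export
setGeneric("closeness", function(x) standardGeneric("closeness"))
#' @rdname accessors
#' @export
setGeneric("degTable", function(x) standardGeneric("degTable"))
#' @rdname accessors
#' @export
setGeneric("degCalls", function(x) standardGeneric("degCalls"))
#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))
#' @rdname accessors
#' @export
setGeneric("eigengenes", function(x) standardGeneric("eigengenes"))
#' @rdname accessors
#' @export
setGeneric("kWithin", function(x) standardGeneric("kWithin"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("traitMatrix", function(x) standardGeneric("traitMatrix"))
#' @rdname accessors
#' @export
setGeneric("panelData", function(x) standardGeneric("panelData"))

#' @rdname accessors
#' @export
setMethod("directions", "PhysioPanel", function(x) x@directions)
#' @rdname accessors
#' @export
setMethod("directions", "ChangeRateMatrix", function(x) x@directions)
#' @rdname accessors
#' @export
setMethod("directions", "StandardizedMatrix", function(x) x@directions)
#' @rdname accessors
#' @export
setMethod("panelData", "PhysioPanel", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("ratesMatrix", "ChangeRateMatrix", function(x) x@rates)
#' @rdname accessors
#' @export
setMethod("standardizedValues", "StandardizedMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("tolranking", "MembershipResult", function(x) x@ranking)
#' @rdname accessors
#' @export
setMethod("tolranking", "TopsisResult", function(x) x@ranking)
#' @rdname accessors
#' @export
setMethod("scores", "MembershipResult", function(x) x@u)
#' @rdname accessors
#' @export
setMethod("scores", "TopsisResult", function(x) x@closeness)
#' @rdname accessors
#' @export
setMethod("indicatorWeights", "MembershipResult", function(x) x@weights)
#' @rdname accessors
#' @export
setMethod("indicatorWeights", "TopsisResult", function(x) x@weights)
#' @rdname accessors
#' @export
setMethod("closeness", "TopsisResult", function(x) x@closeness)
#' @rdname accessors
#' @export
setMethod("degTable", "DEGSet", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("degCalls", "DEGSet", function(x) {
  tb <- x@table
  tb$gene[tb$call != "ns"]
})
#' @rdname accessors
#' @export
setMethod("moduleLabels", "ModuleAssignment", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("eigengenes", "ModuleAssignment", function(x) x@eigengenes)
#' @rdname accessors
#' @export
setMethod("kWithin", "ModuleAssignment", function(x) x@kWithin)
#' @rdname accessors
#' @export
setMethod("groundTruth", "PhysioPanel", function(x) x@groundTruth)
#' @rdname accessors
#' @export
setMethod("groundTruth", "ExpressionStudy",
          function(x) S4Vectors::metadata(x)$groundTruth)
#' @rdname accessors
#' @export
setMethod("traitMatrix", "ExpressionStudy",
          function(x) S4Vectors::metadata(x)$traits)

#' @describeIn accessors abundance matrix of an ExpressionStudy
#' @export
fpkm <- function(x) SummarizedExperiment::assay(x, "fpkm")

setMethod("show", "PhysioPanel", function(object) {
  df <- object@data
  cat(sprintf("PhysioPanel: %d cultivars x %d indicators, %d records\n",
              length(unique(df$cultivar)), length(unique(df$indicator)),
              nrow(df)))
  neg <- names(object@directions)[object@directions == "negative"]
  cat("  negative indicators:",
      if (length(neg)) paste(neg, collapse = ", ") else "none", "\n")
  if (length(object@groundTruth))
    cat("  simulated (ground truth attached)\n")
})

setMethod("show", "ChangeRateMatrix", function(object) {
  cat(sprintf("ChangeRateMatrix: %d cultivars x %d indicators\n",
              nrow(object@rates), ncol(object@rates)))
})

setMethod("show", "MembershipResult", function(object) {
  cat("MembershipResult (higher = more tolerant)\n  ranking:",
      paste(object@ranking, collapse = " > "), "\n")
})

setMethod("show", "TopsisResult", function(object) {
  cat("TopsisResult (relative closeness C_i, higher = more tolerant)\n",
      " ranking:", paste(object@ranking, collapse = " > "), "\n")
})

setMethod("show", "ConcordanceResult", function(object) {
  cat(sprintf(
    "ConcordanceResult: Spearman rho = %.4f, Kendall tau = %.4f, %d reversals\n",
    object@spearmanRho, object@kendallTau, object@nReversals))
})

setMethod("show", "DEGSet", function(object) {
  tb <- object@table
  cat(sprintf(
    "DEGSet [%s]: %d genes, %d up / %d down (FC > %.2g, FDR < %.2g)\n",
    paste(object@group, collapse = ", "), nrow(tb), sum(tb$call == "up"),
    sum(tb$call == "down"), object@fcThreshold, object@fdrThreshold))
})

setMethod("show", "ModuleAssignment", function(object) {
  lab <- object@labels
  nm <- sum(unique(lab) != 0L)
  cat(sprintf("ModuleAssignment: %d genes in %d modules (%d unassigned)\n",
              length(lab), nm, sum(lab == 0L)))
})
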