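#' @import methods
#' @importFrom stats cor cor.test prcomp p.adjust pt sd shapiro.test t.test
#'   rnorm runif quantile hclust cutree as.dist var setNames complete.cases
#' @importFrom utils head read.delim write.table
NULL

.CONDITIONS <- c("control", "stress")
.DIRECTIONS <- c("positive", "negative")

#' PhysioPanel: replicated physiological measurements under control and stress
#'
#' Tidy container for a physiological indicator panel: one value per
#' (cultivar, indicator, condition, replicate). Each indicator carries a
#' direction label: \code{"positive"} indicators signal tolerance when their
#' stress-induced change rate is large (e.g. SOD, CAT, POD, SP, AOC);
#' \code{"negative"} indicators signal damage (e.g. MDA, Pro).
#'
#' @slot data data.frame with columns \code{cultivar}, \code{indicator},
#'   \code{condition} (\code{"control"}/\code{"stress"}), \code{replicate},
#'   \code{value}.
#' @slot directions named character vector mapping every indicator to
#'   \code{"positive"} or \code{"negative"}.
#' @slot groundTruth list; for simulated panels, the planted tolerance
#'   gradient and effect slopes (empty for real data).
#'
#' @seealso [PhysioPanel()], [simulatePhysioPanel()], [changeRates()]
#' @export
setClass("PhysioPanel",
  representation(data = "data.frame", directions = "character",
                 groundTruth = "list"),
  prototype(groundTruth = list()))

setValidity("PhysioPanel", function(object) {
  df <- object@data
  need <- c("cultivar", "indicator", "condition", "replicate", "value")
  if (!all(need %in% names(df)))
    return(paste("data must have columns:", paste(need, collapse = ", ")))
  if (!all(df$condition %in% .CONDITIONS))
    return("condition must be 'control' or 'stress'")
  if (!all(is.finite(df$value))) return("values must be finite")
  ind <- unique(df$indicator)
  if (!all(ind %in% names(object@directions)))
    return("directions must cover every indicator")
  if (!all(object@directions %in% .DIRECTIONS))
    return("directions must be 'positive' or 'negative'")
  cnt <- table(df$cultivar, df$indicator, df$condition)
  if (any(cnt < 2))
    return("every (cultivar, indicator, condition) cell needs >= 2 replicates")
  # identical indicator set across cultivars
  byCv <- tapply(df$indicator, df$cultivar, function(x) sort(unique(x)))
  if (length(unique(vapply(byCv, paste, character(1), collapse = "\r"))) != 1L)
    return("indicator set must be identical across cultivars")
  TRUE
})

#' ChangeRateMatrix: cultivar-by-indicator relative change rates
#'
#' Houses x_ij = (mean stress - mean control) / mean control for cultivar i
#' and indicator j, with the per-indicator direction labels carried along.
#'
#' @slot rates numeric matrix, rows = cultivars, columns = indicators.
#' @slot directions named character vector over the columns.
#' @seealso [changeRates()], [standardizeRates()]
#' @export
setClass("ChangeRateMatrix",
  representation(rates = "matrix", directions = "character"))

setValidity("ChangeRateMatrix", function(object) {
  x <- object@rates
  if (!is.numeric(x) || anyNA(x)) return("rates must be numeric with no NA")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    return("rates must have cultivar rownames and indicator colnames")
  if (!all(colnames(x) %in% names(object@directions)))
    return("directions must cover every indicator column")
  if (!all(object@directions[colnames(x)] %in% .DIRECTIONS))
    return("directions must be 'positive' or 'negative'")
  TRUE
})

#' StandardizedMatrix: direction-aware min-max standardized decision matrix
#'
#' Entries lie in [0, 1]; for positive indicators 1 marks the cultivar with
#' the largest change rate, for negative indicators 1 marks the smallest.
#' Constant columns (no information) are filled with 0.5 and flagged.
#'
#' @slot values numeric matrix in [0,1], cultivars x indicators.
#' @slot directions named character vector over the columns.
#' @slot constantColumns character vector of columns that were constant in
#'   the source change-rate matrix.
#' @seealso [standardizeRates()], [membershipScores()], [topsis()]
#' @export
setClass("StandardizedMatrix",
  representation(values = "matrix", directions = "character",
                 constantColumns = "character"),
  prototype(constantColumns = character()))

setValidity("StandardizedMatrix", function(object) {
  v <- object@values
  if (anyNA(v)) return("values must have no NA")
  if (min(v) < -1e-12 || max(v) > 1 + 1e-12)
    return("values must lie in [0, 1]")
  TRUE
})

#' MembershipResult: membership-function composite scores
#'
#' U_ij equals the standardized value X_ij; the comprehensive value u_i is
#' the (weighted) mean across indicators. Larger u_i = stronger tolerance.
#'
#' @slot U membership value matrix (equals the standardized matrix).
#' @slot u named numeric vector of comprehensive membership values.
#' @slot weights indicator weights summing to 1.
#' @slot ranking cultivar ids ordered by decreasing u (ties broken by id).
#' @seealso [membershipScores()]
#' @export
setClass("MembershipResult",
  representation(U = "matrix", u = "numeric", weights = "numeric",
                 ranking = "character"))

#' TopsisResult: relative closeness to the ideal solution
#'
#' @slot aPlus per-indicator positive ideal (column maxima).
#' @slot aMinus per-indicator negative ideal (column minima).
#' @slot dPlus,dMinus per-cultivar Euclidean distances to the ideals.
#' @slot closeness per-cultivar relative closeness C_i = D-/(D+ + D-).
#' @slot ranking cultivar ids ordered by decreasing closeness.
#' @slot weights indicator weights used (uniform = unweighted).
#' @seealso [topsis()]
#' @export
setClass("TopsisResult",
  representation(aPlus = "numeric", aMinus = "numeric", dPlus = "numeric",
                 dMinus = "numeric", closeness = "numeric",
                 ranking = "character", weights = "numeric"))

setValidity("TopsisResult", function(object) {
  if (any(object@dPlus < 0) || any(object@dMinus < 0))
    return("distances must be non-negative")
  c <- object@closeness
  if (any(c < -1e-12 | c > 1 + 1e-12)) return("closeness must lie in [0, 1]")
  if (any(object@aPlus < object@aMinus - 1e-12))
    return("positive ideal must dominate negative ideal")
  TRUE
})

#' ConcordanceResult: agreement between two cultivar orderings
#'
#' @slot spearmanRho rank-level Spearman coefficient (tie-free closed form).
#' @slot kendallTau Kendall's tau between the two rank vectors.
#' @slot nReversals number of cultivars whose positions differ.
#' @slot rankTable data.frame with per-cultivar ranks under both orderings.
#' @seealso [compareRankings()]
#' @export
setClass("ConcordanceResult",
  representation(spearmanRho = "numeric", kendallTau = "numeric",
                 nReversals = "integer", rankTable = "data.frame"))

setValidity("ConcordanceResult", function(object) {
  if (abs(object@spearmanRho) > 1 + 1e-12) return("|rho| must be <= 1")
  if (abs(object@kendallTau) > 1 + 1e-12) return("|tau| must be <= 1")
  if (object@nReversals == 1L)
    return("a single cultivar cannot change position alone")
  TRUE
})

#' CorrelationResult: pairwise change-rate correlations with method map
#'
#' Pearson is used for a pair when both indicators pass a Shapiro-Wilk
#' normality screen; Spearman otherwise. Pairs involving a constant
#' indicator are reported as NA with a warning at construction.
#'
#' @slot r symmetric correlation matrix (unit diagonal).
#' @slot method character matrix, "pearson" or "spearman" per pair.
#' @slot p symmetric p-value matrix.
#' @slot significant logical matrix at the configured alpha.
#' @slot alpha significance level used.
#' @seealso [changeRateCorrelations()]
#' @export
setClass("CorrelationResult",
  representation(r = "matrix", method = "matrix", p = "matrix",
                 significant = "matrix", alpha = "numeric"))

setValidity("CorrelationResult", function(object) {
  r <- object@r
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-8)))
    return("correlation matrix must be symmetric")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) return("|r| must be <= 1")
  d <- diag(r)
  if (any(abs(d[!is.na(d)] - 1) > 1e-12)) return("diagonal must be 1")
  TRUE
})

#' ExpressionStudy: abundance matrix with sample sheet and trait table
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} whose single assay
#' \code{"fpkm"} holds non-negative FPKM-like abundances (genes x samples);
#' \code{colData} carries \code{cultivar}, \code{tissue} (\code{"above"}/
#' \code{"below"}), \code{condition}, \code{replicate}. The sample-level
#' physiological trait table and (for simulated studies) the planted ground
#' truth live in \code{metadata()} under \code{traits} and
#' \code{groundTruth}.
#'
#' @seealso [ExpressionStudy()], [simulateExpressionStudy()],
#'   [differentialExpression()], [detectModules()]
#' @export
#' @import SummarizedExperiment
setClass("ExpressionStudy", contains = "SummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
  if (!"fpkm" %in% SummarizedExperiment::assayNames(object))
    return("assay 'fpkm' is required")
  m <- SummarizedExperiment::assay(object, "fpkm")
  if (any(m < 0)) return("abundances must be non-negative")
  cd <- SummarizedExperiment::colData(object)
  need <- c("cultivar", "tissue", "condition", "replicate")
  if (!all(need %in% names(cd)))
    return(paste("colData must have columns:", paste(need, collapse = ", ")))
  if (!all(cd$condition %in% .CONDITIONS))
    return("condition must be 'control' or 'stress'")
  if (anyDuplicated(colnames(object))) return("sample ids must be unique")
  grp <- paste(cd$cultivar, cd$tissue)
  for (g in unique(grp)) {
    sub <- cd[grp == g, ]
    if (!all(table(factor(sub$condition, .CONDITIONS)) >= 2))
      return(sprintf("group '%s' needs >= 2 replicates in both conditions", g))
  }
  tr <- S4Vectors::metadata(object)$traits
  if (!is.null(tr) && !all(rownames(tr) %in% colnames(object)))
    return("trait table rownames must be sample ids")
  TRUE
})

#' DEGSet: threshold-filtered differential expression calls for one group
#'
#' Genes are called \code{up}/\code{down} when the linear fold change
#' exceeds \code{fcThreshold} (two-sided, 2^|log2fc| > fc) and the BH false
#' discovery rate is below \code{fdrThreshold}; \code{ns} otherwise.
#'
#' @slot group character of length 2: cultivar, tissue.
#' @slot table data.frame with columns \code{gene}, \code{log2fc}, \code{p},
#'   \code{fdr}, \code{call}.
#' @slot fcThreshold,fdrThreshold the thresholds used.
#' @seealso [differentialExpression()], [intersectDEGSets()]
#' @export
setClass("DEGSet",
  representation(group = "character", table = "data.frame",
                 fcThreshold = "numeric", fdrThreshold = "numeric"))

setValidity("DEGSet", function(object) {
  tb <- object@table
  need <- c("gene", "log2fc", "p", "fdr", "call")
  if (!all(need %in% names(tb)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (any(tb$fdr < 0 | tb$fdr > 1)) return("fdr must lie in [0, 1]")
  lfcCut <- log2(object@fcThreshold)
  up <- tb$call == "up"; dn <- tb$call == "down"
  if (any(up & !(tb$log2fc > lfcCut & tb$fdr < object@fdrThreshold)))
    return("'up' calls must satisfy both thresholds with log2fc > 0")
  if (any(dn & !(tb$log2fc < -lfcCut & tb$fdr < object@fdrThreshold)))
    return("'down' calls must satisfy both thresholds with log2fc < 0")
  TRUE
})

#' ModuleAssignment: co-expression module labels and derived summaries
#'
#' Module id 0 is reserved for unassigned ("grey") genes; it is never merged
#' and never reported as trait-linked. Labels 1, 2, ... are ordered by
#' decreasing module size.
#'
#' @slot labels named integer vector, gene -> module id (0 = unassigned).
#' @slot eigengenes matrix, modules x samples; unit-norm first principal
#'   component scores, sign-oriented along the module mean profile.
#' @slot kWithin named numeric vector of intramodular connectivity.
#' @slot mergeLog data.frame recording merged module pairs.
#' @seealso [detectModules()], [moduleEigengenes()], [hubGenes()]
#' @export
setClass("ModuleAssignment",
  representation(labels = "integer", eigengenes = "matrix",
                 kWithin = "numeric", mergeLog = "data.frame"))

setValidity("ModuleAssignment", function(object) {
  if (is.null(names(object@labels))) return("labels must be named by gene")
  if (any(object@labels < 0L)) return("module ids must be >= 0")
  if (any(object@kWithin < -1e-9)) return("kWithin must be non-negative")
  TRUE
})

#' ModuleTraitResult: module eigengene vs physiological trait associations
#'
#' @slot correlation modules x traits Pearson correlation matrix.
#' @slot p matching p-value matrix.
#' @slot bestModule named integer vector: per trait, the module with the
#'   largest absolute correlation.
#' @seealso [moduleTraitCorrelations()]
#' @export
setClass("ModuleTraitResult",
  representation(correlation = "matrix", p = "matrix",
                 bestModule = "integer"))

setValidity("ModuleTraitResult", function(object) {
  if (any(abs(object@correlation) > 1 + 1e-12, na.rm = TRUE))
    return("|correlation| must be <= 1")
  TRUE
})
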