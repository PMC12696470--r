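# Threshold-based differential expression (log2 Welch t-test + BH) and the
# multi-set Venn intersection yielding the shared gene set.

#' Differential expression calls for one (cultivar, tissue) group
#'
#' Per gene, \code{log2fc = mean(log2(stress + pseudocount)) -
#' mean(log2(control + pseudocount))}; the p-value comes from a Welch
#' two-sample t-test on the log2 values and the FDR from Benjamini-Hochberg
#' across all genes of the group. A gene is called \code{up} (\code{down})
#' when the linear fold change exceeds the threshold two-sidedly,
#' \code{2^|log2fc| > fcThreshold}, the FDR is below \code{fdrThreshold},
#' and the sign of log2fc matches. Zero-variance genes with equal means get
#' p = 1.
#'
#' @param study an [ExpressionStudy-class].
#' @param cultivar,tissue the group to test (>= 2 replicates per condition).
#' @param fcThreshold linear fold-change threshold (default 1.5).
#' @param fdrThreshold BH false-discovery-rate threshold (default 0.05).
#' @param pseudocount added before log2 to guard zeros (default 1).
#' @return A [DEGSet-class].
#' @examples
#' st <- simulateExpressionStudy(nGenes = 300, sharedCount = 10,
#'                               nCandidates = 4, seed = 1)
#' differentialExpression(st, "cvA", "above")
#' @export
differentialExpression <- function(study, cultivar, tissue,
                                   fcThreshold = 1.5, fdrThreshold = 0.05,
                                   pseudocount = 1) {
  stopifnot(is(study, "ExpressionStudy"))
  cd <- SummarizedExperiment::colData(study)
  sel <- cd$cultivar == cultivar & cd$tissue == tissue
  if (!any(sel)) stop(sprintf("no samples for group (%s, %s)",
                              cultivar, tissue))
  ctrl <- sel & cd$condition == "control"
  strs <- sel & cd$condition == "stress"
  if (sum(ctrl) < 2 || sum(strs) < 2)
    stop("need >= 2 replicates per condition")
  m <- fpkm(study)
  if (any(m < 0)) stop("negative abundances are invalid")
  la <- log2(m[, ctrl, drop = FALSE] + pseudocount)
  lb <- log2(m[, strs, drop = FALSE] + pseudocount)
  lfc <- rowMeans(lb) - rowMeans(la)
  va <- apply(la, 1, var); vb <- apply(lb, 1, var)
  na <- ncol(la); nb <- ncol(lb)
  p <- vapply(seq_len(nrow(m)), function(g) {
    if (va[g] == 0 && vb[g] == 0)
      return(if (isTRUE(all.equal(lfc[[g]], 0))) 1 else 0)
    se2a <- va[g] / na; se2b <- vb[g] / nb
    tt <- lfc[[g]] / sqrt(se2a + se2b)
    dfw <- (se2a + se2b)^2 /
      (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
    2 * pt(-abs(tt), dfw)
  }, numeric(1))
  fdr <- p.adjust(p, method = "BH")
  lfcCut <- log2(fcThreshold)
  call <- ifelse(abs(lfc) > lfcCut & fdr < fdrThreshold,
                 ifelse(lfc > 0, "up", "down"), "ns")
  new("DEGSet", group = c(cultivar, tissue),
      table = data.frame(gene = rownames(m), log2fc = unname(lfc), p = p,
                         fdr = fdr, call = call),
      fcThreshold = fcThreshold, fdrThreshold = fdrThreshold)
}

#' Differential expression across all groups of a study
#'
#' @param study an [ExpressionStudy-class].
#' @param ... passed to [differentialExpression()].
#' @return Named list of [DEGSet-class], one per (cultivar, tissue) group.
#' @export
differentialExpressionAll <- function(study, ...) {
  g <- studyGroups(study)
  sets <- lapply(seq_len(nrow(g)), function(i)
    differentialExpression(study, g$cultivar[i], g$tissue[i], ...))
  setNames(sets, g$id)
}

#' Intersection and Venn regions of multiple DEG sets
#'
#' A gene counts as differential in a set when its call is not \code{ns}.
#' The shared set is the intersection across all sets; every one of the
#' 2^k - 1 Venn regions is reported by its membership pattern.
#'
#' @param sets list of >= 2 [DEGSet-class] objects.
#' @return list with \code{shared} (sorted gene ids differential in every
#'   set), \code{perSet} (named list of differential gene vectors) and
#'   \code{venn} (data.frame: binary membership pattern, region size).
#' @export
intersectDEGSets <- function(sets) {
  if (length(sets) < 2) stop("need >= 2 DEG sets")
  perSet <- lapply(sets, degCalls)
  if (is.null(names(perSet)) || any(!nzchar(names(perSet))))
    names(perSet) <- vapply(sets, function(s)
      paste(s@group, collapse = "."), character(1))
  universe <- sort(unique(unlist(perSet)))
  if (length(unlist(lapply(sets, function(s) s@table$gene))) == 0)
    stop("empty gene universe")
  k <- length(perSet)
  memb <- vapply(perSet, function(s) universe %in% s,
                 logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1)
  pattern <- apply(memb, 1, function(z) paste(as.integer(z), collapse = ""))
  allPat <- apply(expand.grid(rep(list(0:1), k))[-1, k:1], 1, paste,
                  collapse = "")
  venn <- data.frame(pattern = allPat,
                     size = as.integer(table(factor(pattern, allPat))))
  shared <- universe[rowSums(memb) == k]
  list(shared = shared, perSet = perSet, venn = venn)
}
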