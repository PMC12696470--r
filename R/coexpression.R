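# From-scratch weighted co-expression core: soft-threshold selection,
# adjacency, topological overlap, static-cut module detection with
# eigengene merging, module-trait correlation, connectivity, hub and
# candidate selection.

#' AdjacencyMatrix: soft-thresholded co-expression adjacency
#'
#' @slot a symmetric gene x gene matrix in [0, 1] with unit diagonal
#'   (self-adjacency is excluded from connectivity sums).
#' @slot power the soft-thresholding exponent beta.
#' @slot mode \code{"unsigned"} (|cor|^beta) or \code{"signed"}
#'   (((1 + cor)/2)^beta).
#' @seealso [adjacencyMatrix()], [tomSimilarity()], [hubGenes()]
#' @export
setClass("AdjacencyMatrix",
  representation(a = "matrix", power = "numeric", mode = "character"))

setValidity("AdjacencyMatrix", function(object) {
  a <- object@a
  if (min(a) < -1e-12 || max(a) > 1 + 1e-12)
    return("adjacency entries must lie in [0, 1]")
  if (!isTRUE(all.equal(a, t(a), tolerance = 1e-8)))
    return("adjacency must be symmetric")
  TRUE
})

#' TOMMatrix: topological overlap similarity
#'
#' @slot t symmetric gene x gene matrix in [0, 1] with unit diagonal;
#'   dissimilarity for clustering is 1 - t.
#' @seealso [tomSimilarity()], [detectModules()]
#' @export
setClass("TOMMatrix", representation(t = "matrix"))

setValidity("TOMMatrix", function(object) {
  tt <- object@t
  if (min(tt) < -1e-9 || max(tt) > 1 + 1e-9)
    return("TOM entries must lie in [0, 1]")
  if (any(abs(diag(tt) - 1) > 1e-12)) return("TOM diagonal must be 1")
  TRUE
})

.log2expr <- function(study, pseudocount = 1)
  log2(fpkm(study) + pseudocount)

#' Drop genes below an expression floor
#'
#' Retains genes whose maximum abundance across samples reaches the
#' threshold (inclusive), the customary low-expression gene filter before
#' network construction.
#'
#' @param study an [ExpressionStudy-class].
#' @param threshold minimum-maximum abundance on the FPKM scale (default 2).
#' @return The filtered [ExpressionStudy-class].
#' @export
filterLowExpression <- function(study, threshold = 2) {
  stopifnot(is(study, "ExpressionStudy"))
  keep <- apply(fpkm(study), 1, max) >= threshold
  if (!any(keep)) stop("all genes fall below the expression threshold")
  study[keep, ]
}

#' Scale-free topology fit index of a connectivity distribution
#'
#' Bins connectivity into \code{nBins} equal-width bins and regresses
#' log10(mean frequency) on log10(mean connectivity) over non-empty bins.
#' The returned R^2 is signed by minus the slope's sign, so it is positive
#' when frequency decays with connectivity (the scale-free direction).
#'
#' @param k per-gene connectivity vector.
#' @param nBins number of equal-width bins (default 10).
#' @return Signed R^2, or NA (with a warning) when fewer than 3 non-empty
#'   bins remain.
#' @export
scaleFreeFit <- function(k, nBins = 10) {
  br <- seq(min(k), max(k), length.out = nBins + 1)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- as.numeric(table(bin)) / length(k)
  meanK <- tapply(k, bin, mean)
  ok <- freq > 0 & !is.na(meanK) & meanK > 0
  if (sum(ok) < 3) {
    warning("fewer than 3 non-empty bins; fit index undefined")
    return(NA_real_)
  }
  fit <- stats::lm(log10(freq[ok]) ~ log10(meanK[ok]))
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[[2]]) * r2
}

#' Choose the soft-thresholding power
#'
#' For each candidate power, builds the adjacency, computes per-gene
#' connectivity and the signed scale-free fit index, and returns the first
#' power whose index reaches \code{target}; if none does, the power with
#' the largest index is returned with a warning.
#'
#' @param study an [ExpressionStudy-class] (no constant genes).
#' @param powers ascending candidate powers (default 1:20).
#' @param target fit-index target (default 0.9).
#' @param mode adjacency mode, \code{"unsigned"} or \code{"signed"}.
#' @param nBins bins for [scaleFreeFit()].
#' @return list with \code{power} (chosen) and \code{table} (data.frame:
#'   \code{power}, \code{fitIndex}, \code{meanK}).
#' @export
pickSoftThreshold <- function(study, powers = 1:20, target = 0.9,
                              mode = c("unsigned", "signed"), nBins = 10) {
  stopifnot(is(study, "ExpressionStudy"), length(powers) > 0)
  mode <- match.arg(mode)
  e <- .log2expr(study)
  sds <- apply(e, 1, sd)
  if (any(sds == 0))
    stop("constant gene(s): ", paste(head(rownames(e)[sds == 0]),
                                     collapse = ", "))
  cc <- cor(t(e))
  base <- if (mode == "unsigned") abs(cc) else (1 + cc) / 2
  diag(base) <- 0
  tab <- do.call(rbind, lapply(powers, function(b) {
    a <- base^b
    k <- rowSums(a)
    data.frame(power = b,
               fitIndex = suppressWarnings(scaleFreeFit(k, nBins)),
               meanK = mean(k))
  }))
  hit <- which(!is.na(tab$fitIndex) & tab$fitIndex >= target)
  if (length(hit)) {
    power <- tab$power[hit[1]]
  } else {
    power <- tab$power[which.max(tab$fitIndex)]
    warning(sprintf(
      "no candidate power reached the fit target %.2f; using argmax %d",
      target, power))
  }
  list(power = power, table = tab)
}

#' Soft-thresholded adjacency of a study
#'
#' Pearson correlation of log2 abundances across samples, raised to the
#' power beta: unsigned \code{|cor|^beta} or signed
#' \code{((1 + cor)/2)^beta}.
#'
#' @param study an [ExpressionStudy-class] with >= 3 samples, or a plain
#'   gene x sample numeric matrix (used as-is, no log transform).
#' @param power the soft-thresholding exponent beta.
#' @param mode \code{"unsigned"} (default) or \code{"signed"}.
#' @return An [AdjacencyMatrix-class].
#' @export
adjacencyMatrix <- function(study, power, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  e <- if (is(study, "ExpressionStudy")) .log2expr(study) else study
  if (ncol(e) < 3) stop("need >= 3 samples")
  sds <- apply(e, 1, sd)
  if (any(sds == 0))
    stop("constant gene(s): ", paste(head(rownames(e)[sds == 0]),
                                     collapse = ", "))
  cc <- cor(t(e))
  a <- if (mode == "unsigned") abs(cc)^power else ((1 + cc) / 2)^power
  a <- (a + t(a)) / 2
  diag(a) <- 1
  new("AdjacencyMatrix", a = a, power = power, mode = mode)
}

#' Topological overlap similarity of an adjacency
#'
#' \code{t_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)} with
#' the sum over u distinct from i and j and connectivity
#' \code{k_i = sum_u a_iu} excluding the self-edge; \code{t_ii = 1}. The
#' degenerate denominator (an isolated pair with a_ij = 1) takes the limit
#' value 1.
#'
#' @param adj an [AdjacencyMatrix-class].
#' @return A [TOMMatrix-class].
#' @export
tomSimilarity <- function(adj) {
  stopifnot(is(adj, "AdjacencyMatrix"))
  a <- adj@a
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tt <- ifelse(den == 0, 1, num / den)
  tt <- (tt + t(tt)) / 2
  diag(tt) <- 1
  new("TOMMatrix", t = tt)
}

# first principal component of the z-scored expression of a gene set,
# unit-norm over samples, oriented along the module mean profile
.eigengene <- function(e, genes) {
  z <- t(scale(t(e[genes, , drop = FALSE])))
  if (length(genes) == 1L) {
    v <- drop(z)
    v <- v / sqrt(sum(v^2))
  } else {
    v <- svd(z, nu = 0, nv = 1)$v[, 1]
  }
  if (cor(v, colMeans(z)) < 0) v <- -v
  setNames(v, colnames(e))
}

#' Module eigengenes
#'
#' Per module, the first principal component of the per-gene z-scored
#' expression across samples (unit norm), sign-oriented so the eigengene
#' correlates positively with the module's mean profile. A one-gene module
#' yields that gene's normalized z-scored profile.
#'
#' @param study an [ExpressionStudy-class].
#' @param labels named integer vector gene -> module id (0 = unassigned,
#'   skipped).
#' @return Matrix modules x samples with rownames \code{ME<id>}.
#' @export
moduleEigengenes <- function(study, labels) {
  e <- .log2expr(study)
  mods <- sort(setdiff(unique(labels), 0L))
  me <- t(vapply(mods, function(m)
    .eigengene(e, names(labels)[labels == m]), numeric(ncol(e))))
  rownames(me) <- paste0("ME", mods)
  me
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity
#' \code{1 - t}, cut statically at \code{cutHeightFrac} times the maximum
#' merge height. Clusters smaller than \code{minSize} are unassigned
#' (module 0). Module eigengenes are then merged iteratively: while any
#' pair of module eigengenes correlates above \code{1 - mergeThreshold},
#' the closest pair is merged and eigengenes are recomputed. Final labels
#' are renumbered by decreasing module size (ties by smallest member id).
#'
#' @param tom a [TOMMatrix-class].
#' @param study the [ExpressionStudy-class] the TOM came from (for
#'   eigengenes).
#' @param adjacency optional [AdjacencyMatrix-class]; when supplied,
#'   intramodular connectivity is computed from it (see [hubGenes()]).
#' @param minSize minimum module size (default 30).
#' @param mergeThreshold eigengene dissimilarity below which modules merge
#'   (default 0.25, i.e. merge when correlation > 0.75).
#' @param cutHeightFrac static cut height as a fraction of the dendrogram
#'   height (default 0.99).
#' @return A [ModuleAssignment-class].
#' @export
detectModules <- function(tom, study, adjacency = NULL, minSize = 30,
                          mergeThreshold = 0.25, cutHeightFrac = 0.99) {
  stopifnot(is(tom, "TOMMatrix"), is(study, "ExpressionStudy"))
  tt <- tom@t
  genes <- rownames(tt)
  if (is.null(genes)) genes <- rownames(study)
  if (nrow(tt) < minSize) {
    warning("fewer genes than minSize; all genes unassigned")
    return(new("ModuleAssignment",
               labels = setNames(integer(nrow(tt)), genes),
               eigengenes = matrix(numeric(0), 0, ncol(study),
                                   dimnames = list(NULL, colnames(study))),
               kWithin = setNames(numeric(nrow(tt)), genes),
               mergeLog = data.frame(from = integer(), into = integer())))
  }
  tree <- hclust(as.dist(1 - tt), method = "average")
  cl <- cutree(tree, h = cutHeightFrac * max(tree$height))
  names(cl) <- genes
  sizes <- table(cl)
  labels <- ifelse(sizes[as.character(cl)] >= minSize, cl, 0L)
  labels <- setNames(as.integer(labels), genes)
  mergeLog <- data.frame(from = integer(), into = integer())
  # iterative eigengene merging
  repeat {
    mods <- sort(setdiff(unique(labels), 0L))
    if (length(mods) < 2) break
    me <- moduleEigengenes(study, labels)
    cm <- cor(t(me))
    diag(cm) <- -Inf
    if (max(cm) <= 1 - mergeThreshold) break
    idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    a <- mods[idx[1]]; b <- mods[idx[2]]
    into <- min(a, b); from <- max(a, b)
    labels[labels == from] <- into
    mergeLog <- rbind(mergeLog, data.frame(from = from, into = into))
  }
  # renumber by decreasing size; ties by smallest member gene id
  mods <- setdiff(unique(labels), 0L)
  if (length(mods)) {
    sz <- vapply(mods, function(m) sum(labels == m), integer(1))
    firstId <- vapply(mods, function(m) min(names(labels)[labels == m]),
                      character(1))
    ord <- mods[order(-sz, firstId)]
    labels <- setNames(c(0L, seq_along(ord))[match(labels, c(0L, ord))],
                       genes)
  }
  me <- if (length(mods)) moduleEigengenes(study, labels)
        else matrix(numeric(0), 0, ncol(study),
                    dimnames = list(NULL, colnames(study)))
  kw <- if (!is.null(adjacency)) .kWithin(adjacency, labels)
        else .kWithin(new("AdjacencyMatrix", a = tt, power = 1,
                          mode = "unsigned"), labels)
  new("ModuleAssignment", labels = labels, eigengenes = me, kWithin = kw,
      mergeLog = mergeLog)
}

.kWithin <- function(adjacency, labels) {
  a <- adjacency@a
  diag(a) <- 0
  kw <- setNames(numeric(length(labels)), names(labels))
  for (m in setdiff(unique(labels), 0L)) {
    idx <- names(labels)[labels == m]
    kw[idx] <- rowSums(a[idx, idx, drop = FALSE])
  }
  kw
}

#' Module eigengene vs trait correlations
#'
#' Pearson correlation and p-value for every (module eigengene, trait)
#' pair; per trait, the module with the largest absolute correlation is
#' reported as its best module.
#'
#' @param eigengenes modules x samples matrix (see [moduleEigengenes()]).
#' @param traits samples x trait numeric matrix; rownames must match the
#'   eigengene sample columns exactly.
#' @return A [ModuleTraitResult-class].
#' @export
moduleTraitCorrelations <- function(eigengenes, traits) {
  sa <- colnames(eigengenes); sb <- rownames(traits)
  if (!identical(sort(sa), sort(sb)))
    stop("sample mismatch between eigengenes and traits: ",
         paste(union(setdiff(sa, sb), setdiff(sb, sa)), collapse = ", "))
  traits <- traits[sa, , drop = FALSE]
  nm <- nrow(eigengenes); nt <- ncol(traits)
  r <- p <- matrix(NA_real_, nm, nt,
                   dimnames = list(rownames(eigengenes), colnames(traits)))
  for (i in seq_len(nm)) for (j in seq_len(nt)) {
    ct <- cor.test(eigengenes[i, ], traits[, j])
    r[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value
  }
  best <- apply(abs(r), 2, which.max)
  bestMod <- setNames(as.integer(sub("^ME", "", rownames(r)[best])),
                      colnames(traits))
  new("ModuleTraitResult", correlation = r, p = p, bestModule = bestMod)
}

#' Hub genes by intramodular connectivity
#'
#' Per module, the \code{topK} genes with the largest intramodular
#' connectivity \code{k_within(g) = sum of adjacency from g to the other
#' genes of its module} (self-edges excluded); modules smaller than
#' \code{topK} return all members. Ties break deterministically by gene
#' id.
#'
#' @param adjacency an [AdjacencyMatrix-class] (or a [TOMMatrix-class] to
#'   rank by topological-overlap connectivity instead).
#' @param labels named integer vector gene -> module id.
#' @param topK hubs per module (default 30).
#' @return list with \code{hubs} (named list module -> gene ids) and
#'   \code{kWithin} (named numeric vector).
#' @export
hubGenes <- function(adjacency, labels, topK = 30) {
  if (is(adjacency, "TOMMatrix"))
    adjacency <- new("AdjacencyMatrix", a = adjacency@t, power = 1,
                     mode = "unsigned")
  stopifnot(is(adjacency, "AdjacencyMatrix"))
  if (!all(names(labels) %in% rownames(adjacency@a)))
    stop("labels name genes absent from the adjacency")
  kw <- .kWithin(adjacency, labels)
  mods <- sort(setdiff(unique(labels), 0L))
  hubs <- lapply(mods, function(m) {
    idx <- names(labels)[labels == m]
    idx[order(-kw[idx], idx, method = "radix")][seq_len(min(topK,
                                                            length(idx)))]
  })
  list(hubs = setNames(hubs, paste0("module", mods)), kWithin = kw)
}

#' Candidate genes: trait-linked hubs that are shared DEGs
#'
#' Takes the union of the hub lists of trait-linked modules and intersects
#' it with the set of genes differentially expressed in every sample group,
#' mirroring the core-gene selection of the discovery pipeline.
#'
#' @param hubSets named list \code{module<id>} -> hub gene ids (see
#'   [hubGenes()]).
#' @param traitModules integer ids of modules linked to traits.
#' @param shared character vector of shared DEG ids.
#' @param kWithin optional named connectivity vector for provenance.
#' @return data.frame with columns \code{gene}, \code{module},
#'   \code{kWithin}, sorted by gene id; zero rows when the intersection is
#'   empty.
#' @export
candidateGenes <- function(hubSets, traitModules, shared, kWithin = NULL) {
  if (!length(hubSets) || !length(shared))
    stop("hub sets and shared set must be non-empty")
  keep <- hubSets[paste0("module", traitModules)]
  keep <- keep[!vapply(keep, is.null, logical(1))]
  prov <- do.call(rbind, lapply(names(keep), function(nm)
    data.frame(gene = keep[[nm]],
               module = as.integer(sub("^module", "", nm)))))
  prov <- prov[!duplicated(prov$gene), , drop = FALSE]
  out <- prov[prov$gene %in% shared, , drop = FALSE]
  out <- out[order(out$gene), , drop = FALSE]
  out$kWithin <- if (!is.null(kWithin)) unname(kWithin[out$gene])
                 else rep(NA_real_, nrow(out))
  rownames(out) <- NULL
  if (!nrow(out)) message("no candidate genes: hub/shared intersection empty")
  out
}
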