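# Seeded generators with known ground truth. One RNG substream per
# cultivar/module/gene (derived deterministically from the master seed) so
# that enlarging a design never perturbs draws of pre-existing units.

.substream <- function(seed, label, i = 0L) {
  h <- sum(utf8ToInt(label)) %% 9973L
  as.integer((as.numeric(seed) %% 100003 * 20011 + h * 1009 + i) %% 2147483629)
}

.withSubstream <- function(seed, label, i, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.substream(seed, label, i))
  expr
}

#' Default physiological indicator design
#'
#' Seven indicators mirroring a leaf stress-physiology panel: five positive
#' indicators (antioxidant enzymes SOD/CAT/POD, soluble protein SP, total
#' antioxidant capacity AOC) and two negative ones (membrane-damage marker
#' MDA and the osmolyte Pro, whose change rates fall with tolerance).
#' Baselines are in the indicators' customary units; \code{effectSlope} is
#' the relative change of the condition mean attained at the extreme of the
#' tolerance gradient.
#'
#' @return data.frame with columns \code{name}, \code{direction},
#'   \code{baseline}, \code{effectSlope}.
#' @export
defaultIndicators <- function() {
  data.frame(
    name = c("SOD", "CAT", "POD", "SP", "AOC", "MDA", "Pro"),
    direction = c(rep("positive", 5), "negative", "negative"),
    baseline = c(200, 80, 300, 15, 60, 8, 30),
    effectSlope = c(0.6, 0.5, 0.7, 0.3, 0.5, 0.8, 0.6))
}

#' Simulate a replicated physiological panel with a planted tolerance order
#'
#' Cultivars receive an evenly spaced latent tolerance gradient in [0, 1]
#' (shuffled over cultivar ids). Control replicates are
#' \code{baseline * (1 + N(0, noiseSd))}; stress replicates are
#' \code{baseline * (1 + effectSlope * g(tolerance) + N(0, noiseSd))} with
#' \code{g(t) = t} for positive indicators and \code{g(t) = 1 - t} for
#' negative ones, so at zero noise the change rate of every indicator is a
#' strictly monotone function of tolerance.
#'
#' @param nCultivars number of cultivars (>= 2).
#' @param indicators data.frame as [defaultIndicators()].
#' @param nReps replicates per (cultivar, condition) cell (>= 2).
#' @param noiseSd relative measurement noise (>= 0).
#' @param seed integer master seed.
#' @return A [PhysioPanel-class]; \code{groundTruth()} holds
#'   \code{tolerance} (named vector) and \code{order} (ids by decreasing
#'   tolerance).
#' @examples
#' p <- simulatePhysioPanel(seed = 1)
#' groundTruth(p)$order
#' @export
simulatePhysioPanel <- function(nCultivars = 9,
                                indicators = defaultIndicators(),
                                nReps = 3, noiseSd = 0.02, seed = 1) {
  if (nCultivars < 2) stop("nCultivars must be >= 2")
  if (nReps < 2) stop("nReps must be >= 2 (downstream tests need variance)")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (any(indicators$baseline <= 0)) stop("baselines must be positive")
  cultivars <- sprintf("cv%02d", seq_len(nCultivars))
  grad <- seq(0, 1, length.out = nCultivars)
  tolerance <- .withSubstream(seed, "tolperm", 0L,
                              setNames(grad[sample.int(nCultivars)], cultivars))
  rows <- vector("list", nCultivars)
  for (i in seq_len(nCultivars)) {
    rows[[i]] <- .withSubstream(seed, "physio", i, {
      out <- lapply(seq_len(nrow(indicators)), function(j) {
        b <- indicators$baseline[j]
        g <- if (indicators$direction[j] == "positive") tolerance[i]
             else 1 - tolerance[i]
        ctrl <- b * (1 + rnorm(nReps, 0, noiseSd))
        strs <- b * (1 + indicators$effectSlope[j] * g +
                       rnorm(nReps, 0, noiseSd))
        data.frame(cultivar = cultivars[i], indicator = indicators$name[j],
                   condition = rep(c("control", "stress"), each = nReps),
                   replicate = rep(seq_len(nReps), 2),
                   value = c(ctrl, strs))
      })
      do.call(rbind, out)
    })
  }
  truth <- list(
    tolerance = tolerance,
    order = names(sort(tolerance, decreasing = TRUE)),
    effectSlope = setNames(indicators$effectSlope, indicators$name),
    directions = setNames(indicators$direction, indicators$name))
  PhysioPanel(do.call(rbind, rows),
              setNames(indicators$direction, indicators$name),
              groundTruth = truth)
}

#' Default planted co-expression module design
#'
#' Three modules whose latent factors are tied to one physiological trait
#' each (SOD positively, MDA negatively, POD positively).
#'
#' @return data.frame with columns \code{size}, \code{trait}, \code{sign},
#'   \code{withinCor}.
#' @export
defaultModules <- function() {
  data.frame(size = c(60, 50, 40), trait = c("SOD", "MDA", "POD"),
             sign = c(1, -1, 1), withinCor = 0.85)
}

#' Simulate an expression study with planted modules, DEGs and candidates
#'
#' Generates a gene x sample FPKM-like matrix over a 2-cultivar x
#' 2-tissue x 2-condition x \code{nReps} design (24 samples by default),
#' with three layers of planted structure:
#' \itemize{
#'   \item \emph{Modules}: genes of module m load (loading
#'     \code{sqrt(withinCor)}; planted hubs load \code{sqrt(hubCor)}) on a
#'     latent factor that is constant within each (group, condition) cell.
#'     The factor combines a condition component (\code{conditionCoupling},
#'     emulating stress-responsive co-expression) with an orthogonal
#'     between-group contrast (cultivar main effect, tissue main effect,
#'     interaction for the default 2 x 2 design), and is linearly tied to
#'     its named physiological trait with the given sign. Because the
#'     factor is cell-constant, replicate comparisons are never
#'     pseudoreplicated and planted fold changes are exact.
#'   \item \emph{DEGs}: per group, \code{degUp}/\code{degDown} genes get a
#'     mean log2 shift of \code{+/-log2fcEffect} under stress;
#'     \code{sharedCount} of the up genes are shifted in every group.
#'   \item \emph{Candidates}: \code{nCandidates} of the shared genes are
#'     module hubs; their total planted log2 fold change is
#'     \code{candidateLog2fc} (module coupling plus an explicit shift), so
#'     they are simultaneously highly connected and four-way differential.
#' }
#' Latent log2 values are exponentiated (base 2) onto a non-negative
#' FPKM-like scale, so downstream log2 fold changes are exact.
#'
#' @param nGenes total genes (>= sum of module sizes plus planted DEG pool).
#' @param modules data.frame as [defaultModules()].
#' @param hubsPerModule planted hubs per module.
#' @param hubCor within-module correlation of hub genes (> withinCor).
#' @param conditionCoupling condition component of each module factor
#'   (difference of factor means, stress minus control).
#' @param cultivars,tissues ids spanning the four sample groups.
#' @param nReps replicates per (group, condition) cell.
#' @param degUp,degDown per-group planted DEG counts (up includes shared).
#' @param sharedCount genes planted as up in all groups (<= degUp).
#' @param nCandidates shared genes that are also module hubs.
#' @param log2fcEffect planted log2 fold change of non-hub DEGs.
#' @param candidateLog2fc total planted log2 fold change of candidates.
#' @param noiseSd per-sample replicate noise on the log2 scale.
#' @param baseRange range of per-gene baseline log2 abundance.
#' @param traitNoiseSd noise linking module factors to their traits.
#' @param seed integer master seed.
#' @return An [ExpressionStudy-class]; \code{groundTruth()} holds
#'   \code{moduleLabels}, \code{plantedHubs}, \code{traitLinks},
#'   \code{degSets} (per group \code{up}/\code{down}), \code{sharedSet} and
#'   \code{candidates}.
#' @examples
#' st <- simulateExpressionStudy(nGenes = 300, sharedCount = 10,
#'                               nCandidates = 4, seed = 1)
#' length(groundTruth(st)$sharedSet)
#' @export
simulateExpressionStudy <- function(nGenes = 1000,
                                    modules = defaultModules(),
                                    hubsPerModule = 10, hubCor = 0.999,
                                    conditionCoupling = 0.45,
                                    cultivars = c("cvA", "cvB"),
                                    tissues = c("above", "below"),
                                    nReps = 3,
                                    degUp = 75, degDown = 75,
                                    sharedCount = 39, nCandidates = 13,
                                    log2fcEffect = 2, candidateLog2fc = 1.3,
                                    noiseSd = 0.02, baseRange = c(4, 9),
                                    traitNoiseSd = 0.2, seed = 1) {
  nMod <- nrow(modules)
  if (sum(modules$size) > nGenes)
    stop("sum of module sizes must be <= nGenes")
  if (any(modules$withinCor <= 0 | modules$withinCor >= 1))
    stop("withinCor must lie in (0, 1)")
  if (sharedCount > degUp)
    stop("sharedCount must be <= every group's DEG (up) count")
  if (nCandidates > sharedCount) stop("nCandidates must be <= sharedCount")
  if (nCandidates > nMod * hubsPerModule)
    stop("nCandidates exceeds the number of planted hubs")
  if (any(modules$size < hubsPerModule))
    stop("hubsPerModule exceeds a module size")
  if (nReps < 2) stop("nReps must be >= 2")

  # design: 4 groups x 2 conditions x nReps
  design <- expand.grid(replicate = seq_len(nReps),
                        condition = c("control", "stress"),
                        tissue = tissues, cultivar = cultivars,
                        stringsAsFactors = FALSE)
  design <- design[, c("cultivar", "tissue", "condition", "replicate")]
  sampleIds <- with(design, paste(cultivar, tissue, condition, replicate,
                                  sep = "_"))
  rownames(design) <- sampleIds
  nS <- nrow(design)
  cellId <- with(design, paste(cultivar, tissue, condition, sep = "_"))
  cells <- unique(cellId)
  sTilde <- ifelse(design$condition == "stress", 0.5, -0.5)
  stressInd <- as.numeric(design$condition == "stress")

  gamma <- conditionCoupling
  # Module factors vary along two axes only: the condition contrast
  # (through the coupling term, so planted fold changes are exact and the
  # within-cell replicate comparison is never pseudoreplicated) and an
  # orthogonal between-group contrast. The group components are the
  # deterministic Helmert contrasts of the group factor - mutually
  # orthogonal and orthogonal to condition - so planted modules can never
  # entangle with each other or with the group-specific DEG blocks by
  # chance. Only nGroups - 1 such contrasts exist; further modules fall
  # back to seeded random group draws (centered and scaled).
  groupId <- with(design, paste(cultivar, tissue, sep = "_"))
  grps <- unique(groupId)
  grpMeta <- unique(design[, c("cultivar", "tissue")])
  ctr <- if (length(cultivars) == 2 && length(tissues) == 2) {
    # balanced +/-1 factorial contrasts: cultivar main effect, tissue
    # main effect, their interaction
    cbind(ifelse(grpMeta$cultivar == cultivars[1], -1, 1),
          ifelse(grpMeta$tissue == tissues[1], -1, 1),
          ifelse(grpMeta$cultivar == cultivars[1], -1, 1) *
            ifelse(grpMeta$tissue == tissues[1], -1, 1))
  } else if (length(grps) > 1) {
    stats::contr.helmert(length(grps))
  } else NULL
  nContr <- if (is.null(ctr)) 0L else ncol(ctr)
  factorMat <- matrix(0, nMod, nS)
  for (m in seq_len(nMod)) {
    eta <- if (m <= nContr) {
      ctr[, m]
    } else {
      e <- .withSubstream(seed, "factor", m, rnorm(length(grps)))
      e - mean(e)
    }
    etaS <- setNames(eta, grps)[groupId]
    if (sd(etaS) > 0) etaS <- etaS / sd(etaS)
    factorMat[m, ] <- gamma * sTilde +
      sqrt(max(0, 1 - gamma^2 / 4)) * etaS
  }

  # gene bookkeeping
  geneIds <- sprintf("gene%04d", seq_len(nGenes))
  labels <- integer(nGenes)
  ptr <- 0L
  hubs <- vector("list", nMod)
  for (m in seq_len(nMod)) {
    idx <- ptr + seq_len(modules$size[m])
    labels[idx] <- m
    hubs[[m]] <- geneIds[idx[seq_len(hubsPerModule)]]
    ptr <- ptr + modules$size[m]
  }
  names(labels) <- geneIds
  noisePool <- geneIds[labels == 0L]

  # candidates: round-robin over the modules' hub slots
  candIdx <- cbind(rep(seq_len(nMod), hubsPerModule),
                   rep(seq_len(hubsPerModule), each = nMod))
  candidates <- vapply(seq_len(nCandidates), function(i)
    hubs[[candIdx[i, 1]]][candIdx[i, 2]], character(1))

  # shared + per-group DEG draws from the noise pool (disjoint)
  nExtraShared <- sharedCount - nCandidates
  groups <- expand.grid(tissue = tissues, cultivar = cultivars,
                        stringsAsFactors = FALSE)
  groups <- groups[, c("cultivar", "tissue")]
  groupIds <- paste(groups$cultivar, groups$tissue, sep = ".")
  nPerGroup <- (degUp - sharedCount) + degDown
  needed <- nExtraShared + nrow(groups) * nPerGroup
  if (needed > length(noisePool))
    stop("nGenes too small for the requested DEG design")
  pool <- .withSubstream(seed, "degpick", 0L, sample(noisePool, needed))
  sharedExtra <- pool[seq_len(nExtraShared)]
  sharedSet <- c(candidates, sharedExtra)
  rest <- if (nExtraShared > 0) pool[-seq_len(nExtraShared)] else pool
  degSets <- list()
  shift <- matrix(0, nGenes, nS, dimnames = list(geneIds, sampleIds))
  for (k in seq_along(groupIds)) {
    take <- rest[(k - 1) * nPerGroup + seq_len(nPerGroup)]
    upOwn <- take[seq_len(degUp - sharedCount)]
    down <- take[(degUp - sharedCount) + seq_len(degDown)]
    gSel <- design$cultivar == groups$cultivar[k] &
            design$tissue == groups$tissue[k]
    onStress <- gSel & design$condition == "stress"
    shift[upOwn, onStress] <- shift[upOwn, onStress] + log2fcEffect
    shift[down, onStress] <- shift[down, onStress] - log2fcEffect
    degSets[[groupIds[k]]] <- list(up = c(sharedSet, upOwn), down = down)
  }
  # candidates: explicit extra shift on top of the module condition coupling
  for (m in seq_len(nMod)) {
    extra <- candidateLog2fc - sqrt(hubCor) * gamma
    if (extra < 0) {
      warning("candidateLog2fc below the module condition coupling; ",
              "clamping the extra shift to 0")
      extra <- 0
    }
    mc <- intersect(candidates, hubs[[m]])
    if (length(mc))
      shift[mc, ] <- shift[mc, ] +
        matrix(rep(extra * stressInd, length(mc)), nrow = length(mc),
               byrow = TRUE)
  }
  # non-candidate shared genes: up in every group
  if (length(sharedExtra))
    shift[sharedExtra, ] <- shift[sharedExtra, , drop = FALSE] +
      matrix(rep(log2fcEffect * stressInd, length(sharedExtra)),
             nrow = length(sharedExtra), byrow = TRUE)

  # assemble log2 matrix gene by gene
  log2x <- matrix(0, nGenes, nS, dimnames = list(geneIds, sampleIds))
  for (g in seq_len(nGenes)) {
    log2x[g, ] <- .withSubstream(seed, "gene", g, {
      base <- runif(1, baseRange[1], baseRange[2])
      m <- labels[g]
      lat <- if (m > 0L) {
        w <- if (geneIds[g] %in% hubs[[m]]) hubCor else modules$withinCor[m]
        sqrt(w) * factorMat[m, ] + sqrt(1 - w) * rnorm(nS)
      } else numeric(nS)
      base + lat + noiseSd * rnorm(nS)
    })
  }
  log2x <- log2x + shift
  mat <- 2^log2x

  # trait table: linked traits follow their module factor; the remaining
  # standard indicators are independent noise
  allTraits <- c("SOD", "CAT", "POD", "SP", "AOC", "MDA", "Pro")
  traitNames <- unique(c(modules$trait, allTraits))
  traits <- .withSubstream(seed, "traits", 0L, {
    tm <- matrix(rnorm(nS * length(traitNames)), nS,
                 dimnames = list(sampleIds, traitNames))
    for (m in seq_len(nMod))
      tm[, modules$trait[m]] <- modules$sign[m] * factorMat[m, ] +
        traitNoiseSd * rnorm(nS)
    tm
  })

  truth <- list(
    moduleLabels = as.list(labels),
    plantedHubs = setNames(hubs, paste0("module", seq_len(nMod),
                                        recycle0 = TRUE)),
    traitLinks = data.frame(module = seq_len(nMod), trait = modules$trait,
                            sign = modules$sign),
    degSets = degSets,
    sharedSet = sharedSet,
    candidates = candidates)
  ExpressionStudy(mat, design, traits = traits, groundTruth = truth)
}
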