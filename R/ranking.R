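# Directional min-max standardization, membership-function composite
# scoring, entropy weighting, TOPSIS and cross-method concordance.

.checkWeights <- function(weights, m, tol = 1e-9) {
  if (length(weights) != m)
    stop(sprintf("expected %d weights, got %d", m, length(weights)))
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > tol) stop("weights must sum to 1")
  weights
}

# stable: decreasing score, ties broken by lexicographic id
.rankIds <- function(score) {
  names(score)[order(-score, names(score), method = "radix")]
}

#' Direction-aware min-max standardization of change rates
#'
#' Positive indicators map through \code{(x - min) / (max - min)} so the
#' cultivar with the largest change rate gets 1; negative indicators map
#' through \code{(max - x) / (max - min)} so the \emph{smallest} change
#' rate gets 1. Constant columns are 0/0-degenerate; they are filled with
#' the neutral membership 0.5, flagged in the result, and carry no
#' information for entropy weighting.
#'
#' @param x a [ChangeRateMatrix-class] with >= 2 rows.
#' @return A [StandardizedMatrix-class].
#' @examples
#' m <- matrix(c(2, 4, 10), dimnames = list(c("a", "b", "c"), "SOD"))
#' x <- new("ChangeRateMatrix", rates = m, directions = c(SOD = "positive"))
#' standardizedValues(standardizeRates(x))
#' @export
standardizeRates <- function(x) {
  stopifnot(is(x, "ChangeRateMatrix"))
  m <- x@rates
  if (nrow(m) < 2) stop("need >= 2 cultivars to standardize")
  dirs <- x@directions[colnames(m)]
  out <- m
  constant <- character()
  for (j in seq_len(ncol(m))) {
    rng <- range(m[, j])
    if (rng[1] == rng[2]) {
      constant <- c(constant, colnames(m)[j])
      out[, j] <- 0.5
    } else if (dirs[j] == "positive") {
      out[, j] <- (m[, j] - rng[1]) / (rng[2] - rng[1])
    } else {
      out[, j] <- (rng[2] - m[, j]) / (rng[2] - rng[1])
    }
  }
  if (length(constant))
    warning("constant column(s) filled with neutral membership 0.5: ",
            paste(constant, collapse = ", "))
  new("StandardizedMatrix", values = out, directions = dirs,
      constantColumns = constant)
}

#' Membership-function composite tolerance scores
#'
#' The membership value of cultivar i on indicator j is its standardized
#' value, \code{U_ij = X_ij}; the comprehensive value is the weighted mean
#' \code{u_i = sum_j w_j U_ij} (equal weights 1/m by default). Larger u_i
#' means stronger saline-alkaline tolerance. The ranking sorts by
#' decreasing u with ties broken by cultivar id.
#'
#' @param X a [StandardizedMatrix-class].
#' @param weights optional non-negative weights summing to 1 (within 1e-9);
#'   see [entropyWeights()] for objective weights.
#' @return A [MembershipResult-class].
#' @export
membershipScores <- function(X, weights = NULL) {
  stopifnot(is(X, "StandardizedMatrix"))
  v <- X@values
  m <- ncol(v)
  w <- if (is.null(weights)) rep(1 / m, m) else .checkWeights(weights, m)
  u <- setNames(drop(v %*% w), rownames(v))
  new("MembershipResult", U = v, u = u, weights = setNames(w, colnames(v)),
      ranking = .rankIds(u))
}

#' Entropy weights for the standardized decision matrix
#'
#' Objective indicator weighting: with column shares
#' \code{p_ij = X_ij / sum_i X_ij}, the entropy
#' \code{e_j = -(1/ln n) sum_i p_ij ln p_ij} (zero shares contribute 0)
#' yields divergence \code{d_j = 1 - e_j} and weights
#' \code{w_j = d_j / sum_j d_j}. Low-entropy (high-information) indicators
#' receive larger weights. All-zero and constant columns carry no
#' information and get weight 0 with a warning.
#'
#' @param X a [StandardizedMatrix-class] (non-negative by construction).
#' @return Named weight vector, non-negative, summing to 1.
#' @export
entropyWeights <- function(X) {
  stopifnot(is(X, "StandardizedMatrix"))
  v <- X@values
  n <- nrow(v)
  d <- vapply(seq_len(ncol(v)), function(j) {
    cs <- sum(v[, j])
    if (cs == 0 || colnames(v)[j] %in% X@constantColumns) return(0)
    p <- v[, j] / cs
    terms <- ifelse(p > 0, p * log(p), 0)
    e <- -sum(terms) / log(n)
    max(1 - e, 0)  # guard float underflow for constant columns
  }, numeric(1))
  d[d < 1e-12] <- 0  # constant columns reach e = 1 only up to rounding
  zero <- d == 0
  if (all(zero)) stop("every column is zero-information; weights undefined")
  if (any(zero))
    warning("zero-information column(s) get weight 0: ",
            paste(colnames(v)[zero], collapse = ", "))
  setNames(d / sum(d), colnames(v))
}

#' TOPSIS relative closeness on the standardized decision matrix
#'
#' The positive ideal A+ takes the per-indicator maxima of X, the negative
#' ideal A- the minima. Per cultivar, Euclidean distances
#' \code{D_i+ = sqrt(sum_j (X_ij - X_j+)^2)} (likewise D_i-) give the
#' relative closeness \code{C_i = D_i- / (D_i+ + D_i-)}; a higher C_i means
#' stronger tolerance. By default distances are computed on X directly
#' (unweighted); optional weights scale the columns first.
#'
#' @param X a [StandardizedMatrix-class].
#' @param weights optional non-negative weights summing to 1.
#' @return A [TopsisResult-class].
#' @examples
#' m <- matrix(c(1, 0, 0.5, 0, 1, 0.5), 3,
#'             dimnames = list(c("a", "b", "c"), c("i1", "i2")))
#' x <- new("StandardizedMatrix", values = m,
#'          directions = c(i1 = "positive", i2 = "positive"))
#' closeness(topsis(x))
#' @export
topsis <- function(X, weights = NULL) {
  stopifnot(is(X, "StandardizedMatrix"))
  v <- X@values
  m <- ncol(v)
  w <- if (is.null(weights)) rep(1, m) else .checkWeights(weights, m)
  v <- sweep(v, 2, w, `*`)
  aPlus <- apply(v, 2, max)
  aMinus <- apply(v, 2, min)
  if (all(aPlus == aMinus))
    stop("all columns constant (", paste(colnames(v), collapse = ", "),
         "): closeness undefined")
  dPlus <- sqrt(rowSums(sweep(v, 2, aPlus, `-`)^2))
  dMinus <- sqrt(rowSums(sweep(v, 2, aMinus, `-`)^2))
  ci <- dMinus / (dPlus + dMinus)
  new("TopsisResult", aPlus = aPlus, aMinus = aMinus, dPlus = dPlus,
      dMinus = dMinus, closeness = setNames(ci, rownames(v)),
      ranking = .rankIds(setNames(ci, rownames(v))),
      weights = setNames(w, colnames(v)))
}

#' PCA diagnostics of the standardized matrix
#'
#' Principal components of the column-centered standardized matrix,
#' reported for inspection only: the composite score is the membership
#' average and no PCA term enters either ranking.
#'
#' @param X a [StandardizedMatrix-class] with >= 3 rows.
#' @return list with \code{explainedVariance} (ratios summing to 1),
#'   \code{loadings} and \code{scores}.
#' @export
pcaSummary <- function(X) {
  stopifnot(is(X, "StandardizedMatrix"))
  v <- X@values
  if (nrow(v) < 3) stop("need >= 3 cultivars for PCA diagnostics")
  pc <- prcomp(v, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  ratios <- if (sum(ev) > 0) ev / sum(ev) else rep(0, length(ev))
  list(explainedVariance = ratios, loadings = pc$rotation, scores = pc$x)
}

#' Concordance between two cultivar orderings
#'
#' Ranks are assigned by position (1 = most tolerant). Spearman's rho uses
#' the tie-free closed form \code{1 - 6 sum(d^2) / (n (n^2 - 1))}; Kendall's
#' tau is computed on the two rank vectors; \code{nReversals} counts the
#' cultivars whose positions differ between the orderings.
#'
#' @param orderA,orderB character vectors, permutations of the same id set,
#'   most tolerant first.
#' @return A [ConcordanceResult-class].
#' @examples
#' a <- c("JD1", "CD32", "QN52", "TQ1", "TD5", "TD15", "JD46", "JD49", "QN54")
#' b <- c("JD1", "QN52", "CD32", "TQ1", "TD5", "TD15", "JD46", "JD49", "QN54")
#' compareRankings(a, b)
#' @export
compareRankings <- function(orderA, orderB) {
  if (!setequal(orderA, orderB) || anyDuplicated(orderA) ||
      anyDuplicated(orderB) || length(orderA) != length(orderB))
    stop("orderings must be permutations of the same id set; difference: ",
         paste(union(setdiff(orderA, orderB), setdiff(orderB, orderA)),
               collapse = ", "))
  n <- length(orderA)
  rankA <- setNames(seq_len(n), orderA)
  rankB <- setNames(seq_len(n), orderB)[orderA]
  d <- rankA - rankB
  rho <- 1 - 6 * sum(d^2) / (n * (n^2 - 1))
  tau <- unname(cor(rankA, rankB, method = "kendall"))
  new("ConcordanceResult", spearmanRho = rho, kendallTau = tau,
      nReversals = sum(d != 0L),
      rankTable = data.frame(cultivar = orderA, rankA = unname(rankA),
                             rankB = unname(rankB)))
}

#' End-to-end dual-method tolerance ranking of a physiological panel
#'
#' Chains [changeRates()] -> [standardizeRates()] ->
#' \{[membershipScores()], [topsis()]\} -> [compareRankings()], with all
#' intermediates returned. Weights can be equal (default), entropy-derived,
#' or user-supplied; TOPSIS is unweighted unless \code{weightTopsis}.
#'
#' @param panel a [PhysioPanel-class].
#' @param weights \code{"equal"}, \code{"entropy"}, or a numeric vector.
#' @param weightTopsis logical; also apply the weights inside TOPSIS
#'   (default FALSE: distances on the standardized matrix directly).
#' @return list with \code{changeRates}, \code{standardized},
#'   \code{weights}, \code{membership}, \code{topsis}, \code{concordance},
#'   \code{scoreCorrelation} (Pearson between u and C over cultivars).
#' @examples
#' res <- rankCultivars(simulatePhysioPanel(seed = 1))
#' res$concordance
#' @export
rankCultivars <- function(panel, weights = "equal", weightTopsis = FALSE) {
  cr <- changeRates(panel)
  std <- standardizeRates(cr)
  w <- if (is.numeric(weights)) .checkWeights(weights, ncol(std@values))
       else switch(match.arg(weights, c("equal", "entropy")),
                   equal = NULL, entropy = entropyWeights(std))
  mem <- membershipScores(std, weights = w)
  top <- topsis(std, weights = if (weightTopsis) w else NULL)
  conc <- compareRankings(mem@ranking, top@ranking)
  list(changeRates = cr, standardized = std, weights = mem@weights,
       membership = mem, topsis = top, concordance = conc,
       scoreCorrelation = unname(cor(mem@u, top@closeness[names(mem@u)])))
}
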