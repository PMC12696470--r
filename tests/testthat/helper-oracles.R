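# Independent brute-force oracles and tiny fixture builders used across
# the suite. Oracles are written with naive loop arithmetic on purpose:
# they must not share code paths with the implementation they check.

# TOPSIS by naive loops: per-column ideals, elementwise Euclidean sums.
bruteTopsis <- function(X) {
  n <- nrow(X); m <- ncol(X)
  aPlus <- numeric(m); aMinus <- numeric(m)
  for (j in seq_len(m)) {
    aPlus[j] <- X[1, j]; aMinus[j] <- X[1, j]
    for (i in seq_len(n)) {
      if (X[i, j] > aPlus[j]) aPlus[j] <- X[i, j]
      if (X[i, j] < aMinus[j]) aMinus[j] <- X[i, j]
    }
  }
  dPlus <- numeric(n); dMinus <- numeric(n); ci <- numeric(n)
  for (i in seq_len(n)) {
    sp <- 0; sm <- 0
    for (j in seq_len(m)) {
      sp <- sp + (X[i, j] - aPlus[j])^2
      sm <- sm + (X[i, j] - aMinus[j])^2
    }
    dPlus[i] <- sqrt(sp); dMinus[i] <- sqrt(sm)
    ci[i] <- dMinus[i] / (dPlus[i] + dMinus[i])
  }
  list(aPlus = aPlus, aMinus = aMinus, dPlus = dPlus, dMinus = dMinus,
       c = ci)
}

# weighted membership mean by naive loops
bruteMembership <- function(X, w = rep(1 / ncol(X), ncol(X))) {
  u <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    s <- 0
    for (j in seq_len(ncol(X))) s <- s + w[j] * X[i, j]
    u[i] <- s
  }
  u
}

# topological overlap by triple loop on an adjacency with unit diagonal
bruteTOM <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(a[i, -i])
  tt <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- a[i, j]
    for (u in seq_len(n)) if (u != i && u != j) num <- num + a[i, u] * a[u, j]
    den <- min(k[i], k[j]) + 1 - a[i, j]
    tt[i, j] <- if (den == 0) 1 else num / den
  }
  tt
}

# per-gene intramodular connectivity by loops
bruteKWithin <- function(a, labels) {
  diag(a) <- 0
  kw <- setNames(numeric(length(labels)), names(labels))
  for (g in names(labels)) {
    if (labels[g] == 0) next
    for (h in names(labels))
      if (h != g && labels[h] == labels[g]) kw[g] <- kw[g] + a[g, h]
  }
  kw
}

# Welch t-test p-value from the textbook formulas
bruteWelchP <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  tt <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(tt), df)
}

# random symmetric adjacency with unit diagonal, entries in [0, 1]
randomAdjacency <- function(n) {
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  a
}

# tiny replicated panel from a cultivar x indicator matrix of change
# rates: control fixed at `base`, stress at base * (1 + rate)
panelFromRates <- function(rates, directions, base = 10, nReps = 3) {
  rows <- list()
  for (cv in rownames(rates)) for (ind in colnames(rates)) {
    rows[[length(rows) + 1]] <- data.frame(
      cultivar = cv, indicator = ind,
      condition = rep(c("control", "stress"), each = nReps),
      replicate = rep(seq_len(nReps), 2),
      value = c(rep(base, nReps), rep(base * (1 + rates[cv, ind]), nReps)))
  }
  PhysioPanel(do.call(rbind, rows), directions)
}

stdMatrix <- function(v, directions = NULL) {
  if (is.null(dimnames(v)))
    dimnames(v) <- list(paste0("cv", seq_len(nrow(v))),
                        paste0("i", seq_len(ncol(v))))
  if (is.null(directions))
    directions <- setNames(rep("positive", ncol(v)), colnames(v))
  new("StandardizedMatrix", values = v, directions = directions)
}

# reference nine-cultivar orderings (membership-function vs TOPSIS),
# used as documented concordance fixtures
orderMembership <- c("JD1", "CD32", "QN52", "TQ1", "TD5", "TD15", "JD46",
                     "JD49", "QN54")
orderTopsis <- c("JD1", "QN52", "CD32", "TQ1", "TD5", "TD15", "JD46",
                 "JD49", "QN54")
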