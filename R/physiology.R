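#' Per-cultivar relative change rates of the physiological indicators
#'
#' For every cultivar i and indicator j,
#' \code{x_ij = (mean(stress) - mean(control)) / mean(control)}: the
#' relative change of the condition means, signed so that directionality is
#' preserved for downstream standardization.
#'
#' @param panel a [PhysioPanel-class].
#' @return A [ChangeRateMatrix-class].
#' @examples
#' p <- simulatePhysioPanel(seed = 1)
#' ratesMatrix(changeRates(p))[1:3, 1:3]
#' @export
changeRates <- function(panel) {
  stopifnot(is(panel, "PhysioPanel"))
  df <- panel@data
  cvs <- sort(unique(df$cultivar))
  inds <- unique(df$indicator)
  x <- matrix(NA_real_, length(cvs), length(inds),
              dimnames = list(cvs, inds))
  for (cv in cvs) for (ind in inds) {
    sub <- df[df$cultivar == cv & df$indicator == ind, ]
    if (!all(.CONDITIONS %in% sub$condition))
      stop(sprintf("missing condition for cell (%s, %s)", cv, ind))
    mc <- mean(sub$value[sub$condition == "control"])
    ms <- mean(sub$value[sub$condition == "stress"])
    if (mc == 0)
      stop(sprintf("zero control mean in cell (%s, %s): change rate undefined",
                   cv, ind))
    x[cv, ind] <- (ms - mc) / mc
  }
  new("ChangeRateMatrix", rates = x, directions = panel@directions[inds])
}

#' Control-vs-stress significance per (cultivar, indicator) cell
#'
#' Welch two-sample t-test (unequal variances, Satterthwaite df) per cell,
#' with star labels from the finest alpha level the p-value beats
#' (\code{"***"} < 0.001 < \code{"**"} < 0.01 < \code{"*"} < 0.05 by
#' default) and \code{"ns"} otherwise. Degenerate cells (zero variance in
#' both conditions) report p = 1 when the means agree and p = 0, with a
#' warning, when they differ.
#'
#' @param panel a [PhysioPanel-class].
#' @param alphaLevels decreasing significance levels mapped to star labels.
#' @return data.frame with columns \code{cultivar}, \code{indicator},
#'   \code{t}, \code{df}, \code{p}, \code{label}.
#' @export
indicatorTests <- function(panel, alphaLevels = c(0.05, 0.01, 0.001)) {
  stopifnot(is(panel, "PhysioPanel"))
  alphaLevels <- sort(alphaLevels, decreasing = TRUE)
  stars <- vapply(seq_along(alphaLevels), function(i)
    paste(rep("*", i), collapse = ""), character(1))
  df <- panel@data
  cells <- unique(df[, c("cultivar", "indicator")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- df[df$cultivar == cells$cultivar[i] &
              df$indicator == cells$indicator[i], ]
    a <- sub$value[sub$condition == "control"]
    b <- sub$value[sub$condition == "stress"]
    if (sd(a) == 0 && sd(b) == 0) {
      if (isTRUE(all.equal(mean(a), mean(b)))) {
        tt <- list(statistic = 0, parameter = NA_real_, p.value = 1)
      } else {
        warning(sprintf(
          "cell (%s, %s): zero variance with unequal means; p set to 0",
          cells$cultivar[i], cells$indicator[i]))
        tt <- list(statistic = Inf, parameter = NA_real_, p.value = 0)
      }
    } else tt <- t.test(b, a, var.equal = FALSE)
    p <- tt$p.value
    hit <- which(p < alphaLevels)
    data.frame(cultivar = cells$cultivar[i], indicator = cells$indicator[i],
               t = unname(tt$statistic), df = unname(tt$parameter), p = p,
               label = if (length(hit)) stars[max(hit)] else "ns")
  })
  do.call(rbind, out)
}

#' Pairwise correlations of the change-rate columns with a normality gate
#'
#' Each indicator column is screened with a Shapiro-Wilk test at
#' \code{normalityAlpha}; a pair is correlated by Pearson only when both
#' columns pass, and by Spearman rank correlation otherwise. Pairs
#' involving a constant column are reported as NA with a warning.
#'
#' @param x a [ChangeRateMatrix-class] with >= 3 rows.
#' @param alpha significance level for flagging pairs (default 0.01).
#' @param normalityAlpha level of the per-column Shapiro-Wilk screen.
#' @return A [CorrelationResult-class].
#' @export
changeRateCorrelations <- function(x, alpha = 0.01, normalityAlpha = 0.05) {
  stopifnot(is(x, "ChangeRateMatrix"))
  m <- x@rates
  if (nrow(m) < 3) stop("need >= 3 cultivars for correlation analysis")
  p <- ncol(m)
  cols <- colnames(m)
  constant <- apply(m, 2, function(v) sd(v) == 0)
  if (any(constant))
    warning("constant column(s): ", paste(cols[constant], collapse = ", "),
            "; their correlations are reported as NA")
  normal <- vapply(seq_len(p), function(j) {
    if (constant[j]) return(FALSE)
    shapiro.test(m[, j])$p.value >= normalityAlpha
  }, logical(1))
  r <- pm <- matrix(NA_real_, p, p, dimnames = list(cols, cols))
  meth <- matrix(NA_character_, p, p, dimnames = list(cols, cols))
  diag(r) <- 1; diag(pm) <- 0
  for (j in seq_len(p - 1)) for (k in (j + 1):p) {
    if (constant[j] || constant[k]) next
    method <- if (normal[j] && normal[k]) "pearson" else "spearman"
    ct <- suppressWarnings(cor.test(m[, j], m[, k], method = method,
                                    exact = FALSE))
    r[j, k] <- r[k, j] <- unname(ct$estimate)
    pm[j, k] <- pm[k, j] <- ct$p.value
    meth[j, k] <- meth[k, j] <- method
  }
  diag(r)[constant] <- NA_real_
  sig <- pm < alpha
  new("CorrelationResult", r = r, method = meth, p = pm, significant = sig,
      alpha = alpha)
}
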