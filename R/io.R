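#' Construct a PhysioPanel
#'
#' @param data data.frame with columns \code{cultivar}, \code{indicator},
#'   \code{condition}, \code{replicate}, \code{value}.
#' @param directions named character vector (\code{"positive"} /
#'   \code{"negative"}) covering every indicator.
#' @param groundTruth optional list of planted simulation truth.
#' @return A [PhysioPanel-class] object.
#' @examples
#' df <- expand.grid(cultivar = c("a", "b"), indicator = "SOD",
#'                   condition = c("control", "stress"), replicate = 1:3)
#' df$value <- ifelse(df$condition == "stress", 15, 10)
#' PhysioPanel(df, c(SOD = "positive"))
#' @export
PhysioPanel <- function(data, directions, groundTruth = list()) {
  data$cultivar <- as.character(data$cultivar)
  data$indicator <- as.character(data$indicator)
  data$condition <- as.character(data$condition)
  new("PhysioPanel", data = data, directions = directions,
      groundTruth = groundTruth)
}

#' Construct an ExpressionStudy
#'
#' @param matrix numeric gene x sample abundance matrix (FPKM-like, >= 0)
#'   with gene rownames and sample-id colnames.
#' @param samples data.frame (rownames = sample ids) with columns
#'   \code{cultivar}, \code{tissue}, \code{condition}, \code{replicate}.
#' @param traits optional sample x indicator numeric trait matrix.
#' @param groundTruth optional list of planted simulation truth.
#' @return An [ExpressionStudy-class] object.
#' @export
ExpressionStudy <- function(matrix, samples, traits = NULL,
                            groundTruth = NULL) {
  if (!setequal(rownames(samples), colnames(matrix)))
    stop("sample sheet ids must match matrix column names; difference: ",
         paste(union(setdiff(rownames(samples), colnames(matrix)),
                     setdiff(colnames(matrix), rownames(samples))),
               collapse = ", "))
  samples <- samples[colnames(matrix), , drop = FALSE]
  md <- list()
  if (!is.null(traits)) md$traits <- as.matrix(traits)
  if (!is.null(groundTruth)) md$groundTruth <- groundTruth
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = matrix),
    colData = S4Vectors::DataFrame(samples), metadata = md)
  new("ExpressionStudy", se)
}

#' Derived (cultivar, tissue) groups of a study
#'
#' @param study an [ExpressionStudy-class].
#' @return data.frame with one row per group: \code{cultivar}, \code{tissue},
#'   \code{id} (\code{cultivar.tissue}).
#' @export
studyGroups <- function(study) {
  cd <- as.data.frame(SummarizedExperiment::colData(study))
  g <- unique(cd[, c("cultivar", "tissue")])
  g$id <- paste(g$cultivar, g$tissue, sep = ".")
  rownames(g) <- NULL
  g[order(g$id), ]
}

#' Read / write a PhysioPanel as tidy TSV
#'
#' The tidy schema has columns \code{cultivar}, \code{indicator},
#' \code{condition}, \code{replicate}, \code{value}; directions travel in a
#' two-column TSV (\code{indicator}, \code{direction}).
#'
#' @param path TSV path for the panel table.
#' @param directionsPath TSV path for the indicator direction map.
#' @param panel a [PhysioPanel-class].
#' @return \code{readPhysioPanel} returns a [PhysioPanel-class];
#'   \code{writePhysioPanel} returns \code{invisible(NULL)}.
#' @export
readPhysioPanel <- function(path, directionsPath) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  dd <- read.delim(directionsPath, stringsAsFactors = FALSE)
  PhysioPanel(df, setNames(dd$direction, dd$indicator))
}

#' @rdname readPhysioPanel
#' @export
writePhysioPanel <- function(panel, path, directionsPath) {
  write.table(panel@data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  dd <- data.frame(indicator = names(panel@directions),
                   direction = unname(panel@directions))
  write.table(dd, directionsPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(NULL)
}

#' Read / write an ExpressionStudy as TSV files
#'
#' The on-disk layout mirrors common transcriptomics practice: a gene x
#' sample matrix TSV (first column = gene id), a sample sheet TSV
#' (\code{sample}, \code{cultivar}, \code{tissue}, \code{condition},
#' \code{replicate}), an optional trait TSV (first column = sample id) and,
#' for simulated studies, a ground-truth JSON.
#'
#' @param matrixPath,samplesPath,traitsPath,groundTruthPath file paths;
#'   \code{traitsPath} and \code{groundTruthPath} may be \code{NULL}.
#' @param study an [ExpressionStudy-class].
#' @return \code{readExpressionStudy} returns an [ExpressionStudy-class];
#'   \code{writeExpressionStudy} returns \code{invisible(NULL)}.
#' @export
readExpressionStudy <- function(matrixPath, samplesPath, traitsPath = NULL,
                                groundTruthPath = NULL) {
  m <- read.delim(matrixPath, row.names = 1, check.names = FALSE)
  ss <- read.delim(samplesPath, stringsAsFactors = FALSE)
  rownames(ss) <- ss$sample
  ss$sample <- NULL
  traits <- if (!is.null(traitsPath))
    as.matrix(read.delim(traitsPath, row.names = 1, check.names = FALSE))
  gt <- if (!is.null(groundTruthPath))
    jsonlite::read_json(groundTruthPath, simplifyVector = TRUE)
  ExpressionStudy(as.matrix(m), ss, traits = traits, groundTruth = gt)
}

#' @rdname readExpressionStudy
#' @export
writeExpressionStudy <- function(study, matrixPath, samplesPath,
                                 traitsPath = NULL, groundTruthPath = NULL) {
  m <- data.frame(gene = rownames(study), fpkm(study), check.names = FALSE)
  write.table(m, matrixPath, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- data.frame(sample = colnames(study),
                   as.data.frame(SummarizedExperiment::colData(study)))
  write.table(ss, samplesPath, sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- traitMatrix(study)
  if (!is.null(traitsPath) && !is.null(tr)) {
    td <- data.frame(sample = rownames(tr), tr, check.names = FALSE)
    write.table(td, traitsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  gt <- groundTruth(study)
  if (!is.null(groundTruthPath) && !is.null(gt))
    jsonlite::write_json(gt, groundTruthPath, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
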