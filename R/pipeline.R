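# End-to-end orchestration: simulate (optional) -> physiology -> ranking ->
# DEG -> co-expression -> candidates, with persisted intermediates and a
# machine-readable report.

#' Assemble and validate a pipeline configuration
#'
#' Exactly one of \code{inputs} (paths to panel/expression TSVs) or
#' \code{simulation} (argument lists for the generators) must be given.
#'
#' @param inputs list with paths \code{panel}, \code{directions},
#'   \code{matrix}, \code{samples}, \code{traits} (optional).
#' @param simulation list with optional elements \code{panel} and
#'   \code{expression}, each an argument list for [simulatePhysioPanel()] /
#'   [simulateExpressionStudy()] (seed is injected from \code{seed}).
#' @param seed integer seed governing all randomness.
#' @param outDir output directory (created if needed); NULL disables
#'   persistence.
#' @param weights \code{"equal"}, \code{"entropy"} or a numeric vector.
#' @param fcThreshold,fdrThreshold DEG thresholds (defaults 1.5, 0.05).
#' @param expressionThreshold low-expression gene filter floor (default 2).
#' @param power soft threshold: \code{"auto"} or a positive integer.
#' @param minSize,mergeThreshold,topK module detection and hub parameters
#'   (defaults 30, 0.25, 30).
#' @param traitAlpha significance level declaring a module trait-linked.
#' @param traitCorMin minimum absolute eigengene-trait correlation for a
#'   trait link (guards against a spurious best module on a null trait).
#' @return Validated config list of class \code{saltolConfig}.
#' @export
pipelineConfig <- function(inputs = NULL, simulation = NULL, seed = 1,
                           outDir = NULL, weights = "equal",
                           fcThreshold = 1.5, fdrThreshold = 0.05,
                           expressionThreshold = 2, power = 12,
                           minSize = 30, mergeThreshold = 0.25, topK = 30,
                           traitAlpha = 0.05, traitCorMin = 0.7) {
  if (is.null(inputs) == is.null(simulation))
    stop("exactly one of 'inputs' and 'simulation' must be given")
  stopifnot(fcThreshold >= 1, fdrThreshold > 0, fdrThreshold <= 1,
            minSize >= 1, mergeThreshold >= 0, mergeThreshold <= 1,
            topK >= 1)
  if (!identical(power, "auto") && (!is.numeric(power) || power < 1))
    stop("power must be 'auto' or a positive number")
  cfg <- list(inputs = inputs, simulation = simulation, seed = seed,
              outDir = outDir, weights = weights,
              fcThreshold = fcThreshold, fdrThreshold = fdrThreshold,
              expressionThreshold = expressionThreshold, power = power,
              minSize = minSize, mergeThreshold = mergeThreshold,
              topK = topK, traitAlpha = traitAlpha, traitCorMin = traitCorMin)
  class(cfg) <- "saltolConfig"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [pipelineConfig()]
#'   arguments.
#' @return Validated config list.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

.persist <- function(outDir, name, df) {
  if (is.null(outDir)) return(invisible(NULL))
  write.table(df, file.path(outDir, name), sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' Run the full tolerance-evaluation and candidate-discovery pipeline
#'
#' Executes simulate (when configured) -> physiology (change rates, per-cell
#' tests, change-rate correlations) -> dual-method ranking -> per-group DEG
#' filtering and four-set intersection -> co-expression (filter, soft
#' threshold, adjacency, TOM, modules, module-trait correlation, hubs) ->
#' candidate genes. All intermediates are persisted under
#' \code{config$outDir} (TSV/JSON) when set; a FAILED marker naming the
#' stage is left behind on error.
#'
#' @param config a config from [pipelineConfig()] or a YAML path for
#'   [readPipelineConfig()].
#' @return list (the pipeline report) with elements \code{panel},
#'   \code{study}, \code{physiology}, \code{ranking}, \code{deg},
#'   \code{coexpression}, \code{candidates} and \code{summary} (plain
#'   counts and orderings; this is what lands in \code{report.json}).
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(simulation = list(
#'   expression = list(nGenes = 300, sharedCount = 10, nCandidates = 4)),
#'   seed = 1)
#' rep <- runPipeline(cfg)
#' rep$summary$nCandidates
#' }
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "saltolConfig"))
  outDir <- config$outDir
  if (!is.null(outDir) &&
      !dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  onFail <- function(stage, err) {
    if (!is.null(outDir))
      writeLines(c(stage, conditionMessage(err)),
                 file.path(outDir, "FAILED"))
    stop(err)
  }
  runStage <- function(name, expr)
    tryCatch(.stage(name, expr), error = function(e) onFail(name, e))

  # -- inputs -----------------------------------------------------------
  io <- runStage("load", {
    if (!is.null(config$simulation)) {
      pa <- config$simulation$panel %||% list()
      ea <- config$simulation$expression %||% list()
      pa$seed <- config$seed; ea$seed <- config$seed
      list(panel = do.call(simulatePhysioPanel, pa),
           study = do.call(simulateExpressionStudy, ea))
    } else {
      inp <- config$inputs
      list(panel = readPhysioPanel(inp$panel, inp$directions),
           study = readExpressionStudy(inp$matrix, inp$samples,
                                       inp$traits))
    }
  })
  panel <- io$panel; study <- io$study

  # -- physiology -------------------------------------------------------
  phys <- runStage("physiology", {
    cr <- changeRates(panel)
    list(changeRates = cr, tests = indicatorTests(panel),
         correlations = changeRateCorrelations(cr))
  })
  .persist(outDir, "change_rates.tsv",
           data.frame(cultivar = rownames(phys$changeRates@rates),
                      phys$changeRates@rates, check.names = FALSE))
  .persist(outDir, "indicator_tests.tsv", phys$tests)

  # -- ranking ----------------------------------------------------------
  rk <- runStage("ranking", rankCultivars(panel, weights = config$weights))
  .persist(outDir, "membership.tsv",
           data.frame(cultivar = names(rk$membership@u),
                      u = unname(rk$membership@u),
                      rank = match(names(rk$membership@u),
                                   rk$membership@ranking)))
  .persist(outDir, "topsis.tsv",
           data.frame(cultivar = names(rk$topsis@closeness),
                      dPlus = unname(rk$topsis@dPlus),
                      dMinus = unname(rk$topsis@dMinus),
                      closeness = unname(rk$topsis@closeness),
                      rank = match(names(rk$topsis@closeness),
                                   rk$topsis@ranking)))
  if (!is.null(outDir))
    jsonlite::write_json(
      list(spearmanRho = rk$concordance@spearmanRho,
           kendallTau = rk$concordance@kendallTau,
           nReversals = rk$concordance@nReversals,
           scoreCorrelation = rk$scoreCorrelation),
      file.path(outDir, "concordance.json"), auto_unbox = TRUE, digits = NA)

  # -- differential expression -----------------------------------------
  deg <- runStage("deg", {
    sets <- differentialExpressionAll(study,
                                      fcThreshold = config$fcThreshold,
                                      fdrThreshold = config$fdrThreshold)
    c(list(sets = sets), intersectDEGSets(sets))
  })
  for (nm in names(deg$sets))
    .persist(outDir, paste0("deg_", nm, ".tsv"), deg$sets[[nm]]@table)
  if (!is.null(outDir)) {
    writeLines(deg$shared, file.path(outDir, "shared_genes.txt"))
    jsonlite::write_json(setNames(as.list(deg$venn$size), deg$venn$pattern),
                         file.path(outDir, "venn_counts.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # -- co-expression ----------------------------------------------------
  cx <- runStage("coexpression", {
    filtered <- filterLowExpression(study, config$expressionThreshold)
    if (identical(config$power, "auto")) {
      pk <- pickSoftThreshold(filtered)
    } else {
      pk <- list(power = config$power, table = NULL)
    }
    adj <- adjacencyMatrix(filtered, pk$power)
    tom <- tomSimilarity(adj)
    mods <- detectModules(tom, filtered, adjacency = adj,
                          minSize = config$minSize,
                          mergeThreshold = config$mergeThreshold)
    traits <- traitMatrix(filtered)
    mt <- NULL; traitMods <- integer()
    if (!is.null(traits) && nrow(mods@eigengenes) > 0) {
      mt <- moduleTraitCorrelations(mods@eigengenes,
                                    traits[colnames(filtered), ,
                                           drop = FALSE])
      sig <- vapply(colnames(mt@p), function(tr) {
        me <- paste0("ME", mt@bestModule[tr])
        mt@p[me, tr] < config$traitAlpha &&
          abs(mt@correlation[me, tr]) >= config$traitCorMin
      }, logical(1))
      traitMods <- sort(unique(mt@bestModule[sig]))
    }
    hb <- hubGenes(adj, mods@labels, topK = config$topK)
    list(filtered = filtered, softThreshold = pk, modules = mods,
         moduleTrait = mt, traitModules = traitMods, hubs = hb)
  })
  if (!is.null(cx$softThreshold$table))
    .persist(outDir, "power_table.tsv", cx$softThreshold$table)
  .persist(outDir, "modules.tsv",
           data.frame(gene = names(cx$modules@labels),
                      module = unname(cx$modules@labels),
                      kWithin = unname(cx$modules@kWithin)))
  if (nrow(cx$modules@eigengenes))
    .persist(outDir, "eigengenes.tsv",
             data.frame(module = rownames(cx$modules@eigengenes),
                        cx$modules@eigengenes, check.names = FALSE))
  if (!is.null(cx$moduleTrait))
    .persist(outDir, "module_trait.tsv",
             data.frame(module = rownames(cx$moduleTrait@correlation),
                        cx$moduleTrait@correlation, check.names = FALSE))
  .persist(outDir, "hubs.tsv",
           do.call(rbind, lapply(names(cx$hubs$hubs), function(nm)
             data.frame(module = nm, gene = cx$hubs$hubs[[nm]]))))

  # -- candidates -------------------------------------------------------
  cand <- runStage("candidates",
    candidateGenes(cx$hubs$hubs, cx$traitModules, deg$shared,
                   kWithin = cx$hubs$kWithin))
  .persist(outDir, "candidates.tsv", cand)

  summary <- list(
    seed = config$seed,
    nCultivars = length(rk$membership@u),
    membershipRanking = rk$membership@ranking,
    topsisRanking = rk$topsis@ranking,
    spearmanRho = rk$concordance@spearmanRho,
    kendallTau = rk$concordance@kendallTau,
    nReversals = rk$concordance@nReversals,
    degCounts = lapply(deg$sets, function(s)
      list(up = sum(s@table$call == "up"),
           down = sum(s@table$call == "down"))),
    nShared = length(deg$shared),
    softPower = cx$softThreshold$power,
    moduleSizes = as.list(table(cx$modules@labels[cx$modules@labels != 0])),
    nUnassigned = sum(cx$modules@labels == 0),
    traitModules = cx$traitModules,
    nCandidates = nrow(cand),
    candidates = cand$gene)
  if (!is.null(outDir)) {
    jsonlite::write_json(summary, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(c(
      sprintf("membership ranking: %s",
              paste(summary$membershipRanking, collapse = " > ")),
      sprintf("topsis ranking:     %s",
              paste(summary$topsisRanking, collapse = " > ")),
      sprintf("spearman rho %.4f, kendall tau %.4f, %d reversals",
              summary$spearmanRho, summary$kendallTau,
              summary$nReversals),
      sprintf("shared DEGs: %d; candidates: %d", summary$nShared,
              summary$nCandidates)),
      file.path(outDir, "report.txt"))
  }
  list(panel = panel, study = study, physiology = phys, ranking = rk,
       deg = deg, coexpression = cx, candidates = cand, summary = summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate pipeline input files
#'
#' Schema checks for the TSV inputs: required columns, replicate counts,
#' id uniqueness, and matrix/sample-sheet agreement. Findings are returned,
#' never raised.
#'
#' @param panel,directions,matrix,samples,traits file paths (any may be
#'   NULL to skip its checks).
#' @return data.frame with columns \code{file}, \code{finding}; zero rows
#'   when everything is well-formed.
#' @export
validateStudy <- function(panel = NULL, directions = NULL, matrix = NULL,
                          samples = NULL, traits = NULL) {
  findings <- list()
  note <- function(file, msg)
    findings[[length(findings) + 1]] <<- data.frame(file = file,
                                                    finding = msg)
  if (!is.null(panel)) {
    df <- tryCatch(read.delim(panel), error = function(e) NULL)
    if (is.null(df)) note(panel, "unreadable TSV")
    else {
      need <- c("cultivar", "indicator", "condition", "replicate", "value")
      miss <- setdiff(need, names(df))
      if (length(miss))
        note(panel, paste("missing column(s):", paste(miss, collapse = ", ")))
      else {
        bad <- setdiff(unique(df$condition), .CONDITIONS)
        if (length(bad))
          note(panel, paste("invalid condition value(s):",
                            paste(bad, collapse = ", ")))
        cnt <- as.data.frame(table(df$cultivar, df$indicator, df$condition))
        low <- cnt[cnt$Freq > 0 & cnt$Freq < 2, ]
        if (nrow(low))
          note(panel, sprintf(
            "cell (%s, %s, %s) has %d replicate(s); >= 2 required",
            low$Var1[1], low$Var2[1], low$Var3[1], low$Freq[1]))
      }
    }
  }
  if (!is.null(directions)) {
    dd <- tryCatch(read.delim(directions), error = function(e) NULL)
    if (is.null(dd) || !all(c("indicator", "direction") %in% names(dd)))
      note(directions, "needs columns indicator, direction")
    else if (!all(dd$direction %in% .DIRECTIONS))
      note(directions, "direction must be 'positive' or 'negative'")
  }
  mIds <- NULL
  if (!is.null(matrix)) {
    m <- tryCatch(read.delim(matrix, row.names = 1, check.names = FALSE),
                  error = function(e) NULL)
    if (is.null(m)) note(matrix, "unreadable TSV")
    else {
      mIds <- colnames(m)
      if (anyDuplicated(rownames(m))) note(matrix, "duplicate gene ids")
      if (any(vapply(m, function(v) any(!is.finite(v) | v < 0),
                     logical(1))))
        note(matrix, "abundances must be finite and non-negative")
    }
  }
  if (!is.null(samples)) {
    ss <- tryCatch(read.delim(samples), error = function(e) NULL)
    need <- c("sample", "cultivar", "tissue", "condition", "replicate")
    if (is.null(ss) || !all(need %in% names(ss)))
      note(samples, paste("needs columns:", paste(need, collapse = ", ")))
    else {
      if (anyDuplicated(ss$sample)) note(samples, "duplicate sample ids")
      if (!is.null(mIds)) {
        miss <- setdiff(mIds, ss$sample)
        extra <- setdiff(ss$sample, mIds)
        if (length(miss))
          note(samples, paste("matrix column(s) missing from sheet:",
                              paste(miss, collapse = ", ")))
        if (length(extra))
          note(samples, paste("sheet sample(s) missing from matrix:",
                              paste(extra, collapse = ", ")))
      }
    }
  }
  if (!is.null(traits)) {
    tr <- tryCatch(read.delim(traits, row.names = 1, check.names = FALSE),
                   error = function(e) NULL)
    if (is.null(tr)) note(traits, "unreadable TSV")
    else if (!is.null(mIds) && !all(rownames(tr) %in% mIds))
      note(traits, "trait rows must be sample ids present in the matrix")
  }
  if (!length(findings))
    return(data.frame(file = character(), finding = character()))
  do.call(rbind, findings)
}
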