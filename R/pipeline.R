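#' Assemble a pipeline configuration
#'
#' Collects inputs and the analysis parameters (all defaulting to the
#' standard settings: count filter 5 in 25\% of samples, perturbation FDR
#' 0.1, network significance 0.05, biomass floor 0.8, objective fraction
#' 1, shift threshold 0.1, GA 300x100 stopping at 0.90 fitness, 10-fold
#' CV, frequency threshold 80\%).
#'
#' @param model path to a model file or a \linkS4class{MetabolicModel}.
#' @param counts,lengths,groups paths to the TSV inputs (see
#'   [readCohort()]) or an \linkS4class{ExpressionCohort} passed as
#'   \code{counts}.
#' @param media path to a media YAML or a [mediaSpec()].
#' @param currency currency metabolite base ids.
#' @param seed integer seed governing every stochastic stage.
#' @param minCount,minFraction low-expression filter parameters.
#' @param alpha perturbation FDR threshold.
#' @param networkQ metabolite-network significance threshold.
#' @param beta,gamma FVA biomass floor and objective fraction.
#' @param delta flux-range shift threshold for marker candidates.
#' @param gaRepeats number of GA repeats for frequency ranking.
#' @param ga a [gaConfig()].
#' @param folds,cvRepeats SVM cross-validation settings.
#' @param frequencyThreshold top-rank frequency threshold (percent).
#' @param healthyLabel,diseaseLabel group labels in the sample table.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(model, counts, lengths = NULL, groups = NULL,
                           media, currency = defaultCurrency(), seed,
                           minCount = 5, minFraction = 0.25, alpha = 0.1,
                           networkQ = 0.05, beta = 0.8, gamma = 1,
                           delta = 0.1, gaRepeats = 100,
                           ga = gaConfig(), folds = 10, cvRepeats = 100,
                           frequencyThreshold = 80,
                           healthyLabel = "healthy",
                           diseaseLabel = "disease") {
  if (missing(seed) || is.null(seed))
    stop("config validation: a seed is required (every stochastic stage ",
         "must be seeded)")
  for (p in c("model", "counts")) {
    v <- get(p)
    if (is.character(v) && !file.exists(v))
      stop("config validation: file not found for '", p, "': ", v)
  }
  structure(list(model = model, counts = counts, lengths = lengths,
                 groups = groups, media = media, currency = currency,
                 seed = as.integer(seed), minCount = minCount,
                 minFraction = minFraction, alpha = alpha,
                 networkQ = networkQ, beta = beta, gamma = gamma,
                 delta = delta, gaRepeats = gaRepeats, ga = ga,
                 folds = folds, cvRepeats = cvRepeats,
                 frequencyThreshold = frequencyThreshold,
                 healthyLabel = healthyLabel,
                 diseaseLabel = diseaseLabel),
            class = "PipelineConfig")
}

#' Run the full two-group flux analysis pipeline
#'
#' Executes preprocess -> context-specific model extraction ->
#' personalization -> cohort FVA -> perturbed-reaction calling ->
#' pathway/metabolite/compartment enrichment -> metabolite network ->
#' marker selection, writing every intermediate artifact and a manifest
#' into \code{outDir}. Re-running an identical configuration reproduces
#' the statistical outputs byte for byte.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the in-memory results (\code{cohort},
#'   \code{contextModel}, \code{ranges}, \code{diff}, \code{enrichment},
#'   \code{network}, \code{components}, \code{panel}, \code{metrics}).
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  model <- stage("load-model",
    if (is.character(config$model)) readModel(config$model) else config$model)
  cohort <- stage("load-counts",
    if (is.character(config$counts))
      readCohort(config$counts, config$lengths, config$groups)
    else config$counts)
  media <- stage("load-media",
    if (is.character(config$media)) readMedia(config$media) else config$media)

  cohort <- stage("preprocess", {
    x <- filterLowExpressed(cohort, config$minCount, config$minFraction)
    normalizeCohort(x)
  })
  writeCohortMatrix(cohort, file.path(outDir, "normalized.tsv"))

  contextModel <- stage("extract", {
    m <- personalizeModel(model, cohort, media,
                          group = config$healthyLabel)
    removeDeadEnds(m)
  })
  writeModel(contextModel, file.path(outDir, "context_model.json"))
  st <- modelStats(contextModel)
  utils::write.table(
    data.frame(reactions = st$reactions, metabolites = st$metabolites,
               genes = st$genes),
    file.path(outDir, "model_stats.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  havg <- stage("group-average-healthy",
    personalizeModel(contextModel, cohort, media,
                     group = config$healthyLabel))
  davg <- stage("group-average-disease",
    personalizeModel(contextModel, cohort, media,
                     group = config$diseaseLabel))
  bref <- stage("biomass-reference", {
    sol <- fba(havg, biomassId(havg))
    if (sol$status != "optimal")
      stop("healthy group-average model has no biomass optimum")
    sol$objective
  })
  fcfg <- fvaConfig(gamma = config$gamma, beta = config$beta,
                    biomassRef = bref)

  ranges <- stage("cohort-fva", {
    models <- personalizeCohort(contextModel, cohort, media)
    cohortFva(models, cohortGroups(cohort), fcfg)
  })
  writeFluxRanges(ranges, file.path(outDir, "flux_ranges.tsv"))

  diff <- stage("diff-flux", callPerturbed(ranges, alpha = config$alpha))
  writeDiffFlux(diff, file.path(outDir, "diff_flux.tsv"),
                model = contextModel)
  perturbed <- diff$reaction[diff$perturbed]

  enr <- stage("enrichment", {
    universe <- contextModel@reactions$id
    list(pathway = enrich(perturbed,
                          reactionSets(contextModel, "pathway"), universe),
         metabolite = enrich(perturbed,
                             reactionSets(contextModel, "metabolite"),
                             universe),
         compartment = compartmentSummary(perturbed, contextModel))
  })
  for (nm in names(enr))
    utils::write.table(enr[[nm]],
                       file.path(outDir, paste0("enrichment_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  network <- components <- NULL
  if (length(perturbed)) {
    network <- stage("metabolite-network", {
      net <- buildNetwork(perturbed, contextModel, config$currency)
      filterSignificant(net, enr$metabolite, config$networkQ)
    })
    components <- networkComponents(network)
    writeSif(network, file.path(outDir, "network.sif"))
    writeGraphml(network, file.path(outDir, "network.graphml"))
    writeLines(vapply(components, paste, character(1), collapse = ","),
               file.path(outDir, "components.txt"))
  }

  markers <- stage("markers", {
    hr <- fva(havg, fcfg)
    dr <- fva(davg, fcfg)
    cand <- detectShiftedExchanges(hr, dr, contextModel,
                                   delta = config$delta)
    if (length(cand) < 1) return(list(panel = NULL, metrics = NULL))
    tab <- buildFeatureTable(ranges, cand, positive = config$diseaseLabel)
    full <- evaluateSvm(tab, folds = config$folds,
                        repeats = config$cvRepeats, seed = config$seed)
    runs <- lapply(seq_len(config$gaRepeats), function(r) {
      cfg <- config$ga
      cfg$seed <- config$seed + r
      gaSelect(tab, cfg)$features
    })
    panel <- rankFeatures(runs, colnames(tab$x),
                          threshold = config$frequencyThreshold)
    top <- if (length(topRanked(panel)))
      evaluateSvm(tab, features = c(paste0(topRanked(panel), "|min"),
                                    paste0(topRanked(panel), "|max")),
                  folds = config$folds, repeats = config$cvRepeats,
                  seed = config$seed)
    else NULL
    panel@cvMetrics <- list(full = full$mean,
                            topRanked = if (!is.null(top)) top$mean)
    list(panel = panel, candidates = cand, table = tab,
         metrics = list(full = full, topRanked = top))
  })
  if (!is.null(markers$panel)) {
    jsonlite::write_json(
      list(candidates = markers$candidates,
           reactionFrequency = as.list(reactionFrequency(markers$panel)),
           topRanked = topRanked(markers$panel),
           cvMetrics = markers$panel@cvMetrics),
      file.path(outDir, "markers.json"), auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package = as.character(utils::packageVersion("FluxCohort")),
    seed = config$seed,
    parameters = config[c("minCount", "minFraction", "alpha", "networkQ",
                          "beta", "gamma", "delta", "gaRepeats", "folds",
                          "cvRepeats", "frequencyThreshold")],
    contextModel = st,
    nPerturbed = length(perturbed))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, contextModel = contextModel,
                 ranges = ranges, diff = diff, enrichment = enr,
                 network = network, components = components,
                 panel = markers$panel, markers = markers))
}
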