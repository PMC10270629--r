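#' Detect exchange reactions with shifted flux ranges
#'
#' Compares the FVA interval of every exchange reaction between the
#' healthy and disease group-average models. Interval similarity is the
#' Jaccard index \eqn{J = |h \cap d| / |h \cup d|}; a reaction is a marker
#' candidate when \eqn{J < 1 - \delta}. Degenerate (point) intervals are
#' compared by endpoint distance against the absolute tolerance.
#'
#' @param hRanges,dRanges [fva()] results for the healthy and disease
#'   group-average models (identical configuration and reaction sets).
#' @param model the template \linkS4class{MetabolicModel} (identifies
#'   exchange reactions).
#' @param delta dissimilarity threshold in [0, 1), default 0.1.
#' @param tol absolute tolerance for point intervals.
#' @return character vector of candidate exchange reaction ids.
#' @export
detectShiftedExchanges <- function(hRanges, dRanges, model, delta = 0.1,
                                   tol = 1e-6) {
  if (!identical(hRanges$reaction, dRanges$reaction))
    stop("healthy and disease FVA tables cover different reactions")
  exch <- model@reactions$id[model@reactions$kind == "exchange"]
  keep <- hRanges$reaction %in% exch
  h <- hRanges[keep, ]; d <- dRanges[keep, ]
  shifted <- mapply(function(h1, h2, d1, d2) {
    inter <- max(0, min(h2, d2) - max(h1, d1))
    union <- max(h2, d2) - min(h1, d1)
    if (union < tol)   # two point intervals
      return(max(abs(h1 - d1), abs(h2 - d2)) > tol)
    (inter / union) < 1 - delta
  }, h$min, h$max, d$min, d$max)
  h$reaction[shifted]
}

#' Classifier metrics from a confusion matrix
#'
#' Disease is the positive class: accuracy = (TP+TN)/total, sensitivity =
#' TP/(TP+FN), specificity = TN/(TN+FP). A metric with a zero denominator
#' is \code{NA}, never 0.
#'
#' @param cm named numeric with elements \code{TP}, \code{TN}, \code{FP},
#'   \code{FN} (non-negative counts, positive total).
#' @return list with \code{accuracy}, \code{sensitivity},
#'   \code{specificity}.
#' @export
classMetrics <- function(cm) {
  cm <- unlist(cm)[c("TP", "TN", "FP", "FN")]
  if (any(is.na(cm))) stop("confusion matrix needs TP, TN, FP, FN")
  if (any(cm < 0)) stop("negative counts in confusion matrix")
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sens_den <- cm[["TP"]] + cm[["FN"]]
  spec_den <- cm[["TN"]] + cm[["FP"]]
  list(accuracy = (cm[["TP"]] + cm[["TN"]]) / total,
       sensitivity = if (sens_den > 0) cm[["TP"]] / sens_den else NA_real_,
       specificity = if (spec_den > 0) cm[["TN"]] / spec_den else NA_real_)
}

#' Assemble an SVM feature table from cohort flux ranges
#'
#' Features are the per-individual minimum and maximum FVA fluxes of the
#' candidate reactions, named \code{"<reaction>|min"} and
#' \code{"<reaction>|max"}.
#'
#' @param ranges tidy data.frame from [cohortFva()] (infeasible samples
#'   already excluded).
#' @param reactions candidate reaction ids.
#' @param positive label of the positive (disease) class; default the
#'   second group level encountered.
#' @return list of class \code{FeatureTable}: \code{x} (sample x feature
#'   matrix), \code{labels} (named character), \code{positive}.
#' @export
buildFeatureTable <- function(ranges, reactions, positive = NULL) {
  sub <- ranges[ranges$reaction %in% reactions, ]
  samples <- unique(sub$sample)
  x <- matrix(NA_real_, length(samples), 2 * length(reactions),
              dimnames = list(samples,
                              c(paste0(reactions, "|min"),
                                paste0(reactions, "|max"))))
  for (r in reactions) {
    rr <- sub[sub$reaction == r, ]
    x[rr$sample, paste0(r, "|min")] <- rr$min
    x[rr$sample, paste0(r, "|max")] <- rr$max
  }
  if (anyNA(x)) stop("missing flux values for some sample/reaction pairs")
  labels <- stats::setNames(
    sub$group[match(samples, sub$sample)], samples)
  if (is.null(positive)) positive <- unique(labels)[2]
  structure(list(x = x, labels = labels, positive = positive),
            class = "FeatureTable")
}

.stratifiedFolds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

.svmFoldRun <- function(x, y, fold, folds, positive) {
  cm <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (!any(fold == f)) next
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
    fit <- e1071::svm(xs[tr, , drop = FALSE], y[tr],
                      kernel = "polynomial", degree = 2, coef0 = 1,
                      cost = 1, scale = FALSE)
    pred <- stats::predict(fit, xs[!tr, , drop = FALSE])
    truth <- y[!tr]
    cm["TP"] <- cm["TP"] + sum(pred == positive & truth == positive)
    cm["TN"] <- cm["TN"] + sum(pred != positive & truth != positive)
    cm["FP"] <- cm["FP"] + sum(pred == positive & truth != positive)
    cm["FN"] <- cm["FN"] + sum(pred != positive & truth == positive)
  }
  cm
}

#' Evaluate an SVM classifier by repeated stratified cross-validation
#'
#' Polynomial-kernel SVM of degree 2 (C = 1, coef0 = 1), evaluated by
#' stratified k-fold cross-validation: per fold, features are z-score
#' standardized with statistics fit on the training folds only; test
#' predictions are pooled into one confusion matrix per repeat.
#'
#' @param table a [buildFeatureTable()] result.
#' @param features feature names to use (default all).
#' @param folds number of folds, default 10.
#' @param repeats number of repetitions with fresh fold assignments.
#' @param seed optional RNG seed; identical seeds give identical fold
#'   assignments and metrics.
#' @return list with \code{mean} (accuracy/sensitivity/specificity
#'   averaged over repeats), \code{perRepeat} (data.frame), and
#'   \code{confusion} (counts summed over repeats).
#' @export
evaluateSvm <- function(table, features = NULL, folds = 10, repeats = 1,
                        seed = NULL) {
  if (is.null(features)) features <- colnames(table$x)
  if (!length(features)) stop("empty feature subset")
  missing <- setdiff(features, colnames(table$x))
  if (length(missing))
    stop("features absent from the table: ",
         paste(missing, collapse = ", "))
  y <- factor(table$labels)
  if (nlevels(y) < 2) stop("labels contain a single class")
  x <- table$x[, features, drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  per <- vector("list", repeats)
  cmTotal <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (r in seq_len(repeats)) {
    fold <- .stratifiedFolds(as.character(y), folds)
    cm <- .svmFoldRun(x, y, fold, folds, table$positive)
    m <- classMetrics(cm)
    per[[r]] <- data.frame(repeat. = r, accuracy = m$accuracy,
                           sensitivity = m$sensitivity,
                           specificity = m$specificity)
    cmTotal <- cmTotal + cm
  }
  per <- do.call(rbind, per)
  list(mean = list(accuracy = mean(per$accuracy),
                   sensitivity = mean(per$sensitivity),
                   specificity = mean(per$specificity)),
       perRepeat = per, confusion = cmTotal)
}

#' Genetic-algorithm configuration for wrapper feature selection
#'
#' Defaults follow the common wrapper setup: population of 300 binary
#' chromosomes, at most 100 generations, early stop once the best fitness
#' (cross-validated SVM accuracy) reaches 0.90.
#'
#' @param populationSize chromosomes per generation (default 300).
#' @param generations generation cap (default 100).
#' @param fitnessStop early-stopping fitness (default 0.90).
#' @param crossoverRate per-pair uniform-crossover probability.
#' @param mutationRate per-bit flip probability (default 1/L).
#' @param tournamentSize tournament selection size.
#' @param elitism number of best chromosomes copied unchanged.
#' @param fitnessFolds CV folds used inside the fitness function.
#' @param seed optional RNG seed.
#' @return list of class \code{GaConfig}.
#' @export
gaConfig <- function(populationSize = 300, generations = 100,
                     fitnessStop = 0.90, crossoverRate = 0.8,
                     mutationRate = NULL, tournamentSize = 2,
                     elitism = 1, fitnessFolds = 10, seed = NULL) {
  stopifnot(populationSize > 0, generations > 0,
            crossoverRate >= 0, crossoverRate <= 1,
            is.null(mutationRate) ||
              (mutationRate >= 0 && mutationRate <= 1))
  structure(list(populationSize = populationSize,
                 generations = generations, fitnessStop = fitnessStop,
                 crossoverRate = crossoverRate,
                 mutationRate = mutationRate,
                 tournamentSize = tournamentSize, elitism = elitism,
                 fitnessFolds = fitnessFolds, seed = seed),
            class = "GaConfig")
}

#' Binary GA wrapper feature selection around the SVM
#'
#' Chromosomes are bit vectors over the feature set (1 = feature
#' included). Fitness is the stratified cross-validated accuracy of the
#' SVM on the selected features, computed against one fold assignment
#' fixed per run so chromosome comparisons are consistent; the all-zero
#' chromosome has fitness 0 and is never sent to the SVM. Evolution uses
#' tournament selection, uniform crossover, per-bit mutation and elitism,
#' and stops when the best fitness reaches \code{fitnessStop} or the
#' generation cap.
#'
#' @param table a [buildFeatureTable()] result.
#' @param config a [gaConfig()].
#' @return list with \code{features} (selected feature names),
#'   \code{chromosome} (logical), \code{fitness}, \code{trace}
#'   (per-generation best fitness), \code{generations}.
#' @export
gaSelect <- function(table, config = gaConfig()) {
  L <- ncol(table$x)
  if (L < 2) stop("feature selection needs at least 2 features")
  if (!is.null(config$seed)) set.seed(config$seed)
  y <- factor(table$labels)
  if (nlevels(y) < 2) stop("labels contain a single class")
  mut <- if (is.null(config$mutationRate)) 1 / L else config$mutationRate
  fold <- .stratifiedFolds(as.character(y), config$fitnessFolds)
  cache <- new.env(parent = emptyenv())
  fitness <- function(chrom) {
    if (!any(chrom)) return(0)
    key <- rawToChar(as.raw(44L + chrom))
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    cm <- .svmFoldRun(table$x[, chrom, drop = FALSE], y, fold,
                      config$fitnessFolds, table$positive)
    acc <- classMetrics(cm)$accuracy
    assign(key, acc, envir = cache)
    acc
  }
  P <- config$populationSize
  pop <- matrix(stats::runif(P * L) < 0.5, P, L)
  trace <- numeric(0)
  repeat {
    fit <- apply(pop, 1, fitness)
    best <- which.max(fit)
    trace <- c(trace, fit[best])
    if (fit[best] >= config$fitnessStop ||
        length(trace) >= config$generations) {
      return(list(features = colnames(table$x)[pop[best, ]],
                  chromosome = pop[best, ], fitness = fit[best],
                  trace = trace, generations = length(trace)))
    }
    nextPop <- matrix(FALSE, P, L)
    nElite <- min(config$elitism, P)
    if (nElite > 0)
      nextPop[seq_len(nElite), ] <-
        pop[order(-fit)[seq_len(nElite)], , drop = FALSE]
    i <- nElite + 1L
    while (i <= P) {
      p1 <- pop[.tournament(fit, config$tournamentSize), ]
      p2 <- pop[.tournament(fit, config$tournamentSize), ]
      if (stats::runif(1) < config$crossoverRate) {
        mask <- stats::runif(L) < 0.5
        c1 <- ifelse(mask, p1, p2)
        c2 <- ifelse(mask, p2, p1)
      } else {
        c1 <- p1; c2 <- p2
      }
      c1 <- xor(c1, stats::runif(L) < mut)
      c2 <- xor(c2, stats::runif(L) < mut)
      nextPop[i, ] <- c1
      if (i + 1L <= P) nextPop[i + 1L, ] <- c2
      i <- i + 2L
    }
    pop <- nextPop
  }
}

.tournament <- function(fit, size) {
  cand <- sample.int(length(fit), min(size, length(fit)),
                     replace = length(fit) < size)
  cand[which.max(fit[cand])]
}

#' Rank features by GA selection frequency
#'
#' Runs of the GA yield one feature subset each; a feature's frequency is
#' the percentage of subsets containing it, and a reaction's frequency is
#' the larger of its min-flux and max-flux features. Reactions with
#' frequency at or above \code{threshold} form the top-ranked marker set.
#'
#' @param subsets list of feature-name vectors (e.g.
#'   \code{lapply(runs, `[[`, "features")}).
#' @param features the full feature universe (column names of the table).
#' @param threshold top-rank frequency threshold in percent (default 80).
#' @return a \linkS4class{MarkerPanel}.
#' @export
rankFeatures <- function(subsets, features, threshold = 80) {
  stopifnot(length(subsets) >= 1)
  counts <- vapply(features, function(f)
    sum(vapply(subsets, function(s) f %in% s, logical(1))), numeric(1))
  freq <- 100 * counts / length(subsets)
  rxns <- sub("\\|(min|max)$", "", features)
  rxnFreq <- vapply(split(freq, rxns), max, numeric(1))
  new("MarkerPanel",
      candidates = sort(unique(rxns)),
      featureFrequency = freq,
      reactionFrequency = rxnFreq,
      topRanked = sort(names(rxnFreq)[rxnFreq >= threshold]),
      threshold = threshold,
      nRepeats = length(subsets),
      cvMetrics = list())
}

#' @rdname MarkerPanel-class
#' @param object a \linkS4class{MarkerPanel}
#' @export
topRanked <- function(object) object@topRanked

#' @rdname MarkerPanel-class
#' @export
reactionFrequency <- function(object) object@reactionFrequency

setMethod("show", "MarkerPanel", function(object) {
  cat("MarkerPanel:", length(object@candidates), "candidate reactions,",
      length(object@topRanked), "top-ranked (frequency >=",
      object@threshold, "% over", object@nRepeats, "GA repeats)\n")
  if (length(object@topRanked))
    cat("  top-ranked:", paste(object@topRanked, collapse = ", "), "\n")
})

#' Validate a marker panel on an external cohort
#'
#' Evaluates the SVM restricted to the panel's top-ranked features (both
#' min and max fluxes of each top-ranked reaction) on an external feature
#' table, optionally excluding a subgroup of samples (e.g. a confounded
#' normoglycemic-but-insulin-resistant subgroup).
#'
#' @param panel a \linkS4class{MarkerPanel}.
#' @param table external [buildFeatureTable()] result; must contain the
#'   panel's features.
#' @param exclude sample ids to drop before evaluation.
#' @param folds,repeats,seed passed to [evaluateSvm()].
#' @return [evaluateSvm()] result.
#' @export
validatePanel <- function(panel, table, exclude = NULL, folds = 10,
                          repeats = 1, seed = NULL) {
  feats <- c(paste0(panel@topRanked, "|min"),
             paste0(panel@topRanked, "|max"))
  missing <- setdiff(feats, colnames(table$x))
  if (length(missing))
    stop("panel features absent from the external table: ",
         paste(missing, collapse = ", "))
  if (!is.null(exclude)) {
    keep <- setdiff(rownames(table$x), exclude)
    table <- structure(list(x = table$x[keep, , drop = FALSE],
                            labels = table$labels[keep],
                            positive = table$positive),
                       class = "FeatureTable")
  }
  evaluateSvm(table, features = feats, folds = folds, repeats = repeats,
              seed = seed)
}
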