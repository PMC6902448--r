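# End-to-end convenience layer: train a phyloclassifier from an aligned
# complement + clade map, classify query complements, and persist models.

#' Train a phyloclassifier from an alignment and clade map
#'
#' Runs the full training pipeline: clade partitioning, leakage-free
#' training score matrix (per-genome leave-one-out logo estimation),
#' standardizer fit, and network training.  Full-data clade logos are
#' returned for scoring query genomes.
#'
#' @param aln a [SprinzlAlignment-class] with functional types assigned.
#' @param map a [CladeMap-class].
#' @param spec a [NetworkSpec-class].
#' @inheritParams estimateCladeLogos
#' @return A list with `model` (a [TrainedPhyloclassifier-class] carrying
#'   the standardizer), `logos` (full-data [FunctionLogo-class] list),
#'   `scores` (the training score matrix) and `partition`.
#' @export
trainPhyloclassifier <- function(aln, map, spec = networkSpec(),
                                 background = "clade_frequencies",
                                 correction = "miller_madow") {
  part <- partitionByClade(aln, map)
  S <- buildTrainingMatrix(part, background, correction)
  std <- fitStandardizer(S)
  model <- trainNetwork(applyStandardizer(S, std), attr(S, "labels"), spec,
                        standardizer = std)
  list(model = model,
       logos = estimateCladeLogos(part, background, correction),
       scores = S, partition = part)
}

#' Classify query genome complements
#'
#' Scores query complements against the training logos, standardizes with
#' the model's standardizer and returns classification reports.
#'
#' @param aln query [SprinzlAlignment-class] (one or more genomes) with
#'   functional types assigned.
#' @param model a [TrainedPhyloclassifier-class] carrying a standardizer.
#' @param logos the full-data training logos (as returned by
#'   [trainPhyloclassifier()]).
#' @param threshold equivocality threshold (default 0.8).
#' @return A classification report data.frame, see
#'   [predictProbabilities()].
#' @export
classifyGenomes <- function(aln, model, logos, threshold = 0.8) {
  S <- scoreGenomes(aln, logos)
  predictProbabilities(model, S, standardize = TRUE, threshold = threshold)
}

#' Save / load a trained phyloclassifier
#'
#' Persists the model (spec, weights, standardizer, clade order) as a
#' versioned JSON archive with full numeric precision.
#'
#' @param model a [TrainedPhyloclassifier-class].
#' @param path file path.
#' @return `writePhyloclassifier()` returns `path` invisibly;
#'   `readPhyloclassifier()` returns the restored
#'   [TrainedPhyloclassifier-class].
#' @export
writePhyloclassifier <- function(model, path) {
  stopifnot(is(model, "TrainedPhyloclassifier"))
  std <- model@standardizer
  obj <- list(
    format = "tRNAcif-phyloclassifier",
    version = 1L,
    cladeOrder = model@cladeOrder,
    spec = list(hiddenLayers = model@spec@hiddenLayers,
                l2Alpha = model@spec@l2Alpha,
                maxEpochs = model@spec@maxEpochs,
                tol = model@spec@tol, seed = model@spec@seed),
    weights = lapply(model@weights, function(p)
      list(W = p$W, b = p$b)),
    standardizer = if (is.null(std)) NULL else
      list(center = std@center, scale = std@scale, nTrain = std@nTrain,
           cladeOrder = std@cladeOrder),
    trainingLog = model@trainingLog)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writePhyloclassifier
#' @export
readPhyloclassifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "tRNAcif-phyloclassifier"))
    stop("not a phyloclassifier archive: ", path)
  num <- function(x) as.numeric(unlist(x))
  chr <- function(x) as.character(unlist(x))
  spec <- networkSpec(as.integer(unlist(obj$spec$hiddenLayers)),
                      num(obj$spec$l2Alpha), as.integer(obj$spec$maxEpochs),
                      num(obj$spec$tol), as.integer(obj$spec$seed))
  weights <- lapply(obj$weights, function(p)
    list(W = do.call(rbind, lapply(p$W, num)), b = num(p$b)))
  cladeOrder <- chr(obj$cladeOrder)
  std <- NULL
  if (!is.null(obj$standardizer)) {
    so <- chr(obj$standardizer$cladeOrder)
    std <- new("ScoreStandardizer",
               center = setNames(num(obj$standardizer$center), so),
               scale = setNames(num(obj$standardizer$scale), so),
               nTrain = as.integer(obj$standardizer$nTrain),
               cladeOrder = so)
  }
  new("TrainedPhyloclassifier", spec = spec, weights = weights,
      standardizer = std, cladeOrder = cladeOrder,
      trainingLog = list(loss = num(obj$trainingLog$loss),
                         evaluations = num(obj$trainingLog$evaluations),
                         converged = isTRUE(obj$trainingLog$converged)))
}
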