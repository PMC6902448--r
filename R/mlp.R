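# Multilayer-perceptron phyloclassifier: training, prediction, LOOCV and
# architecture search on standardized clade-score vectors.

.layerSizes <- function(spec, d, K) c(d, spec@hiddenLayers, K)

# Glorot-uniform weight initialization, biases at zero; deterministic
# given the seed.
.mlpInit <- function(sizes, seed) {
  .withSeed(seed, {
    lapply(seq_len(length(sizes) - 1L), function(l) {
      fin <- sizes[l]; fout <- sizes[l + 1L]
      bd <- sqrt(6 / (fin + fout))
      list(W = matrix(runif(fin * fout, -bd, bd), fin, fout),
           b = numeric(fout))
    })
  })
}

.flattenWeights <- function(params)
  unlist(lapply(params, function(p) c(p$W, p$b)), use.names = FALSE)

.unflattenWeights <- function(theta, sizes) {
  out <- vector("list", length(sizes) - 1L)
  pos <- 0L
  for (l in seq_along(out)) {
    fin <- sizes[l]; fout <- sizes[l + 1L]
    out[[l]] <- list(W = matrix(theta[pos + seq_len(fin * fout)], fin, fout),
                     b = theta[pos + fin * fout + seq_len(fout)])
    pos <- pos + fin * fout + fout
  }
  out
}

# Forward pass to softmax probabilities.
.mlpForward <- function(params, X) {
  A <- X
  L <- length(params)
  for (l in seq_len(L)) {
    Z <- A %*% params[[l]]$W
    Z <- sweep(Z, 2L, params[[l]]$b, "+")
    A <- if (l < L) pmax(Z, 0) else Z
  }
  A <- A - apply(A, 1L, max)
  P <- exp(A)
  P / rowSums(P)
}

#' Train the phyloclassifier network
#'
#' Minimizes the L2-penalized softmax cross-entropy of a ReLU multilayer
#' perceptron on standardized score vectors by full-batch L-BFGS, running
#' at most `maxEpochs` iterations and stopping early once the
#' per-iteration loss decrease falls below `tol`.  Training is
#' deterministic given the spec's seed, which governs weight
#' initialization only.
#'
#' @param X standardized score matrix (genomes x clades).
#' @param y clade label per row (character or factor); at least two
#'   distinct classes are required unless an explicit `cladeOrder` fixes
#'   the output space.
#' @param spec a [NetworkSpec-class].
#' @param standardizer optional [ScoreStandardizer-class] to store with
#'   the model.
#' @param cladeOrder optional explicit output clade order; labels must be
#'   a subset.  Used by cross-validation folds whose training rows may not
#'   cover every clade.
#' @return A [TrainedPhyloclassifier-class].
#' @examples
#' S <- rbind(matrix(rnorm(20, 2), 10, 2), matrix(rnorm(20, -2), 10, 2))
#' colnames(S) <- c("A", "B")
#' fit <- trainNetwork(S, rep(c("A", "B"), each = 10), networkSpec(8))
#' @export
trainNetwork <- function(X, y, spec = networkSpec(), standardizer = NULL,
                         cladeOrder = NULL) {
  stopifnot(is(spec, "NetworkSpec"))
  y <- as.character(y)
  if (is.null(cladeOrder)) {
    cladeOrder <- if (!is.null(colnames(X)) && all(y %in% colnames(X)))
      colnames(X) else sort(unique(y))
    if (length(unique(y)) < 2L)
      stop("training labels contain a single class")
  }
  if (nrow(X) != length(y)) stop("rows of X must match labels")
  yIdx <- match(y, cladeOrder)
  if (anyNA(yIdx)) stop("labels outside the clade order")
  sizes <- .layerSizes(spec, ncol(X), length(cladeOrder))
  theta0 <- .flattenWeights(.mlpInit(sizes, spec@seed))
  cache <- new.env(parent = emptyenv())
  cache$theta <- NULL
  evalAt <- function(th) {
    if (is.null(cache$theta) || !identical(th, cache$theta)) {
      r <- .mlpLossGrad(th, X, yIdx - 1L, sizes, spec@l2Alpha)
      cache$theta <- th
      cache$value <- r$value
      cache$grad <- as.numeric(r$gradient)
    }
    invisible(NULL)
  }
  fn <- function(th) { evalAt(th); cache$value }
  gr <- function(th) { evalAt(th); cache$grad }
  opt <- optim(theta0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = spec@maxEpochs,
                              factr = spec@tol / .Machine$double.eps))
  new("TrainedPhyloclassifier", spec = spec,
      weights = .unflattenWeights(opt$par, sizes),
      standardizer = standardizer, cladeOrder = cladeOrder,
      trainingLog = list(loss = opt$value,
                         evaluations = unname(opt$counts[1L]),
                         converged = opt$convergence == 0L))
}

#' Classification probability vectors
#'
#' Runs standardized score vectors through the trained network's soft-max
#' output.  The top clade is the arg-max; exact ties are broken by clade
#' order (first wins) and reported via a message.
#'
#' @param model a [TrainedPhyloclassifier-class].
#' @param scores standardized score matrix (or single named vector) with
#'   clades matching the model's `cladeOrder`; set `standardize = TRUE` to
#'   apply the model's stored standardizer to raw scores first.
#' @param standardize apply the stored standardizer (default `FALSE`).
#' @param threshold equivocality threshold on the top probability
#'   (default 0.8).
#' @return A data.frame with one row per genome: `genome_id`, `topClade`,
#'   `topProbability`, `equivocal`, and one probability column per clade;
#'   probabilities are non-negative and sum to 1 per row.
#' @export
predictProbabilities <- function(model, scores, standardize = FALSE,
                                 threshold = 0.8) {
  stopifnot(is(model, "TrainedPhyloclassifier"))
  if (is.null(dim(scores)))
    scores <- matrix(scores, 1L, dimnames = list("query", names(scores)))
  if (standardize) {
    if (is.null(model@standardizer))
      stop("model carries no standardizer")
    scores <- applyStandardizer(scores, model@standardizer)
  }
  if (!is.null(colnames(scores)) &&
      !identical(colnames(scores), model@cladeOrder))
    stop("clade order of scores does not match the model")
  P <- .mlpForward(model@weights, scores)
  colnames(P) <- model@cladeOrder
  topIdx <- apply(P, 1L, which.max)
  ties <- apply(P, 1L, function(r) sum(r == max(r)) > 1L)
  if (any(ties))
    message(sum(ties), " tie(s) broken by clade order")
  ids <- rownames(scores)
  if (is.null(ids)) ids <- paste0("genome", seq_len(nrow(P)))
  out <- data.frame(genome_id = ids,
                    topClade = model@cladeOrder[topIdx],
                    topProbability = P[cbind(seq_len(nrow(P)), topIdx)],
                    stringsAsFactors = FALSE)
  out$equivocal <- assessEquivocality(out, threshold)
  cbind(out, as.data.frame(P, check.names = FALSE))
}

#' Equivocality of classifications
#'
#' A classification is equivocal (interpreted as "none-of-the-above") when
#' its maximum classification probability falls below the threshold.
#'
#' @param report a data.frame with a `topProbability` column (as from
#'   [predictProbabilities()]), or a numeric vector of top probabilities.
#' @param threshold probability threshold (default 0.80).
#' @return Logical vector: `TRUE` where the classification is equivocal.
#' @examples
#' assessEquivocality(c(0.9998, 0.79), threshold = 0.8)
#' @export
assessEquivocality <- function(report, threshold = 0.8) {
  p <- if (is.data.frame(report)) report$topProbability else report
  p < threshold
}

#' Leave-one-out cross-validation on cached score vectors
#'
#' For each genome, refits the standardizer and the network on all other
#' genomes' score vectors and classifies the held-out vector.  Optionally
#' oversamples the training rows to clade balance within each fold.
#'
#' @param scores training score matrix (genomes x clades), typically from
#'   [buildTrainingMatrix()].
#' @param labels true clade per row; defaults to the matrix's `labels`
#'   attribute.
#' @param spec a [NetworkSpec-class].
#' @param balance clade-balancing mode: `"none"` (default), `"fold"`
#'   (oversample the training rows to clade balance within each fold;
#'   leakage-free) or `"pre"` (oversample the whole vector set once with
#'   [oversampleBalance()] and cross-validate over the balanced set,
#'   duplicates included — the workflow that produces balanced-model
#'   summary metrics; duplicated vectors share information across folds,
#'   so these metrics characterize the balanced training set rather than
#'   generalization).  `TRUE` is accepted as `"fold"`.
#' @param threshold equivocality threshold passed through to the reports.
#' @return A list with `accuracy` (fraction of genomes whose top clade
#'   equals their true clade) and `outcomes` (data.frame of genome, true
#'   clade, predicted clade, top probability, correctness).
#' @seealso [loocvAccuracy()] for the full pipeline from an alignment.
#' @export
loocvFromScores <- function(scores, labels = attr(scores, "labels"),
                            spec = networkSpec(), balance = "none",
                            threshold = 0.8) {
  stopifnot(nrow(scores) == length(labels))
  if (isTRUE(balance)) balance <- "fold"
  if (isFALSE(balance)) balance <- "none"
  balance <- match.arg(balance, c("none", "fold", "pre"))
  labels <- as.character(labels)
  if (balance == "pre") {
    bal <- oversampleBalance(scores, labels, seed = spec@seed)
    scores <- bal$scores
    labels <- bal$labels
  }
  n <- nrow(scores)
  pred <- character(n)
  prob <- numeric(n)
  for (i in seq_len(n)) {
    Str <- scores[-i, , drop = FALSE]
    ytr <- labels[-i]
    if (balance == "fold") {
      bal <- oversampleBalance(Str, ytr, seed = spec@seed + i)
      Str <- bal$scores
      ytr <- bal$labels
    }
    if (nrow(Str) >= 2L) {
      std <- fitStandardizer(Str)
      Str <- applyStandardizer(Str, std)
      held <- applyStandardizer(scores[i, , drop = FALSE], std)
    } else {
      held <- scores[i, , drop = FALSE]
    }
    fit <- trainNetwork(Str, ytr, spec,
                        cladeOrder = sort(unique(labels)))
    rep1 <- predictProbabilities(fit, held, threshold = threshold)
    pred[i] <- rep1$topClade
    prob[i] <- rep1$topProbability
  }
  outcomes <- data.frame(genome_id = rownames(scores), trueClade = labels,
                         predicted = pred, topProbability = prob,
                         correct = pred == labels, stringsAsFactors = FALSE)
  list(accuracy = mean(outcomes$correct), outcomes = outcomes)
}

#' Leave-one-out cross-validation from an alignment
#'
#' Builds the leakage-free training score matrix (each genome scored
#' against logos estimated without its own genes) and runs
#' [loocvFromScores()] on it.
#'
#' @param aln a [SprinzlAlignment-class] with functional types assigned.
#' @param map a [CladeMap-class].
#' @param spec a [NetworkSpec-class].
#' @inheritParams estimateCladeLogos
#' @param balance oversample training rows to clade balance per fold.
#' @return As [loocvFromScores()], plus the `scores` matrix used.
#' @export
loocvAccuracy <- function(aln, map, spec = networkSpec(),
                          background = "clade_frequencies",
                          correction = "miller_madow", balance = FALSE) {
  part <- partitionByClade(aln, map)
  S <- buildTrainingMatrix(part, background, correction)
  res <- loocvFromScores(S, spec = spec, balance = balance)
  res$scores <- S
  res
}

#' Exhaustive architecture search by LOOCV accuracy
#'
#' Evaluates every hidden-layer architecture in the given bounds
#' (all width combinations for each layer count) by leave-one-out
#' cross-validated accuracy on cached score vectors.  Ties are broken by
#' fewest parameters, then fewest layers.
#'
#' @param scores training score matrix (genomes x clades).
#' @param labels true clade per row; defaults to the `labels` attribute.
#' @param layers layer counts to consider (default `1:4`).
#' @param widths widths each layer may take (default `8:16`).
#' @param l2Alpha,maxEpochs,tol,seed passed to [networkSpec()] for every
#'   candidate.
#' @return A list with `best` (the selected [NetworkSpec-class]) and
#'   `results` (data.frame of architecture, layer count, parameter count,
#'   accuracy).
#' @export
searchArchitecture <- function(scores, labels = attr(scores, "labels"),
                               layers = 1:4, widths = 8:16,
                               l2Alpha = 0.01, maxEpochs = 2000L,
                               tol = 1e-4, seed = 1L) {
  if (length(layers) < 1L || length(widths) < 1L)
    stop("architecture bounds must be non-empty")
  K <- length(unique(as.character(labels)))
  d <- ncol(scores)
  cands <- list()
  for (L in layers) {
    grid <- do.call(expand.grid, rep(list(widths), L))
    for (r in seq_len(nrow(grid)))
      cands[[length(cands) + 1L]] <- as.integer(unlist(grid[r, ]))
  }
  nParams <- vapply(cands, function(h) {
    sizes <- c(d, h, K)
    sum((sizes[-length(sizes)] + 1L) * sizes[-1L])
  }, numeric(1))
  acc <- vapply(cands, function(h) {
    spec <- networkSpec(h, l2Alpha, maxEpochs, tol, seed)
    loocvFromScores(scores, labels, spec)$accuracy
  }, numeric(1))
  results <- data.frame(
    architecture = vapply(cands, paste, "", collapse = "x"),
    layers = vapply(cands, length, integer(1)),
    parameters = nParams, accuracy = acc, stringsAsFactors = FALSE)
  ord <- order(-results$accuracy, results$parameters, results$layers)
  best <- cands[[ord[1L]]]
  list(best = networkSpec(best, l2Alpha, maxEpochs, tol, seed),
       results = results)
}
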