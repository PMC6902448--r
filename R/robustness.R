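# Robustness battery: one-vs-all confusion metrics, label-permutation
# null, alignment-site bootstrap, leave-clade-out variants and
# oversampling balance.

#' One-vs-all confusion metrics
#'
#' Builds the true x predicted confusion matrix and computes, per clade
#' one-vs-all, precision `tp / (tp + fp)`, recall `tp / (tp + fn)` and
#' balanced accuracy `(TPR + TNR) / 2`, plus overall accuracy.  A
#' precision denominator of zero yields 0 (reported via a message).
#'
#' @param truth true clade labels.
#' @param predicted predicted clade labels (same length).
#' @param labels clade label universe (default: union of both).
#' @return A [ConfusionSummary-class].
#' @examples
#' confusionMetrics(c("A", "A", "B"), c("A", "B", "B"))
#' @export
confusionMetrics <- function(truth, predicted,
                             labels = sort(unique(c(truth, predicted)))) {
  if (length(truth) == 0L) stop("empty label input")
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  m <- table(factor(truth, labels), factor(predicted, labels))
  m <- unclass(m)
  names(dimnames(m)) <- c("true", "predicted")
  total <- sum(m)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  tn <- total - tp - fp - fn
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  if (any(tp + fp == 0))
    message("precision denominator 0 for clade(s) ",
            paste(labels[tp + fp == 0], collapse = ", "), "; reported as 0")
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  tnr <- ifelse(tn + fp > 0, tn / (tn + fp), 0)
  perClade <- data.frame(precision = prec, recall = rec,
                         balancedAccuracy = (rec + tnr) / 2,
                         row.names = labels)
  new("ConfusionSummary", confusion = m, perClade = perClade,
      accuracy = sum(tp) / total)
}

#' Label-permutation null of LOOCV accuracy
#'
#' Tests the significance of the observed leave-one-out cross-validated
#' accuracy by permuting clade labels over training genomes and recording
#' the LOOCV accuracy of each permuted replicate.  The p-value is the
#' positively biased permutation estimator `(b + 1) / (B + 1)` with
#' `b = #\{null >= observed\}`.
#'
#' Two permutation schemes are available.  `"score_labels"` permutes the
#' labels over cached per-genome score vectors and retrains per fold;
#' it is cheap but ignores that the leave-one-out score vectors themselves
#' depend on the clade assignment.  `"full_pipeline"` permutes the
#' genome-to-clade assignment and rebuilds the leave-one-out score matrix
#' per replicate before LOOCV, making null replicates exactly exchangeable
#' with the observed statistic; it is the calibrated choice when effect
#' sizes are small, at higher cost.
#'
#' @param scores training score matrix (genomes x clades); for
#'   `"full_pipeline"` give `partition` as well.
#' @param labels true clade per row; defaults to the `labels` attribute.
#' @param spec a [NetworkSpec-class].
#' @param B number of permutation replicates.
#' @param seed RNG seed for the permutations.
#' @param scheme `"score_labels"` (default) or `"full_pipeline"`.
#' @param partition the [CladePartition-class] the scores came from
#'   (required for `"full_pipeline"`).
#' @inheritParams estimateCladeLogos
#' @return A [PermutationNull-class].
#' @export
permutationTest <- function(scores, labels = attr(scores, "labels"),
                            spec = networkSpec(), B = 1000L, seed = 1L,
                            scheme = c("score_labels", "full_pipeline"),
                            partition = NULL,
                            background = "clade_frequencies",
                            correction = "miller_madow") {
  if (B < 1L) stop("B must be >= 1")
  scheme <- match.arg(scheme)
  labels <- as.character(labels)
  observed <- loocvFromScores(scores, labels, spec)$accuracy
  if (scheme == "score_labels") {
    nullAcc <- .withSeed(seed, {
      vapply(seq_len(B), function(b) {
        loocvFromScores(scores, sample(labels), spec)$accuracy
      }, numeric(1))
    })
  } else {
    if (is.null(partition))
      stop("scheme 'full_pipeline' requires the partition")
    genomes <- rownames(scores)
    nullAcc <- .withSeed(seed, {
      vapply(seq_len(B), function(b) {
        permAssign <- setNames(sample(labels), genomes)
        partB <- .repartition(partition, permAssign)
        Sb <- buildTrainingMatrix(partB, background, correction)
        loocvFromScores(Sb, spec = spec)$accuracy
      }, numeric(1))
    })
  }
  p <- (sum(nullAcc >= observed) + 1) / (B + 1)
  new("PermutationNull", observed = observed, nullAccuracies = nullAcc,
      pValue = p, replicates = as.integer(B))
}

# Rebuild a partition under a new genome -> clade assignment covering the
# same genomes (used by the full-pipeline permutation scheme).
.repartition <- function(partition, assignments) {
  aln <- partition@alignment
  gi <- aln@geneInfo
  training <- gi$genome_id %in% names(assignments)
  sets <- split(which(training), assignments[gi$genome_id[training]])
  new("CladePartition", alignment = aln, sets = sets,
      cladeOf = assignments, excluded = partition@excluded)
}

# Resample alignment columns with replacement (same column multiset for
# training and queries); duplicated coordinate labels are disambiguated
# consistently so features keep their coordinate identity.
.resampleColumns <- function(aln, idx) {
  s <- aln@seqs[, idx, drop = FALSE]
  colnames(s) <- make.unique(colnames(aln@seqs)[idx])
  new("SprinzlAlignment", seqs = s, geneInfo = aln@geneInfo)
}

#' Alignment-site bootstrap of phyloclassification
#'
#' Resamples alignment columns with replacement to the original column
#' count (the same resampled column multiset applied to training and
#' query genes), then re-runs the full pipeline per replicate: logo
#' estimation from leave-one-out sets, standardizer and network
#' retraining, and classification of all training genomes (via their
#' leave-one-out score vectors) and query genomes (via full-data logos).
#'
#' @param aln training [SprinzlAlignment-class].
#' @param map a [CladeMap-class].
#' @param spec a [NetworkSpec-class].
#' @param queries optional query [SprinzlAlignment-class] on the same
#'   coordinate frame.
#' @param R number of bootstrap replicates (default 100).
#' @param seed RNG seed.
#' @inheritParams estimateCladeLogos
#' @return A [BootstrapSummary-class]: per-genome clade frequencies over
#'   replicates (rows sum to 1) and, for training genomes, the count of
#'   replicates whose top classification was the true clade.
#' @export
siteBootstrap <- function(aln, map, spec = networkSpec(), queries = NULL,
                          R = 100L, seed = 1L,
                          background = "clade_frequencies",
                          correction = "miller_madow") {
  if (R < 1L) stop("R must be >= 1")
  if (!is.null(queries) &&
      !identical(sprinzlCoordinates(queries), sprinzlCoordinates(aln)))
    stop("queries must share the training alignment's coordinate frame")
  part0 <- partitionByClade(aln, map,
                            queryGenomes = if (is.null(queries)) character(0)
                            else genomeIds(queries))
  C <- ncol(aln@seqs)
  trainGenomes <- names(part0@cladeOf)
  queryGenomes <- if (is.null(queries)) character(0) else genomeIds(queries)
  allGenomes <- c(trainGenomes, queryGenomes)
  cladesAll <- sort(unique(unname(part0@cladeOf)))
  tally <- matrix(0L, length(allGenomes), length(cladesAll),
                  dimnames = list(allGenomes, cladesAll))
  colIdx <- .withSeed(seed, {
    replicate(R, sample.int(C, C, replace = TRUE), simplify = FALSE)
  })
  for (r in seq_len(R)) {
    alnR <- .resampleColumns(aln, colIdx[[r]])
    partR <- new("CladePartition", alignment = alnR, sets = part0@sets,
                 cladeOf = part0@cladeOf, excluded = part0@excluded)
    S <- buildTrainingMatrix(partR, background, correction)
    std <- fitStandardizer(S)
    specR <- networkSpec(spec@hiddenLayers, spec@l2Alpha, spec@maxEpochs,
                         spec@tol, spec@seed + r)
    fit <- trainNetwork(applyStandardizer(S, std), attr(S, "labels"), specR,
                        standardizer = std)
    rep1 <- predictProbabilities(fit, applyStandardizer(S, std))
    top <- setNames(rep1$topClade, rep1$genome_id)
    if (!is.null(queries)) {
      logosR <- estimateCladeLogos(partR, background, correction)
      Sq <- scoreGenomes(.resampleColumns(queries, colIdx[[r]]), logosR)
      repQ <- predictProbabilities(fit, applyStandardizer(Sq, std))
      top <- c(top, setNames(repQ$topClade, repQ$genome_id))
    }
    hit <- cbind(match(names(top), allGenomes), match(top, cladesAll))
    tally[hit] <- tally[hit] + 1L
  }
  correct <- rep(NA_real_, length(allGenomes))
  names(correct) <- allGenomes
  correct[trainGenomes] <- tally[cbind(match(trainGenomes, allGenomes),
                                       match(part0@cladeOf[trainGenomes],
                                             cladesAll))]
  new("BootstrapSummary", replicates = as.integer(R),
      frequencies = tally / R, correctCounts = correct)
}

#' Leave-clade-out model variant
#'
#' Retrains the phyloclassifier with one clade's data excluded from
#' training; the excluded clade's genomes become queries scored against
#' the remaining clades' logos, and the model's input and output
#' dimensions shrink accordingly (the excluded label can never be
#' predicted).  Reports carry the equivocality flag, supporting the
#' "none-of-the-above" interpretation of equivocal classifications.
#'
#' @param aln a [SprinzlAlignment-class] with functional types assigned.
#' @param map a [CladeMap-class].
#' @param exclude the clade label to leave out.
#' @param spec a [NetworkSpec-class].
#' @param threshold equivocality threshold (default 0.8).
#' @inheritParams estimateCladeLogos
#' @return A list with `model` (the retrained
#'   [TrainedPhyloclassifier-class]), `logos` (full-data logos of the
#'   remaining clades), `inModel` (classification report for genomes of
#'   retained clades) and `excluded` (report for the left-out clade's
#'   genomes).
#' @export
leaveCladeOutVariant <- function(aln, map, exclude, spec = networkSpec(),
                                 threshold = 0.8,
                                 background = "clade_frequencies",
                                 correction = "miller_madow") {
  part0 <- partitionByClade(aln, map)
  if (!exclude %in% names(part0@sets))
    stop("clade '", exclude, "' is not a retained clade")
  if (length(part0@sets) - 1L < 2L)
    stop("excluding clade '", exclude, "' leaves fewer than 2 clades")
  outGenomes <- names(part0@cladeOf)[part0@cladeOf == exclude]
  keep <- map@assignments[!names(map@assignments) %in% outGenomes]
  map2 <- new("CladeMap", assignments = keep, minGeneCount = map@minGeneCount)
  part <- partitionByClade(aln, map2, queryGenomes = outGenomes)
  S <- buildTrainingMatrix(part, background, correction)
  std <- fitStandardizer(S)
  fit <- trainNetwork(applyStandardizer(S, std), attr(S, "labels"), spec,
                      standardizer = std)
  inModel <- predictProbabilities(fit, applyStandardizer(S, std),
                                  threshold = threshold)
  logos <- estimateCladeLogos(part, background, correction)
  outAln <- aln[aln@geneInfo$genome_id %in% outGenomes, ]
  Sout <- scoreGenomes(outAln, logos)
  excludedRep <- predictProbabilities(fit, applyStandardizer(Sout, std),
                                      threshold = threshold)
  list(model = fit, logos = logos, inModel = inModel, excluded = excludedRep)
}

#' Oversample score vectors to clade balance
#'
#' Resamples training score vectors with replacement within each clade so
#' that every clade reaches the sample size of the best-sampled clade.
#' Original vectors are always retained; only additional resampled copies
#' are appended.  Deterministic given the seed.
#'
#' @param scores training score matrix (genomes x clades).
#' @param labels clade label per row; defaults to the `labels` attribute.
#' @param seed RNG seed.
#' @return A list with the balanced `scores` matrix and its `labels`.
#' @export
oversampleBalance <- function(scores, labels = attr(scores, "labels"),
                              seed = 1L) {
  labels <- as.character(labels)
  stopifnot(nrow(scores) == length(labels))
  target <- max(table(labels))
  extra <- .withSeed(seed, {
    unlist(lapply(split(seq_along(labels), labels), function(idx) {
      need <- target - length(idx)
      if (need > 0) sample(idx, need, replace = TRUE) else integer(0)
    }), use.names = FALSE)
  })
  idx <- c(seq_along(labels), extra)
  out <- scores[idx, , drop = FALSE]
  rownames(out) <- make.unique(rownames(scores)[idx])
  outLabels <- labels[idx]
  attr(out, "labels") <- outLabels
  attr(out, "cladeOrder") <- attr(scores, "cladeOrder")
  list(scores = out, labels = outLabels)
}
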