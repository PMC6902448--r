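# Confusion metrics, permutation null, site bootstrap, leave-clade-out
# and oversampling balance.

test_that("confusion metrics reproduce the one-vs-all formulas", {
  # tp = 6, fp = 4 for clade A gives precision 0.60
  truth <- c(rep("A", 8), rep("B", 8))
  pred <- c(rep("A", 6), "B", "B", rep("A", 4), rep("B", 4))
  cm <- confusionMetrics(truth, pred)
  expect_equal(cm@perClade["A", "precision"], 0.6)
  expect_equal(cm@perClade["A", "recall"], 6 / 8)
  # perfect predictions: all metrics 1
  cmP <- confusionMetrics(truth, truth)
  expect_true(all(as.matrix(cmP@perClade) == 1))
  expect_equal(cmP@accuracy, 1)
  expect_error(confusionMetrics(character(0), character(0)), "empty")
  expect_error(confusionMetrics(c("A"), c("A", "B")), "equal length")
})

test_that("confusion metrics match brute-force enumeration of 3-class assignments", {
  labels <- c("A", "B", "C")
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    truth <- sample(labels, n, replace = TRUE)
    pred <- sample(labels, n, replace = TRUE)
    cm <- suppressMessages(confusionMetrics(truth, pred, labels))
    oracle <- bruteConfusion(truth, pred, labels)
    for (L in labels)
      expect_equal(unlist(cm@perClade[L, ]),
                   oracle[[L]][colnames(cm@perClade)],
                   ignore_attr = TRUE)
    expect_equal(cm@accuracy, mean(truth == pred))
    expect_equal(unname(rowSums(cm@confusion)),
                 unname(vapply(labels, function(L) sum(truth == L), 0)))
  }
})

test_that("permutation p-values hit their extremes", {
  # observed exceeding every null value gives p = 1/(B+1)
  S <- separableScores(nPerClade = 5, seed = 21)
  pt <- permutationTest(S, spec = networkSpec(8, seed = 2), B = 19, seed = 3)
  expect_equal(pt@observed, 1)
  expect_equal(pt@pValue, 1 / 20)
  expect_length(pt@nullAccuracies, 19L)
  expect_true(all(pt@nullAccuracies >= 0 & pt@nullAccuracies <= 1))
  # an observed value at or below every null gives p = 1: degenerate
  # scores make every labeling equally (un)learnable
  S0 <- S
  S0[] <- 0
  pt0 <- suppressWarnings(
    permutationTest(S0, attr(S, "labels"), networkSpec(8, seed = 2),
                    B = 9, seed = 3))
  expect_equal(pt0@pValue, 1)
})

test_that("site bootstrap keeps books straight on an invariant alignment", {
  # all-identical columns: every replicate resamples identical data and
  # must classify identically
  d <- syntheticDesign(nClades = 2, genomesPerClade = 4,
                       genesPerGenome = c(12, 12), nCoordinates = 8,
                       nPlantedFeatures = 2, signal = 0.9, seed = 61)
  ds <- generateDataset(d)
  aln <- ds$alignment
  onecol <- aln@seqs[, 1]
  alnU <- sprinzlAlignment(
    vapply(seq_len(nrow(aln@seqs)), function(i)
      paste(rep(onecol[i], 8), collapse = ""), ""),
    as.character(1:8), geneData(aln)$genome_id,
    geneId = geneData(aln)$gene_id,
    functionalType = geneData(aln)$functional_type)
  bs <- siteBootstrap(alnU, ds$cladeMap, networkSpec(8, seed = 2),
                      R = 5, seed = 7)
  expect_true(all(bs@frequencies %in% c(0, 1)))
  # per-genome clade fractions always sum to 1
  bs2 <- siteBootstrap(ds$alignment, ds$cladeMap, networkSpec(8, seed = 2),
                       R = 8, seed = 7)
  expect_equal(unname(rowSums(bs2@frequencies)),
               rep(1, nrow(bs2@frequencies)))
  expect_true(all(bs2@correctCounts <= 8, na.rm = TRUE))
})

test_that("bootstrap counts are exchangeable over genome input order", {
  d <- syntheticDesign(nClades = 2, genomesPerClade = 3,
                       genesPerGenome = c(10, 10), nCoordinates = 12,
                       nPlantedFeatures = 3, signal = 0.9, seed = 62)
  ds <- generateDataset(d)
  aln <- ds$alignment
  perm <- rev(seq_len(nGenes(aln)))
  bs1 <- siteBootstrap(aln, ds$cladeMap, networkSpec(8, seed = 2),
                       R = 5, seed = 3)
  bs2 <- siteBootstrap(aln[perm, ], ds$cladeMap, networkSpec(8, seed = 2),
                       R = 5, seed = 3)
  g <- rownames(bs1@frequencies)
  expect_equal(bs1@frequencies[g, ], bs2@frequencies[g, ])
})

test_that("leave-clade-out shrinks the model and flags the excluded clade", {
  d <- syntheticDesign(nClades = 3, genomesPerClade = 5,
                       genesPerGenome = c(20, 25), nCoordinates = 40,
                       nPlantedFeatures = 10, signal = 0.9, seed = 63)
  ds <- generateDataset(d)
  lco <- leaveCladeOutVariant(ds$alignment, ds$cladeMap, "clade2",
                              spec = networkSpec(8, seed = 2))
  # the excluded label can never be predicted
  expect_false("clade2" %in% lco$model@cladeOrder)
  expect_false(any(c(lco$inModel$topClade, lco$excluded$topClade) == "clade2"))
  expect_setequal(lco$excluded$genome_id,
                  paste0("clade2_g", 1:5))
  # excluded genomes are on average more equivocal than in-model genomes
  expect_lt(mean(lco$excluded$topProbability),
            mean(lco$inModel$topProbability))
  expect_error(leaveCladeOutVariant(ds$alignment, ds$cladeMap, "nope"),
               "not a retained clade")
  # K = 2: exclusion would leave a single clade
  d2 <- syntheticDesign(nClades = 2, genomesPerClade = 3,
                        genesPerGenome = c(10, 10), nCoordinates = 12,
                        nPlantedFeatures = 2, seed = 64)
  ds2 <- generateDataset(d2)
  expect_error(leaveCladeOutVariant(ds2$alignment, ds2$cladeMap, "clade1"),
               "fewer than 2")
})

test_that("oversampling balances to the best-sampled clade and keeps originals", {
  set.seed(10)
  S <- matrix(rnorm(2 * 45), 45, 2, dimnames = list(paste0("g", 1:45), c("A", "B")))
  labels <- rep(c("x", "y", "z"), c(30, 11, 4))
  bal <- oversampleBalance(S, labels, seed = 5)
  expect_equal(unname(table(bal$labels)[c("x", "y", "z")]), rep(30L, 3),
               ignore_attr = TRUE)
  # originals all retained, duplicates drawn from the right clades
  expect_equal(bal$scores[seq_len(45), ], S, ignore_attr = TRUE)
  extra <- bal$labels[-seq_len(45)]
  expect_equal(sum(extra == "y"), 19L)
  expect_equal(sum(extra == "z"), 26L)
  # already balanced input: unchanged
  lab2 <- rep(c("x", "y"), each = 10)
  bal2 <- oversampleBalance(S[1:20, ], lab2, seed = 5)
  expect_equal(bal2$scores, S[1:20, ], ignore_attr = TRUE)
  expect_identical(bal2$labels, lab2)
  # deterministic given the seed
  bal3 <- oversampleBalance(S, labels, seed = 5)
  expect_identical(bal3$scores, bal$scores)
})
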