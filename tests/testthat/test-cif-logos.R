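# Function-logo estimation: profiles, information, heights, and oracle
# equivalence with a brute-force implementation.

test_that("class-conditional profiles count carriers and gaps never match", {
  df <- data.frame(gene = paste0("g", 1:4), genome = "G1",
                   type = c("L", "L", "F", "X"),
                   seq = c("GAC", "GAC", "G-C", "GAC"))
  aln <- makeAln(df)
  pr <- classConditionalProfile(aln, "G", "1")
  expect_equal(pr$n, 4L)
  expect_equal(pr$p, c(F = 0.25, L = 0.5, X = 0.25))
  # the gap at coordinate 2 of g3 does not carry the A feature
  pr2 <- classConditionalProfile(aln, "A", "2")
  expect_equal(pr2$n, 3L)
  expect_equal(pr2$p, c(L = 2 / 3, X = 1 / 3))
  # absent feature: empty profile
  pr3 <- classConditionalProfile(aln, "U", "1")
  expect_equal(pr3$n, 0L)
  expect_length(pr3$p, 0L)
  expect_error(classConditionalProfile(aln, "A", "99"), "coordinate")
})

test_that("feature information follows the corrected KL divergence", {
  q22 <- uniformBackground()
  # p = q gives zero information
  expect_equal(featureInformation(q22, n = 50, q = q22), 0)
  # a single-class profile against a uniform 22-class background
  expect_equal(featureInformation(c(L = 1), n = 10, q = q22), log2(22))
  # two equiprobable classes against a uniform 4-class background: 1 bit
  q4 <- stats::setNames(rep(0.25, 4), c("A", "G", "L", "F"))
  expect_equal(featureInformation(c(A = 0.5, G = 0.5), n = 8, q = q4), 1.0)
  # corrected information never exceeds the raw value and the correction
  # vanishes as n grows
  raw <- featureInformation(c(L = 1), 10, q22, "none")
  mm10 <- featureInformation(c(L = 1), 10, q22, "miller_madow")
  mm1e6 <- featureInformation(c(L = 1), 1e6, q22, "miller_madow")
  expect_lt(mm10, raw)
  expect_lt(raw - mm1e6, 1e-4)
  ex4 <- featureInformation(c(L = 1), 4, q22, "exact_small_n")
  expect_lte(ex4, featureInformation(c(L = 1), 4, q22, "none"))
  # background-support violation
  qq <- c(L = 0.5, F = 0.5)
  expect_error(featureInformation(c(X = 1), 5, qq), "background")
  expect_error(featureInformation(c(L = 1), 0, qq), "n must be")
})

test_that("exact small-sample correction equals direct enumeration", {
  # independent oracle: enumerate all class-count compositions of n draws
  # from q and average the plug-in divergence (3 classes keeps the
  # enumeration exhaustive)
  q <- c(A = 0.5, B = 0.3, C = 0.2)
  n <- 4
  exp_kl <- 0
  for (a in 0:n) for (b in 0:(n - a)) {
    cc <- n - a - b
    pr <- dmultinom(c(a, b, cc), n, q)
    ph <- c(a, b, cc) / n
    kl <- sum(ifelse(ph > 0, ph * log2(ph / q), 0))
    exp_kl <- exp_kl + pr * kl
  }
  expect_equal(tRNAcif:::.exactKLBias(n, q), exp_kl, tolerance = 1e-12)
})

test_that("Gorodkin heights apportion information by background odds", {
  q4 <- stats::setNames(rep(0.25, 4), c("A", "G", "L", "F"))
  h <- gorodkinHeights(c(A = 0.5, G = 0.5), q4, D = 1)
  expect_equal(h, c(A = 0.5, G = 0.5, L = 0, F = 0))
  # zero information: all-zero heights
  expect_equal(unname(gorodkinHeights(c(A = 1), q4, 0)), rep(0, 4))
  # single-class limit against uniform 22 classes
  q22 <- uniformBackground()
  h22 <- gorodkinHeights(c(L = 1), q22, log2(22))
  expect_equal(h22[["L"]], log2(22))
  expect_equal(sum(h22), log2(22))
  # heights scale linearly in D for fixed p and q
  p <- c(A = 0.7, L = 0.3)
  expect_equal(gorodkinHeights(p, q4, 2), 2 * gorodkinHeights(p, q4, 1))
})

test_that("estimated logos match the brute-force oracle on micro-fixtures", {
  df <- data.frame(gene = paste0("g", 1:5),
                   genome = c("G1", "G1", "G2", "G2", "G2"),
                   type = c("L", "F", "L", "X", "J"),
                   seq = c("ACGU", "AC-U", "GCGA", "ACUA", "GUG-"))
  aln <- makeAln(df)
  map <- cladeMap(c(G1 = "X1", G2 = "X1"), minGeneCount = 1)
  part <- partitionByClade(aln, map)
  for (corr in c("none", "miller_madow")) {
    logos <- estimateCladeLogos(part, background = "clade_frequencies",
                                correction = corr)
    lg <- logos[["X1"]]
    q <- logoBackground(lg)
    oracle <- bruteLogo(aln, q, corr)
    expect_setequal(rownames(heights(lg)), names(oracle))
    for (f in names(oracle)) {
      expect_equal(unname(heights(lg)[f, ]), unname(oracle[[f]]$h),
                   tolerance = 1e-12)
      expect_equal(featureInfo(lg)[[f]], oracle[[f]]$D, tolerance = 1e-12)
      expect_equal(featureSupport(lg)[[f]], oracle[[f]]$n)
    }
  }
})

test_that("height normalization and determinism hold on random datasets", {
  for (s in 1:10) {
    d <- syntheticDesign(nClades = 2, genomesPerClade = 3,
                         genesPerGenome = c(10, 15), nCoordinates = 12,
                         nPlantedFeatures = 3, backgroundIdentity = 1,
                         signal = 0.8, seed = 900 + s)
    ds <- generateDataset(d)
    part <- partitionByClade(ds$alignment, ds$cladeMap)
    logos <- estimateCladeLogos(part)
    for (lg in logos) {
      expect_true(all(heights(lg) >= 0))
      expect_lt(max(abs(rowSums(heights(lg)) - featureInfo(lg))), 1e-9)
    }
  }
  # determinism: identical gene sets give identical logos
  d <- syntheticDesign(nClades = 2, genomesPerClade = 3,
                       genesPerGenome = c(10, 10), nCoordinates = 12,
                       nPlantedFeatures = 3, seed = 1)
  ds <- generateDataset(d)
  part <- partitionByClade(ds$alignment, ds$cladeMap)
  expect_identical(heights(estimateCladeLogos(part)[[1]]),
                   heights(estimateCladeLogos(part)[[1]]))
})

test_that("clades differing at one coordinate differ only there", {
  # two clades identical except at coordinate 3
  mk <- function(b3) data.frame(
    gene = paste0("g", 1:4), genome = "G", type = c("L", "F", "L", "F"),
    seq = paste0("AC", b3, "U"))
  df <- rbind(mk("G"), mk("U"))
  df$gene <- paste0("g", 1:8)
  df$genome <- rep(c("G1", "G2"), each = 4)
  aln <- makeAln(df)
  map <- cladeMap(c(G1 = "K1", G2 = "K2"), minGeneCount = 1)
  logos <- estimateCladeLogos(partitionByClade(aln, map), background = "uniform")
  f1 <- rownames(heights(logos[["K1"]]))
  f2 <- rownames(heights(logos[["K2"]]))
  diffFeats <- c(setdiff(f1, f2), setdiff(f2, f1))
  expect_true(all(grepl("@3$", diffFeats)))
  common <- intersect(f1, f2)
  expect_equal(heights(logos[["K1"]])[common, ],
               heights(logos[["K2"]])[common, ])
})

test_that("logo tables round-trip exactly through TSV", {
  d <- syntheticDesign(nClades = 2, genomesPerClade = 3,
                       genesPerGenome = c(12, 12), nCoordinates = 10,
                       nPlantedFeatures = 3, seed = 4)
  ds <- generateDataset(d)
  lg <- estimateCladeLogos(partitionByClade(ds$alignment, ds$cladeMap))[[1]]
  path <- withr::local_tempfile(fileext = ".tsv")
  exportLogoTable(lg, path)
  back <- readLogoTable(path)
  expect_identical(back@clade, lg@clade)
  expect_identical(back@coordinates, lg@coordinates)
  expect_equal(heights(back), heights(lg))
  expect_equal(featureInfo(back), featureInfo(lg))
  expect_identical(featureSupport(back), featureSupport(lg))
  expect_equal(logoBackground(back), logoBackground(lg))
  # a single-feature logo has at most 22 rows
  df <- data.frame(gene = c("g1", "g2"), genome = "G1", type = c("L", "F"),
                   seq = c("A", "A"))
  alnS <- makeAln(df)
  mapS <- cladeMap(c(G1 = "Z"), minGeneCount = 1)
  lgS <- estimateCladeLogos(partitionByClade(alnS, mapS))[[1]]
  pathS <- withr::local_tempfile(fileext = ".tsv")
  exportLogoTable(lgS, pathS)
  body <- readLines(pathS)
  body <- body[!startsWith(body, "#")][-1]
  expect_lte(length(body), 22L)
})
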