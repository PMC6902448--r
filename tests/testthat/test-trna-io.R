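# Reading, normalization, typing, filtering, pruning, partitioning and
# complement summaries.

test_that("tabular round trip preserves sequences, coordinates and metadata", {
  df <- data.frame(gene = c("g1", "g2", "g3"),
                   genome = c("G1", "G1", "G2"),
                   type = c("F", "A", "L"),
                   seq = c("ACGUA", "AC-UA", "GGGUU"),
                   anticodon = c("GAA", "UGC", NA))
  aln <- makeAln(df)
  expect_equal(nGenes(aln), 3L)
  expect_equal(nchar(df$seq[1]), length(sprinzlCoordinates(aln)))
  for (fmt in c("tabular", "stockholm")) {
    path <- withr::local_tempfile(fileext = ".txt")
    writeAlignedGenes(aln, path, fmt)
    back <- readAlignedGenes(path, fmt)
    expect_identical(back@seqs, aln@seqs)
    expect_identical(geneData(back), geneData(aln))
  }
})

test_that("input is normalized to the RNA alphabet", {
  aln <- sprinzlAlignment(c(g1 = "acgTt"), as.character(1:5), "G1")
  expect_identical(unname(aln@seqs[1, ]), c("A", "C", "G", "U", "U"))
  # ambiguity codes become gaps
  aln2 <- sprinzlAlignment(c(g1 = "ANGRU"), as.character(1:5), "G1")
  expect_identical(unname(aln2@seqs[1, ]), c("A", "-", "G", "-", "U"))
  # symbols outside the alphabet are a format error naming gene and column
  expect_error(sprinzlAlignment(c(gX = "ACZGU"), as.character(1:5), "G1"),
               "gX.*column 3")
})

test_that("sequence length must match the coordinate row", {
  expect_error(sprinzlAlignment(c(g1 = "ACGU"), as.character(1:5), "G1"),
               "length 4.*5 coordinates")
  path <- withr::local_tempfile()
  writeLines(c("# STOCKHOLM 1.0",
               "#=GF SPRINZL_COORDS 1 2 3 4 5",
               "#=GS g1 GENOME G1",
               "g1  ACGU", "//"), path)
  expect_error(readAlignedGenes(path, "stockholm"), "length 4")
  # missing coordinate annotation is a format error
  path2 <- withr::local_tempfile()
  writeLines(c("# STOCKHOLM 1.0", "g1  ACGU", "//"), path2)
  expect_error(readAlignedGenes(path2, "stockholm"), "SPRINZL_COORDS")
})

test_that("anticodons type genes via the standard genetic code", {
  df <- data.frame(gene = c("g1", "g2", "g3"),
                   genome = "G1", type = NA,
                   seq = "ACGUA",
                   anticodon = c("GAA", "UGC", "CAU"))
  aln <- makeAln(df)
  # GAA -> codon UUC -> Phe; UGC -> codon GCA -> Ala
  typed <- assignFunctionalTypes(aln, cauPolicy = "default_X")
  expect_identical(geneData(typed)$functional_type, c("F", "A", "X"))
  typed2 <- assignFunctionalTypes(aln, cauPolicy = "default_J")
  expect_identical(geneData(typed2)$functional_type[3], "J")
  # explicit labels always win, also for CAU genes
  df$type <- c(NA, NA, "X")
  typed3 <- assignFunctionalTypes(makeAln(df), cauPolicy = "default_M")
  expect_identical(geneData(typed3)$functional_type, c("F", "A", "X"))
  # unlabeled CAU under labels_required is a typing error
  expect_error(assignFunctionalTypes(aln, cauPolicy = "labels_required"),
               "CAU")
  # an anticodon matching a stop codon is a typing error
  dfStop <- data.frame(gene = "g1", genome = "G1", type = NA,
                       seq = "ACGUA", anticodon = "UUA")  # codon UAA
  expect_error(assignFunctionalTypes(makeAln(dfStop)), "stop codon")
})

test_that("prediction filters apply whitelists and intron blacklists", {
  df <- data.frame(gene = paste0("g", 1:3), genome = "G1",
                   type = c("F", "A", "K"), seq = "ACGUA",
                   anticodon = c("GAA", "UGC", "AAA"))
  aln <- makeAln(df)
  res <- filterPredictions(aln, anticodonWhitelist = c("GAA", "UGC"))
  expect_equal(nGenes(res$alignment), 2L)
  expect_identical(res$rejections$gene_id, "g3")
  expect_identical(res$rejections$rule, "anticodon_whitelist")
  # no rules: identity
  res0 <- filterPredictions(aln)
  expect_identical(res0$alignment@seqs, aln@seqs)
  expect_equal(nrow(res0$rejections), 0L)
  # intron-flagged gene of a blacklisted isotype is removed
  aln2 <- sprinzlAlignment(df$seq, as.character(1:5), "G1", df$gene,
                           df$type, df$anticodon, intron = c(TRUE, FALSE, TRUE))
  res2 <- filterPredictions(aln2, intronBlacklist = c("F", "A"))
  expect_identical(res2$rejections$gene_id, "g1")
  expect_equal(nGenes(res2$alignment), 2L)
})

test_that("filter rule config files parse and reject malformed input", {
  path <- withr::local_tempfile()
  writeLines(c("anticodon_whitelist = GAA, UGC", "exclude_genes = g9"), path)
  rules <- readFilterRules(path)
  expect_identical(rules$anticodonWhitelist, c("GAA", "UGC"))
  expect_identical(rules$excludeGenes, "g9")
  bad <- withr::local_tempfile()
  writeLines("just some text", bad)
  expect_error(readFilterRules(bad), "malformed")
  bad2 <- withr::local_tempfile()
  writeLines("unknown_key = 1", bad2)
  expect_error(readFilterRules(bad2), "unknown filter config key")
})

test_that("column pruning honors the inclusive gap threshold", {
  # 100 genes; column 2 has 99 gaps, column 3 has 98 gaps
  seqs <- vapply(1:100, function(i) {
    paste0("A", if (i <= 99) "-" else "C", if (i <= 98) "-" else "G", "U")
  }, "")
  aln <- sprinzlAlignment(seqs, as.character(1:4), "G1",
                          geneId = paste0("g", 1:100), functionalType = "L")
  pruned <- pruneColumns(aln, gapThreshold = 0.99)
  expect_identical(sprinzlCoordinates(pruned), c("1", "3", "4"))
  # idempotent at a fixed threshold
  expect_identical(pruneColumns(pruned, 0.99)@seqs, pruned@seqs)
  # explicit coordinate drop list
  dropped <- pruneColumns(aln, 0.99, dropCoordinates = c("3", "4"))
  expect_identical(sprinzlCoordinates(dropped), "1")
  expect_error(pruneColumns(aln, 0.99, dropCoordinates = c("1", "3", "4")),
               "all alignment columns")
  expect_error(pruneColumns(aln, 0), "gapThreshold")
})

test_that("clade partitioning pools, excludes and fuses correctly", {
  df <- data.frame(gene = paste0("g", 1:25),
                   genome = rep(c("G1", "G2", "G3", "G4", "G5"), each = 5),
                   type = "L", seq = "ACGUA")
  aln <- makeAln(df)
  map <- cladeMap(c(G1 = "A", G2 = "A", G3 = "A", G4 = "B", G5 = "C"),
                  minGeneCount = 10)
  part <- partitionByClade(aln, map)
  expect_identical(cladeLabels(part), "A")
  expect_equal(lengths(cladeSets(part))[["A"]], 15L)
  expect_setequal(excludedClades(part)$clade, c("B", "C"))
  expect_equal(sort(excludedClades(part)$genes), c(5L, 5L))
  # partition followed by union over clades loses and duplicates nothing
  map2 <- cladeMap(c(G1 = "A", G2 = "A", G3 = "B", G4 = "B", G5 = "C"),
                   minGeneCount = 1)
  part2 <- partitionByClade(aln, map2)
  expect_identical(sort(unlist(cladeSets(part2), use.names = FALSE)),
                   seq_len(25L))
  # clade fusion via aliases
  mapF <- cladeMap(c(G1 = "B2", G2 = "B3", G3 = "B2", G4 = "A", G5 = "A"),
                   minGeneCount = 1, aliases = c(B2 = "B2+3", B3 = "B2+3"))
  partF <- partitionByClade(aln, mapF)
  expect_true("B2+3" %in% cladeLabels(partF))
  expect_equal(lengths(cladeSets(partF))[["B2+3"]], 15L)
  # unmapped genomes error unless query-flagged
  mapQ <- cladeMap(c(G1 = "A", G2 = "A", G3 = "A", G4 = "B"), minGeneCount = 1)
  expect_error(partitionByClade(aln, mapQ), "no clade assignment")
  expect_silent(partitionByClade(aln, mapQ, queryGenomes = "G5"))
  expect_error(partitionByClade(aln, cladeMap(character(0), 1)), "empty")
})

test_that("leave-one-out sets remove exactly one genome's genes", {
  df <- data.frame(gene = paste0("g", 1:20),
                   genome = rep(c("G1", "G2", "G3", "G4"), each = 5),
                   type = "L", seq = "ACGUA")
  aln <- makeAln(df)
  map <- cladeMap(c(G1 = "A", G2 = "A", G3 = "A", G4 = "B"), minGeneCount = 1)
  part <- partitionByClade(aln, map)
  loo <- leaveOneOutSets(part, "G2")
  expect_equal(lengths(cladeSets(loo))[["A"]], 10L)
  expect_identical(cladeSets(loo)[["B"]], cladeSets(part)[["B"]])
  expect_false(any(geneData(aln)$genome_id[cladeSets(loo)[["A"]]] == "G2"))
  # query-only genome: no-op
  map2 <- cladeMap(c(G1 = "A", G2 = "A", G3 = "A"), minGeneCount = 1)
  part2 <- partitionByClade(aln, map2, queryGenomes = "G4")
  expect_identical(cladeSets(leaveOneOutSets(part2, "G4")), cladeSets(part2))
  # removing a single-genome clade is a degenerate-clade error
  expect_error(leaveOneOutSets(part, "G4"), "degenerate")
  expect_error(leaveOneOutSets(part, "nope"), "not present")
})

test_that("complement summaries report the printed ratio arithmetic", {
  # displayed T/G and N/T ratios round to two decimals
  expect_equal(summaryFromCounts(27, 1395)$genesPerGenome, 51.67)
  expect_equal(summaryFromCounts(11, 555, 40362)$genesPerGenome, 50.45)
  expect_equal(summaryFromCounts(11, 555, 40362)$basesPerGene, 72.72)
  # single gene ACGU: N = 4, uniform composition
  aln <- makeAln(data.frame(gene = "g1", genome = "G1", type = "L",
                            seq = "ACGU"))
  s <- complementSummary(aln)
  expect_equal(s$bases, 4)
  expect_equal(c(s$pctA, s$pctU, s$pctG, s$pctC), rep(25, 4))
  # percentages sum to 100 on an arbitrary gapped fixture
  df <- data.frame(gene = paste0("g", 1:6),
                   genome = rep(c("G1", "G2"), each = 3), type = "L",
                   seq = c("ACGU-", "AAC-U", "GGG--", "C-CUA", "UU-GA", "ACGUA"))
  map <- cladeMap(c(G1 = "X1", G2 = "X2"), minGeneCount = 1)
  sm <- complementSummary(partitionByClade(makeAln(df), map))
  expect_equal(sm$pctA + sm$pctU + sm$pctG + sm$pctC, rep(100, 2))
  expect_equal(sm$genes / sm$genomes, sm$genesPerGenome)
  # rounded display retains full precision internally
  disp <- formatComplementSummary(sm)
  expect_equal(disp$basesPerGene, round(sm$basesPerGene, 2))
})
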