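# Synthetic clade-structured tRNA gene complements with planted
# class-informative features.

# Draw the determinant sets of a design: shared per-class identity
# determinants (common to all clades) and clade-specific planted
# determinants, disjoint from the shared set and from each other at the
# (class, coordinate) level.  Consumes the RNG stream; callers seed.
.drawDeterminants <- function(design) {
  K <- design@nClades
  C <- design@nCoordinates
  cls <- design@classes
  coords <- as.character(seq_len(C))
  shared <- do.call(rbind, lapply(cls, function(cl) {
    co <- sample.int(C, min(design@backgroundIdentity, C))
    data.frame(class = cl, coordinate = coords[co],
               base = sample(.BASES, length(co), replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  grid <- expand.grid(class = cls, coordinate = coords,
                      stringsAsFactors = FALSE)
  usedShared <- paste(shared$class, shared$coordinate)
  grid <- grid[!(paste(grid$class, grid$coordinate) %in% usedShared), ]
  need <- K * design@nPlantedFeatures
  if (need > nrow(grid))
    stop("infeasible design: ", need, " planted determinants requested but ",
         "only ", nrow(grid), " free (class, coordinate) pairs available")
  pick <- grid[sample.int(nrow(grid), need), ]
  planted <- data.frame(
    clade = rep(paste0("clade", seq_len(K)), each = design@nPlantedFeatures),
    class = pick$class, coordinate = pick$coordinate,
    base = sample(.BASES, need, replace = TRUE),
    stringsAsFactors = FALSE)
  list(shared = shared, planted = planted)
}

# Generate genomes for given clade labels using the design's gene model.
# dets: list(shared, planted); genomeClades: named character vector
# (genome id -> clade, matching planted$clade or absent for none).
.generateGenomes <- function(design, genomeClades, dets) {
  C <- design@nCoordinates
  coords <- as.character(seq_len(C))
  cls <- design@classes
  geneCounts <- vapply(genomeClades, function(.)
    if (design@genesPerGenome[1L] == design@genesPerGenome[2L])
      design@genesPerGenome[1L]
    else sample(seq(design@genesPerGenome[1L], design@genesPerGenome[2L]), 1L),
    integer(1))
  total <- sum(geneCounts)
  geneGenome <- rep(names(genomeClades), geneCounts)
  geneClade <- rep(unname(genomeClades), geneCounts)
  geneClass <- unlist(lapply(geneCounts, function(n) {
    if (n >= length(cls))
      c(cls, sample(cls, n - length(cls), replace = TRUE))
    else sample(cls, n)
  }), use.names = FALSE)
  # background: uniform random bases with gaps at rate gapRate
  mat <- matrix(sample(.BASES, total * C, replace = TRUE), total, C)
  mat[matrix(runif(total * C) < design@gapRate, total, C)] <- .GAP
  applyDets <- function(df, byClade) {
    for (i in seq_len(nrow(df))) {
      rows <- if (byClade)
        which(geneClass == df$class[i] & geneClade == df$clade[i])
      else which(geneClass == df$class[i])
      if (!length(rows)) next
      co <- match(df$coordinate[i], coords)
      respected <- runif(length(rows)) < design@signal
      mat[rows[respected], co] <<- df$base[i]
    }
  }
  applyDets(dets$shared, byClade = FALSE)
  applyDets(dets$planted, byClade = TRUE)
  geneIds <- paste0(geneGenome, "_t", unlist(lapply(geneCounts, seq_len)))
  sprinzlAlignment(apply(mat, 1L, paste, collapse = ""), coords,
                   genomeId = geneGenome, geneId = geneIds,
                   functionalType = geneClass)
}

#' Generate a synthetic clade-structured dataset
#'
#' Draws a tRNA gene complement alignment for K clades of genomes.  Each
#' gene's bases are uniform random (or gap, at the design's gap rate),
#' overwritten at shared class-identity determinants (all clades) and at
#' its clade's planted determinants with probability `signal`.  At
#' `signal = 1` and gap rate 0 every clade-k gene carries all clade-k
#' determinants for its class; at `signal = 0` the clades are
#' statistically exchangeable.  Deterministic given the design's seed.
#'
#' @param design a [SyntheticDesign-class].
#' @return A list with `alignment` (a [SprinzlAlignment-class]),
#'   `cladeMap` (a [CladeMap-class] with `minGeneCount = 1`; synthetic
#'   designs control their own sizes), `truth` (list of `shared` and
#'   `planted` determinant data.frames) and `design`.
#' @examples
#' d <- syntheticDesign(nClades = 2, genomesPerClade = 3,
#'                      genesPerGenome = c(25, 25), nCoordinates = 30,
#'                      nPlantedFeatures = 5)
#' ds <- generateDataset(d)
#' ds$alignment
#' @export
generateDataset <- function(design) {
  stopifnot(is(design, "SyntheticDesign"))
  .withSeed(design@seed, {
    dets <- .drawDeterminants(design)
    cladeLabs <- paste0("clade", seq_len(design@nClades))
    genomeClades <- unlist(lapply(seq_len(design@nClades), function(k) {
      g <- design@genomesPerClade[k]
      setNames(rep(cladeLabs[k], g), paste0(cladeLabs[k], "_g", seq_len(g)))
    }))
    aln <- .generateGenomes(design, genomeClades, dets)
    list(alignment = aln,
         cladeMap = cladeMap(genomeClades, minGeneCount = 1),
         truth = dets, design = design)
  })
}

#' Generate query genomes from a novel clade
#'
#' Draws genomes from a (K+1)-th clade with its own planted determinants
#' at (class, coordinate) pairs never used by the training clades, for
#' "none-of-the-above" experiments: a classifier trained on the K design
#' clades has never seen this clade's signal.
#'
#' @param design the training [SyntheticDesign-class].
#' @param nGenomes number of novel-clade genomes (default 5).
#' @param seed RNG seed for the novel clade (default `design@seed + 1`);
#'   the training determinants are re-derived from the design seed, so the
#'   novel determinants are disjoint from them by construction.
#' @return A list with `alignment` (the query genomes, genome ids
#'   `novel_g*`) and `truth` (the novel clade's planted determinants).
#' @export
generateNovelCladeQueries <- function(design, nGenomes = 5L,
                                      seed = design@seed + 1L) {
  stopifnot(is(design, "SyntheticDesign"))
  detsTrain <- .withSeed(design@seed, .drawDeterminants(design))
  novelLab <- paste0("clade", design@nClades + 1L)
  .withSeed(seed, {
    coords <- as.character(seq_len(design@nCoordinates))
    grid <- expand.grid(class = design@classes, coordinate = coords,
                        stringsAsFactors = FALSE)
    used <- c(paste(detsTrain$shared$class, detsTrain$shared$coordinate),
              paste(detsTrain$planted$class, detsTrain$planted$coordinate))
    grid <- grid[!(paste(grid$class, grid$coordinate) %in% used), ]
    if (design@nPlantedFeatures > nrow(grid))
      stop("infeasible design: no free (class, coordinate) pairs left ",
           "for a novel clade")
    pick <- grid[sample.int(nrow(grid), design@nPlantedFeatures), ]
    novelPlanted <- data.frame(
      clade = novelLab, class = pick$class, coordinate = pick$coordinate,
      base = sample(.BASES, nrow(pick), replace = TRUE),
      stringsAsFactors = FALSE)
    dets <- list(shared = detsTrain$shared, planted = novelPlanted)
    genomeClades <- setNames(rep(novelLab, nGenomes),
                             paste0("novel_g", seq_len(nGenomes)))
    aln <- .generateGenomes(design, genomeClades, dets)
    list(alignment = aln, truth = novelPlanted)
  })
}
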