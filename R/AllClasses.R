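# S4 classes for aligned tRNA gene complements, clade maps, function logos,
# score standardization, the MLP phyloclassifier, robustness results and
# synthetic designs.

#' @include tRNAcif-package.R AllGenerics.R
NULL

## SprinzlAlignment ----------------------------------------------------------

#' Sprinzl-coordinate-aligned tRNA gene complement
#'
#' Holds tRNA gene sequences aligned in a common Sprinzl coordinate frame,
#' as a character matrix (genes x coordinates) over `{A,C,G,U,-}` together
#' with per-gene metadata (`gene_id`, `genome_id`, `functional_type`,
#' `anticodon`, optionally `intron`).  Coordinate labels are opaque strings;
#' no numeric ordering is assumed beyond input order, so Sprinzl insertion
#' codes such as `"20a"` are supported.
#'
#' @slot seqs character matrix, one row per gene, one column per Sprinzl
#'   coordinate; entries in `A`, `C`, `G`, `U` or `-`.
#' @slot geneInfo data.frame with columns `gene_id`, `genome_id`,
#'   `functional_type` (one of [functionalClasses()] or `NA` before typing),
#'   `anticodon` (3-mer over ACGU or `NA`) and optional logical `intron`.
#'
#' @seealso [sprinzlAlignment()], [readAlignedGenes()]
#' @export
setClass("SprinzlAlignment",
         representation(seqs = "matrix", geneInfo = "data.frame"))

setValidity("SprinzlAlignment", function(object) {
  s <- object@seqs
  gi <- object@geneInfo
  if (!is.character(s)) return("seqs must be a character matrix")
  if (is.null(colnames(s))) return("coordinate labels (colnames) are required")
  if (anyDuplicated(colnames(s))) return("coordinate labels must be unique")
  if (nrow(s) != nrow(gi)) return("seqs and geneInfo disagree on gene count")
  need <- c("gene_id", "genome_id", "functional_type", "anticodon")
  if (!all(need %in% names(gi)))
    return(paste("geneInfo must contain columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(gi$gene_id)) return("gene_id values must be unique")
  rn <- rownames(s)
  if (is.null(rn)) rn <- character(0)
  if (nrow(s) > 0L && !identical(rn, as.character(gi$gene_id)))
    return("rownames(seqs) must equal geneInfo$gene_id")
  bad <- !(s %in% c(.BASES, .GAP))
  dim(bad) <- dim(s)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    return(sprintf("invalid symbol '%s' in gene '%s' at coordinate '%s'",
                   s[w[1L], w[2L]], rownames(s)[w[1L]], colnames(s)[w[2L]]))
  }
  ft <- gi$functional_type
  badft <- !is.na(ft) & !(ft %in% .CLASSES)
  if (any(badft))
    return(sprintf("unknown functional type '%s' for gene '%s'",
                   ft[badft][1L], gi$gene_id[badft][1L]))
  TRUE
})

# Normalize raw aligned sequences to the RNA alphabet: upper case, T->U,
# '.'/'~' to '-', IUPAC ambiguity codes to '-' (features are defined only
# over A/C/G/U).  Any residue left outside the alphabet is a format error
# naming the gene and column.
.normalizeSeqs <- function(x, geneIds) {
  x <- toupper(x)
  x <- chartr("T", "U", x)
  mat <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  mat[mat %in% c(".", "~", "R", "Y", "S", "W", "K", "M", "B", "D", "H",
                 "V", "N")] <- .GAP
  bad <- !(mat %in% c(.BASES, .GAP))
  dim(bad) <- dim(mat)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("unknown residue symbol '%s' in gene '%s' at column %d",
                 mat[w[1L], w[2L]], geneIds[w[1L]], w[2L]))
  }
  mat
}

#' Construct a SprinzlAlignment
#'
#' @param sequences character vector of aligned sequences (one per gene).
#'   Input is normalized: case-folded, `T` mapped to `U`, `.`/`~` to `-`,
#'   and IUPAC ambiguity codes treated as gaps.
#' @param coordinates character vector of unique Sprinzl coordinate labels,
#'   one per alignment column.
#' @param genomeId genome of origin for each gene (recycled if length 1).
#' @param geneId unique gene identifiers; defaults to `names(sequences)` or
#'   `gene1, gene2, ...`.
#' @param functionalType functional class per gene (see
#'   [functionalClasses()]), or `NA` to assign later with
#'   [assignFunctionalTypes()].
#' @param anticodon anticodon 3-mer per gene or `NA`.
#' @param intron logical flag per gene marking intron-containing
#'   predictions (used by [filterPredictions()]).
#' @return A [SprinzlAlignment-class] object.
#' @examples
#' aln <- sprinzlAlignment(c(g1 = "ACGUA", g2 = "acg-t"),
#'                         coordinates = as.character(1:5),
#'                         genomeId = "G1")
#' sprinzlCoordinates(aln)
#' @export
sprinzlAlignment <- function(sequences, coordinates, genomeId,
                             geneId = names(sequences),
                             functionalType = NA_character_,
                             anticodon = NA_character_,
                             intron = FALSE) {
  n <- length(sequences)
  if (is.null(geneId)) geneId <- paste0("gene", seq_len(n))
  geneId <- as.character(geneId)
  coordinates <- as.character(coordinates)
  lens <- nchar(sequences)
  if (any(lens != length(coordinates))) {
    i <- which(lens != length(coordinates))[1L]
    stop(sprintf(
      "aligned sequence of gene '%s' has length %d but there are %d coordinates",
      geneId[i], lens[i], length(coordinates)))
  }
  mat <- .normalizeSeqs(as.character(sequences), geneId)
  dimnames(mat) <- list(geneId, coordinates)
  ft <- toupper(as.character(rep_len(functionalType, n)))
  ft[ft %in% c("", "NA")] <- NA_character_
  ac <- toupper(chartr("t", "u", as.character(rep_len(anticodon, n))))
  ac <- chartr("T", "U", ac)
  ac[ac %in% c("", "NA")] <- NA_character_
  gi <- data.frame(gene_id = geneId,
                   genome_id = as.character(rep_len(genomeId, n)),
                   functional_type = ft,
                   anticodon = ac,
                   intron = rep_len(as.logical(intron), n),
                   stringsAsFactors = FALSE)
  rownames(gi) <- NULL
  new("SprinzlAlignment", seqs = mat, geneInfo = gi)
}

#' @rdname tRNAcif-generics
#' @export
setMethod("sprinzlCoordinates", "SprinzlAlignment", function(x) colnames(x@seqs))

#' @rdname tRNAcif-generics
#' @export
setMethod("geneData", "SprinzlAlignment", function(x) x@geneInfo)

#' @rdname tRNAcif-generics
#' @export
setMethod("genomeIds", "SprinzlAlignment", function(x) unique(x@geneInfo$genome_id))

#' @rdname tRNAcif-generics
#' @export
setMethod("nGenes", "SprinzlAlignment", function(x) nrow(x@seqs))

#' @describeIn SprinzlAlignment-class subset genes (`i`, by index, logical
#'   or `gene_id`) and/or coordinates (`j`, by index or label).
#' @param x,i,j,...,drop see base subsetting; `drop` is ignored.
#' @export
setMethod("[", "SprinzlAlignment", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@seqs))
  if (missing(j)) j <- seq_len(ncol(x@seqs))
  if (is.character(i)) i <- match(i, rownames(x@seqs))
  new("SprinzlAlignment",
      seqs = x@seqs[i, j, drop = FALSE],
      geneInfo = x@geneInfo[i, , drop = FALSE])
})

setMethod("show", "SprinzlAlignment", function(object) {
  cat(sprintf("SprinzlAlignment: %d genes x %d coordinates, %d genomes\n",
              nrow(object@seqs), ncol(object@seqs),
              length(unique(object@geneInfo$genome_id))))
  typed <- sum(!is.na(object@geneInfo$functional_type))
  cat(sprintf("  functional types assigned: %d/%d\n", typed, nrow(object@seqs)))
})

## CladeMap -------------------------------------------------------------------

#' Genome-to-clade map
#'
#' Maps genome identifiers to clade labels, with a minimum pooled gene count
#' per retained clade (clades below the threshold are excluded at
#' partitioning time, mirroring the exclusion of poorly sampled clades from
#' training).
#'
#' @slot assignments named character vector, genome id -> clade label.
#' @slot minGeneCount minimum pooled tRNA gene count a clade must reach to
#'   be retained (default 120).
#' @seealso [cladeMap()], [partitionByClade()]
#' @export
setClass("CladeMap",
         representation(assignments = "character", minGeneCount = "numeric"))

setValidity("CladeMap", function(object) {
  a <- object@assignments
  if (length(a) > 0L && (is.null(names(a)) || any(names(a) == "")))
    return("assignments must be a named character vector (genome -> clade)")
  if (anyDuplicated(names(a)))
    return("each genome must map to exactly one clade")
  if (length(object@minGeneCount) != 1L || object@minGeneCount < 1)
    return("minGeneCount must be a single value >= 1")
  TRUE
})

#' Construct a CladeMap
#'
#' @param assignments named character vector mapping genome ids to clade
#'   labels.
#' @param minGeneCount minimum pooled gene count per retained clade
#'   (default 120).
#' @param aliases optional named character vector of clade aliases applied
#'   to the assignment values, supporting clade fusion (e.g.
#'   `c(B2 = "B2+3", B3 = "B2+3")`).
#' @return A [CladeMap-class] object.
#' @examples
#' cm <- cladeMap(c(g1 = "B2", g2 = "B3", g3 = "A"),
#'                minGeneCount = 1,
#'                aliases = c(B2 = "B2+3", B3 = "B2+3"))
#' cladeLabels(cm)
#' @export
cladeMap <- function(assignments, minGeneCount = 120, aliases = NULL) {
  a <- as.character(assignments)
  names(a) <- names(assignments)
  if (!is.null(aliases)) {
    hit <- a %in% names(aliases)
    a[hit] <- unname(aliases[a[hit]])
  }
  new("CladeMap", assignments = a, minGeneCount = as.numeric(minGeneCount))
}

#' Read a clade map from a TSV file
#'
#' The file must have columns `genome_id` and `clade`.
#'
#' @param path file path.
#' @inheritParams cladeMap
#' @return A [CladeMap-class] object.
#' @export
readCladeMap <- function(path, minGeneCount = 120, aliases = NULL) {
  df <- read.delim(path, colClasses = "character")
  if (!all(c("genome_id", "clade") %in% names(df)))
    stop("clade map must have columns 'genome_id' and 'clade'")
  cladeMap(setNames(df$clade, df$genome_id), minGeneCount, aliases)
}

#' @rdname tRNAcif-generics
#' @export
setMethod("cladeAssignments", "CladeMap", function(x) x@assignments)

#' @rdname tRNAcif-generics
#' @export
setMethod("cladeLabels", "CladeMap", function(x) sort(unique(unname(x@assignments))))

setMethod("show", "CladeMap", function(object) {
  cat(sprintf("CladeMap: %d genomes in %d clades (minGeneCount = %g)\n",
              length(object@assignments),
              length(unique(object@assignments)), object@minGeneCount))
})

## CladePartition -------------------------------------------------------------

#' Clade-wise partition of a tRNA gene complement alignment
#'
#' The result of [partitionByClade()]: per retained clade, the indices of
#' its pooled gene set within the parent alignment, plus a report of clades
#' excluded for insufficient data.
#'
#' @slot alignment the parent [SprinzlAlignment-class].
#' @slot sets named list of integer gene indices, one element per retained
#'   clade.
#' @slot cladeOf named character vector, genome id -> clade label, for
#'   genomes in retained clades.
#' @slot excluded data.frame (`clade`, `genes`) for clades dropped below
#'   the minimum gene count.
#' @seealso [partitionByClade()], [leaveOneOutSets()], [estimateCladeLogos()]
#' @export
setClass("CladePartition",
         representation(alignment = "SprinzlAlignment", sets = "list",
                        cladeOf = "character", excluded = "data.frame"))

setValidity("CladePartition", function(object) {
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    return("sets must be a uniquely named list of gene index vectors")
  if (any(lengths(object@sets) < 1L))
    return("every retained clade must contain at least one gene")
  TRUE
})

#' @rdname tRNAcif-generics
#' @export
setMethod("cladeSets", "CladePartition", function(x) x@sets)

#' @rdname tRNAcif-generics
#' @export
setMethod("cladeLabels", "CladePartition", function(x) names(x@sets))

#' @rdname tRNAcif-generics
#' @export
setMethod("excludedClades", "CladePartition", function(x) x@excluded)

setMethod("show", "CladePartition", function(object) {
  cat(sprintf("CladePartition: %d retained clades (%s)\n",
              length(object@sets),
              paste(sprintf("%s: %d genes", names(object@sets),
                            lengths(object@sets)), collapse = ", ")))
  if (nrow(object@excluded))
    cat(sprintf("  excluded: %s\n",
                paste(sprintf("%s (%d genes)", object@excluded$clade,
                              object@excluded$genes), collapse = ", ")))
})

## FunctionLogo ---------------------------------------------------------------

#' Per-clade tRNA function logo
#'
#' For one clade, the Gorodkin heights of every observed feature
#' (base, Sprinzl coordinate) apportioned over the 22 functional classes,
#' together with the (sample-size-corrected) feature information in bits,
#' the gene support per feature, and the class background distribution the
#' heights were computed against.  Features carried by no gene in the clade
#' have no entry (implicitly zero).
#'
#' @slot clade clade label.
#' @slot heights numeric matrix, rows = observed features (named
#'   `"<base>@<coordinate>"`), columns = the 22 classes; entry is the height
#'   of that class at that feature in bits.
#' @slot info named numeric vector of feature information (bits); for every
#'   feature, `sum(heights[f, ])` equals `info[f]`.
#' @slot support named integer vector of gene counts carrying each feature.
#' @slot background named numeric class background distribution.
#' @slot coordinates the full coordinate label universe of the source
#'   alignment.
#' @seealso [estimateCladeLogos()], [gorodkinHeights()]
#' @export
setClass("FunctionLogo",
         representation(clade = "character", heights = "matrix",
                        info = "numeric", support = "integer",
                        background = "numeric", coordinates = "character"))

setValidity("FunctionLogo", function(object) {
  H <- object@heights
  if (nrow(H) && any(H < -1e-12)) return("heights must be non-negative")
  if (nrow(H) != length(object@info) || nrow(H) != length(object@support))
    return("heights, info and support must cover the same features")
  if (nrow(H) && max(abs(rowSums(H) - object@info)) > 1e-9)
    return("heights must sum to the feature information per feature")
  if (abs(sum(object@background) - 1) > 1e-9)
    return("background must be a probability distribution")
  TRUE
})

#' @rdname tRNAcif-generics
#' @export
setMethod("heights", "FunctionLogo", function(x) x@heights)

#' @rdname tRNAcif-generics
#' @export
setMethod("featureInfo", "FunctionLogo", function(x) x@info)

#' @rdname tRNAcif-generics
#' @export
setMethod("featureSupport", "FunctionLogo", function(x) x@support)

#' @rdname tRNAcif-generics
#' @export
setMethod("logoBackground", "FunctionLogo", function(x) x@background)

#' @rdname tRNAcif-generics
#' @export
setMethod("cladeLabels", "FunctionLogo", function(x) x@clade)

setMethod("show", "FunctionLogo", function(object) {
  cat(sprintf("FunctionLogo for clade '%s': %d features, total information %.3f bits\n",
              object@clade, nrow(object@heights), sum(object@info)))
})

## ScoreStandardizer ----------------------------------------------------------

#' Clade-score standardizer
#'
#' Per-clade means and standard deviations of training score vectors;
#' applied as `(S - mean) / sd` to both training and query scores.  Columns
#' with zero training variance are divided by 1 (the standardized column is
#' identically zero) rather than producing non-finite values.
#'
#' @slot center per-clade training means.
#' @slot scale per-clade training standard deviations (zeros replaced by 1).
#' @slot nTrain number of training vectors the standardizer was fitted on.
#' @slot cladeOrder clade label order the standardizer expects.
#' @seealso [fitStandardizer()], [applyStandardizer()]
#' @export
setClass("ScoreStandardizer",
         representation(center = "numeric", scale = "numeric",
                        nTrain = "integer", cladeOrder = "character"))

setValidity("ScoreStandardizer", function(object) {
  if (object@nTrain < 2L) return("standardizer must be fitted on >= 2 vectors")
  if (any(object@scale <= 0)) return("scale elements must be positive")
  if (length(object@center) != length(object@cladeOrder) ||
      length(object@scale) != length(object@cladeOrder))
    return("center/scale must match cladeOrder")
  TRUE
})

setMethod("show", "ScoreStandardizer", function(object) {
  cat(sprintf("ScoreStandardizer over %d clades, fitted on %d vectors\n",
              length(object@cladeOrder), object@nTrain))
})

## NetworkSpec ----------------------------------------------------------------

#' Multilayer-perceptron specification
#'
#' Architecture and optimization contract of the phyloclassifier network:
#' ReLU hidden layers, softmax output, L2-penalized cross-entropy minimized
#' by full-batch L-BFGS for at most `maxEpochs` iterations, stopping early
#' once the per-iteration loss decrease falls below `tol`.
#'
#' @slot hiddenLayers integer vector of hidden-layer widths.
#' @slot activation hidden activation; only `"relu"` is supported.
#' @slot l2Alpha L2 regularization penalty (default 0.01).
#' @slot maxEpochs maximum optimizer iterations (default 2000).
#' @slot tol minimum loss decrease for continuing (default 1e-4).
#' @slot seed RNG seed governing weight initialization.
#' @seealso [networkSpec()], [trainNetwork()]
#' @export
setClass("NetworkSpec",
         representation(hiddenLayers = "integer", activation = "character",
                        l2Alpha = "numeric", maxEpochs = "integer",
                        tol = "numeric", seed = "integer"))

setValidity("NetworkSpec", function(object) {
  if (length(object@hiddenLayers) < 1L || any(object@hiddenLayers < 1L))
    return("hiddenLayers must contain at least one positive width")
  if (object@activation != "relu") return("only the 'relu' activation is supported")
  if (object@tol <= 0) return("tol must be positive")
  if (object@maxEpochs < 1L) return("maxEpochs must be >= 1")
  TRUE
})

#' Construct a NetworkSpec
#'
#' @param hiddenLayers integer vector of hidden-layer widths (default a
#'   single hidden layer of 13 nodes, a typical outcome of
#'   [searchArchitecture()] at realistic clade counts).
#' @param l2Alpha L2 penalty (default 0.01).
#' @param maxEpochs maximum optimizer iterations (default 2000).
#' @param tol minimum loss decrease before early stop (default 1e-4).
#' @param seed RNG seed for weight initialization (default 1).
#' @return A [NetworkSpec-class] object.
#' @examples
#' networkSpec(hiddenLayers = c(13))
#' @export
networkSpec <- function(hiddenLayers = 13L, l2Alpha = 0.01,
                        maxEpochs = 2000L, tol = 1e-4, seed = 1L) {
  new("NetworkSpec", hiddenLayers = as.integer(hiddenLayers),
      activation = "relu", l2Alpha = as.numeric(l2Alpha),
      maxEpochs = as.integer(maxEpochs), tol = as.numeric(tol),
      seed = as.integer(seed))
}

setMethod("show", "NetworkSpec", function(object) {
  cat(sprintf("NetworkSpec: hidden [%s], relu, alpha %g, maxEpochs %d, tol %g, seed %d\n",
              paste(object@hiddenLayers, collapse = ", "), object@l2Alpha,
              object@maxEpochs, object@tol, object@seed))
})

## TrainedPhyloclassifier -----------------------------------------------------

#' Trained phyloclassifier
#'
#' A fitted multilayer perceptron together with the score standardizer and
#' the clade label order of its input and output dimensions.
#'
#' @slot spec the [NetworkSpec-class] the model was trained under.
#' @slot weights list of per-layer weight matrices and bias vectors.
#' @slot standardizer the [ScoreStandardizer-class] fitted on training
#'   scores, or `NULL` when standardization is managed externally.
#' @slot cladeOrder clade labels, fixing input feature order and output
#'   class order.
#' @slot trainingLog list with final `loss`, objective `evaluations`, and
#'   `converged` flag.
#' @seealso [trainNetwork()], [predictProbabilities()]
#' @export
setClass("TrainedPhyloclassifier",
         representation(spec = "NetworkSpec", weights = "list",
                        standardizer = "ANY", cladeOrder = "character",
                        trainingLog = "list"))

setMethod("show", "TrainedPhyloclassifier", function(object) {
  cat(sprintf("TrainedPhyloclassifier: %d clades (%s), hidden [%s]\n",
              length(object@cladeOrder),
              paste(object@cladeOrder, collapse = ", "),
              paste(object@spec@hiddenLayers, collapse = ", ")))
  cat(sprintf("  final loss %.6f after %d objective evaluations\n",
              object@trainingLog$loss, object@trainingLog$evaluations))
})

## Robustness results ---------------------------------------------------------

#' Permutation null distribution of classification accuracy
#'
#' @slot observed observed LOOCV accuracy.
#' @slot nullAccuracies accuracy per label-permutation replicate.
#' @slot pValue `(b + 1) / (B + 1)` where `b` is the number of null
#'   accuracies at or above the observed one.
#' @slot replicates number of permutation replicates `B`.
#' @seealso [permutationTest()]
#' @export
setClass("PermutationNull",
         representation(observed = "numeric", nullAccuracies = "numeric",
                        pValue = "numeric", replicates = "integer"))

setValidity("PermutationNull", function(object) {
  if (object@pValue <= 0 || object@pValue > 1) return("pValue must lie in (0, 1]")
  if (any(object@nullAccuracies < 0 | object@nullAccuracies > 1))
    return("null accuracies must lie in [0, 1]")
  TRUE
})

setMethod("show", "PermutationNull", function(object) {
  cat(sprintf("PermutationNull: observed accuracy %.4f, B = %d, p = %.4g\n",
              object@observed, object@replicates, object@pValue))
})

#' Alignment-site bootstrap summary
#'
#' @slot replicates number of site-bootstrap replicates.
#' @slot frequencies matrix (genome x clade) of replicate fractions in
#'   which each genome's top classification was each clade; rows sum to 1.
#' @slot correctCounts named vector: for genomes with a known clade, the
#'   number of replicates whose top classification equalled it (`NA` for
#'   queries without a reference clade).
#' @seealso [siteBootstrap()]
#' @export
setClass("BootstrapSummary",
         representation(replicates = "integer", frequencies = "matrix",
                        correctCounts = "numeric"))

setMethod("show", "BootstrapSummary", function(object) {
  known <- object@correctCounts[!is.na(object@correctCounts)]
  cat(sprintf("BootstrapSummary: %d replicates, %d genomes\n",
              object@replicates, nrow(object@frequencies)))
  if (length(known))
    cat(sprintf("  correct-clade counts: min %g / median %g of %d\n",
                min(known), stats::median(known), object@replicates))
})

#' One-vs-all confusion summary
#'
#' @slot confusion true x predicted count matrix.
#' @slot perClade data.frame of one-vs-all `precision`, `recall` and
#'   `balancedAccuracy` per clade.
#' @slot accuracy overall accuracy.
#' @seealso [confusionMetrics()]
#' @export
setClass("ConfusionSummary",
         representation(confusion = "matrix", perClade = "data.frame",
                        accuracy = "numeric"))

setMethod("show", "ConfusionSummary", function(object) {
  cat(sprintf("ConfusionSummary: overall accuracy %.4f\n", object@accuracy))
  print(round(object@perClade, 4))
})

## SyntheticDesign ------------------------------------------------------------

#' Synthetic clade-structured tRNA data design
#'
#' Parameters of the synthetic generator: K clades of genomes carrying tRNA
#' gene complements over a shared Sprinzl coordinate frame, with shared
#' class-identity determinants common to all clades (emulating universal
#' tRNA identity elements) and clade-specific planted determinants (the
#' ground-truth CIFs), each respected with probability `signal`.
#'
#' @slot nClades number of training clades K.
#' @slot genomesPerClade integer vector (recycled to K) of genomes per
#'   clade; unequal values give imbalanced designs.
#' @slot genesPerGenome inclusive range (length 2) of tRNA gene counts per
#'   genome.
#' @slot nCoordinates number of Sprinzl coordinates.
#' @slot classes functional classes in play (subset of
#'   [functionalClasses()]).
#' @slot nPlantedFeatures clade-specific planted determinants per clade.
#' @slot signal probability a determinant is respected in a gene.
#' @slot backgroundIdentity shared identity determinants per class.
#' @slot gapRate per-position gap probability at non-determinant positions.
#' @slot seed RNG seed; generation is deterministic given the design.
#' @seealso [syntheticDesign()], [generateDataset()]
#' @export
setClass("SyntheticDesign",
         representation(nClades = "integer", genomesPerClade = "integer",
                        genesPerGenome = "integer", nCoordinates = "integer",
                        classes = "character", nPlantedFeatures = "integer",
                        signal = "numeric", backgroundIdentity = "integer",
                        gapRate = "numeric", seed = "integer"))

setValidity("SyntheticDesign", function(object) {
  if (object@nClades < 1L) return("nClades must be >= 1")
  if (length(object@genesPerGenome) != 2L ||
      any(object@genesPerGenome < 1L) ||
      object@genesPerGenome[1L] > object@genesPerGenome[2L])
    return("genesPerGenome must be an increasing range of two positive integers")
  if (object@signal < 0 || object@signal > 1) return("signal must lie in [0, 1]")
  if (object@gapRate < 0 || object@gapRate > 1) return("gapRate must lie in [0, 1]")
  if (!all(object@classes %in% .CLASSES)) return("classes must be functional classes")
  if (anyDuplicated(object@classes)) return("classes must be unique")
  TRUE
})

#' Construct a SyntheticDesign
#'
#' Defaults emulate the scale of a well-sampled bacterial clade analysis:
#' 8 clades, 25 genomes per clade, 30-55 tRNA genes per genome spanning all
#' 22 functional classes over 72 Sprinzl coordinates, 20 planted
#' clade-specific determinants per clade respected with probability 0.9
#' over a background of shared identity signal plus uniform noise.
#'
#' @param nClades number of clades (default 8).
#' @param genomesPerClade genomes per clade, recycled to `nClades`
#'   (default 25).
#' @param genesPerGenome range of gene counts per genome (default
#'   `c(30, 55)`).
#' @param nCoordinates number of coordinates (default 72).
#' @param classes functional classes (default all 22).
#' @param nPlantedFeatures planted clade-specific determinants per clade
#'   (default 20).
#' @param signal probability a determinant is respected (default 0.9).
#' @param backgroundIdentity shared identity determinants per class
#'   (default 5).
#' @param gapRate gap probability at free positions (default 0.02).
#' @param seed RNG seed (default 1).
#' @return A [SyntheticDesign-class] object.
#' @examples
#' syntheticDesign(nClades = 3, genomesPerClade = 4,
#'                 genesPerGenome = c(25, 25), nCoordinates = 40)
#' @export
syntheticDesign <- function(nClades = 8L, genomesPerClade = 25L,
                            genesPerGenome = c(30L, 55L),
                            nCoordinates = 72L,
                            classes = functionalClasses(),
                            nPlantedFeatures = 20L, signal = 0.9,
                            backgroundIdentity = 5L, gapRate = 0.02,
                            seed = 1L) {
  new("SyntheticDesign",
      nClades = as.integer(nClades),
      genomesPerClade = as.integer(rep_len(genomesPerClade, nClades)),
      genesPerGenome = as.integer(genesPerGenome),
      nCoordinates = as.integer(nCoordinates),
      classes = as.character(classes),
      nPlantedFeatures = as.integer(nPlantedFeatures),
      signal = as.numeric(signal),
      backgroundIdentity = as.integer(backgroundIdentity),
      gapRate = as.numeric(gapRate),
      seed = as.integer(seed))
}

setMethod("show", "SyntheticDesign", function(object) {
  cat(sprintf(
    "SyntheticDesign: %d clades x {%s} genomes, %d-%d genes/genome, %d coordinates\n",
    object@nClades, paste(object@genomesPerClade, collapse = ","),
    object@genesPerGenome[1L], object@genesPerGenome[2L], object@nCoordinates))
  cat(sprintf("  %d planted features/clade, signal %.2f, gap rate %.2f, seed %d\n",
              object@nPlantedFeatures, object@signal, object@gapRate, object@seed))
})
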