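# Genome scoring against clade function logos, the leakage-free training
# score matrix, and score standardization.

# Build the full (4*C x 22) height matrix of a logo on the coordinate
# frame of an alignment.  Logo features at coordinates absent from the
# frame are dropped (query genes cannot carry them); frame features absent
# from the logo stay zero.
.logoHeightsOnFrame <- function(logo, coords) {
  C <- length(coords)
  Hfull <- matrix(0, 4L * C, length(.CLASSES))
  feats <- rownames(logo@heights)
  if (length(feats)) {
    parts <- strsplit(feats, "@", fixed = TRUE)
    b <- match(vapply(parts, `[`, "", 1L), .BASES)
    co <- match(vapply(parts, `[`, "", 2L), coords)
    keep <- !is.na(co)
    if (any(keep))
      Hfull[b[keep] + 4L * (co[keep] - 1L), ] <- logo@heights[keep, , drop = FALSE]
  }
  Hfull
}

#' Score genome tRNA complements against clade logos
#'
#' For each genome `g` and clade `X`, computes the mean over the genome's
#' genes of the summed Gorodkin heights of the features each gene carries,
#' taken at the gene's own functional class:
#' `S_g^X = (1/|T_g|) * sum_{t in T_g} sum_{f in t} h^{i_t}_{f,X}`
#' (bits per gene).  Features, coordinates or classes absent from a logo
#' contribute zero, and gaps carry no features, so reduced query
#' complements score without error.
#'
#' @param aln a [SprinzlAlignment-class] of one or more genome complements
#'   with functional types assigned.
#' @param logos named list of [FunctionLogo-class] (as from
#'   [estimateCladeLogos()]).
#' @return Numeric matrix, rows = genomes, columns = clades
#'   (in `names(logos)` order), in bits per gene.
#' @seealso [buildTrainingMatrix()] for leakage-free training scores.
#' @export
scoreGenomes <- function(aln, logos) {
  stopifnot(is(aln, "SprinzlAlignment"), length(logos) >= 1L)
  if (nrow(aln@seqs) == 0L) stop("empty gene complement")
  ca <- .countArrays(aln@seqs, aln@geneInfo)
  C <- ncol(aln@seqs)
  Mflat <- matrix(ca$cnt, nrow = 4L * C * length(.CLASSES))
  Hmat <- vapply(logos, function(lg)
    as.vector(.logoHeightsOnFrame(lg, colnames(aln@seqs))),
    numeric(4L * C * length(.CLASSES)))
  S <- crossprod(Mflat, Hmat) / ca$genes
  dimnames(S) <- list(ca$genomes, names(logos))
  S
}

#' Score a single genome complement
#'
#' Convenience wrapper around [scoreGenomes()] for one genome.
#'
#' @param aln a [SprinzlAlignment-class]; must contain exactly one genome
#'   unless `genomeId` selects one.
#' @param logos named list of [FunctionLogo-class].
#' @param genomeId genome to score when the alignment holds several.
#' @return Named numeric score vector over clades (bits per gene).
#' @export
scoreComplement <- function(aln, logos, genomeId = NULL) {
  if (!is.null(genomeId))
    aln <- aln[aln@geneInfo$genome_id == genomeId, ]
  if (length(unique(aln@geneInfo$genome_id)) != 1L)
    stop("alignment holds multiple genomes; give genomeId")
  drop(scoreGenomes(aln, logos))
}

#' Leakage-free training score matrix
#'
#' Scores every training genome `g` against logos re-estimated from the
#' leave-one-out sets `T_X - T_g` (the genome's own genes removed from its
#' clade's pooled set before logo estimation), so no genome's score vector
#' contains information contributed by its own genes.  Only the genome's
#' own clade's logo changes under leave-one-out; other clades' logos equal
#' the full-data logos.
#'
#' @inheritParams estimateCladeLogos
#' @return Numeric matrix (training genomes x clades, bits per gene) with
#'   attributes `labels` (true clade per row) and `cladeOrder`.
#' @export
buildTrainingMatrix <- function(partition,
                                background = c("clade_frequencies", "uniform",
                                               "pooled_frequencies"),
                                correction = c("miller_madow", "exact_small_n",
                                               "none")) {
  background <- match.arg(background)
  correction <- match.arg(correction)
  stopifnot(is(partition, "CladePartition"))
  aln <- partition@alignment
  trainIdx <- sort(unlist(partition@sets, use.names = FALSE))
  seqs <- aln@seqs[trainIdx, , drop = FALSE]
  info <- aln@geneInfo[trainIdx, , drop = FALSE]
  ca <- .countArrays(seqs, info)
  C <- ncol(seqs)
  K <- length(partition@sets)
  clades <- names(partition@sets)
  nFeat <- 4L * C * length(.CLASSES)
  memberOf <- lapply(partition@sets, function(idx)
    unique(aln@geneInfo$genome_id[idx]))
  cladeCnt <- lapply(clades, function(cl)
    .sumOver(ca$cnt, match(memberOf[[cl]], ca$genomes)))
  names(cladeCnt) <- clades
  cladeClassCnt <- lapply(clades, function(cl)
    rowSums(ca$classCnt[, match(memberOf[[cl]], ca$genomes), drop = FALSE]))
  names(cladeClassCnt) <- clades
  pooledCnt <- rowSums(ca$classCnt)
  # full-data heights per clade, for the columns where leave-one-out does
  # not change the training set
  Hfull <- vapply(clades, function(cl) {
    q <- .backgroundFromCounts(cladeClassCnt[[cl]], background, pooledCnt)
    as.vector(.logoCompute(cladeCnt[[cl]], q, correction)$H)
  }, numeric(nFeat))
  Mflat <- matrix(ca$cnt, nrow = nFeat)
  S <- crossprod(Mflat, Hfull) / ca$genes
  dimnames(S) <- list(ca$genomes, clades)
  cladeOfGenome <- partition@cladeOf[ca$genomes]
  d3 <- dim(ca$cnt)[1:3]
  for (gIdx in seq_along(ca$genomes)) {
    cl <- cladeOfGenome[[gIdx]]
    gCnt <- array(ca$cnt[, , , gIdx, drop = FALSE], dim = d3)
    looCnt <- cladeCnt[[cl]] - gCnt
    looClassCnt <- cladeClassCnt[[cl]] - ca$classCnt[, gIdx]
    if (sum(looClassCnt) == 0)
      stop("clade '", cl, "' contains only the genes of genome '",
           ca$genomes[gIdx], "' (degenerate clade under leave-one-out)")
    q <- .backgroundFromCounts(looClassCnt, background,
                               pooledCnt - ca$classCnt[, gIdx])
    Hloo <- .logoCompute(looCnt, q, correction)$H
    S[gIdx, cl] <- sum(gCnt * array(Hloo, dim = d3)) / ca$genes[[gIdx]]
  }
  attr(S, "labels") <- unname(cladeOfGenome)
  attr(S, "cladeOrder") <- clades
  S
}

#' Fit a score standardizer
#'
#' Computes per-clade means and standard deviations of a training score
#' matrix.  Columns with zero variance get scale 1 (their standardized
#' values are identically zero), with a warning.
#'
#' @param scores training score matrix (genomes x clades).
#' @return A [ScoreStandardizer-class].
#' @export
fitStandardizer <- function(scores) {
  if (nrow(scores) < 2L) stop("standardizer must be fitted on >= 2 score vectors")
  ctr <- colMeans(scores)
  sc <- apply(scores, 2L, sd)
  if (any(sc == 0)) {
    warning("zero-variance score column(s) ",
            paste(colnames(scores)[sc == 0], collapse = ", "),
            "; scale set to 1")
    sc[sc == 0] <- 1
  }
  new("ScoreStandardizer", center = ctr, scale = sc,
      nTrain = nrow(scores), cladeOrder = colnames(scores))
}

#' Apply a score standardizer
#'
#' Standardizes score vectors element-wise: `(S - mean) / sd`.
#'
#' @param scores score matrix or single named score vector with clades
#'   matching the standardizer's `cladeOrder`.
#' @param standardizer a [ScoreStandardizer-class].
#' @return Standardized scores with the shape of the input.
#' @export
applyStandardizer <- function(scores, standardizer) {
  stopifnot(is(standardizer, "ScoreStandardizer"))
  if (is.null(dim(scores))) scores <- matrix(scores, 1L,
                                             dimnames = list(NULL, names(scores)))
  if (!identical(colnames(scores), standardizer@cladeOrder))
    stop("clade order of scores does not match the standardizer")
  sweep(sweep(scores, 2L, standardizer@center, "-"),
        2L, standardizer@scale, "/")
}

#' Write / read a score matrix as TSV
#'
#' Rows are genomes, columns clades, with a `standardized` flag column;
#' readable back losslessly.
#'
#' @param scores score matrix with genome rownames.
#' @param path file path.
#' @param standardized whether the scores are standardized.
#' @return `writeScoreMatrix()` returns `path` invisibly;
#'   `readScoreMatrix()` returns the score matrix with attribute
#'   `standardized`.
#' @export
writeScoreMatrix <- function(scores, path, standardized = FALSE) {
  header <- paste(c("genome_id", "standardized", colnames(scores)),
                  collapse = "\t")
  body <- vapply(seq_len(nrow(scores)), function(i) {
    paste(c(rownames(scores)[i], standardized,
            sprintf("%.17g", scores[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname writeScoreMatrix
#' @export
readScoreMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  S <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(S) <- df$genome_id
  attr(S, "standardized") <- all(as.logical(df$standardized))
  S
}
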