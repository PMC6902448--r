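# Clade partitioning, leave-one-out training sets and complement summaries.

#' @include AllClasses.R
NULL

#' Partition a tRNA gene complement by clade
#'
#' Pools the genes of each genome into per-clade gene sets.  Clades whose
#' pooled gene count falls below the clade map's `minGeneCount` are
#' excluded and reported rather than retained (mirroring the exclusion of
#' poorly sampled clades from training).  Genomes present in the alignment
#' but absent from the map are an error unless listed in `queryGenomes`,
#' in which case their genes are simply left out of the partition.
#'
#' @param aln a [SprinzlAlignment-class].
#' @param map a [CladeMap-class].
#' @param queryGenomes genome ids present in the alignment that are
#'   query-only and carry no clade assignment.
#' @return A [CladePartition-class].
#' @examples
#' aln <- sprinzlAlignment(c(g1 = "ACG", g2 = "ACG"), as.character(1:3),
#'                         genomeId = c("G1", "G2"), functionalType = "L")
#' partitionByClade(aln, cladeMap(c(G1 = "A", G2 = "B"), minGeneCount = 1))
#' @export
partitionByClade <- function(aln, map, queryGenomes = character(0)) {
  stopifnot(is(aln, "SprinzlAlignment"), is(map, "CladeMap"))
  if (length(map@assignments) == 0L)
    stop("clade map is empty")
  gi <- aln@geneInfo
  genomes <- unique(gi$genome_id)
  unknown <- setdiff(genomes, c(names(map@assignments), queryGenomes))
  if (length(unknown))
    stop("genomes with no clade assignment and not flagged as queries: ",
         paste(head(unknown), collapse = ", "))
  training <- !(gi$genome_id %in% queryGenomes)
  clade <- map@assignments[gi$genome_id]
  idxByClade <- split(which(training), clade[training])
  counts <- lengths(idxByClade)
  keep <- counts >= map@minGeneCount
  excluded <- data.frame(clade = names(idxByClade)[!keep],
                         genes = unname(counts[!keep]),
                         stringsAsFactors = FALSE)
  sets <- idxByClade[keep]
  if (length(sets) == 0L)
    stop("no clade reaches the minimum gene count of ", map@minGeneCount)
  cladeOf <- map@assignments[intersect(names(map@assignments),
                                       gi$genome_id[training])]
  cladeOf <- cladeOf[cladeOf %in% names(sets)]
  new("CladePartition", alignment = aln, sets = sets,
      cladeOf = cladeOf, excluded = excluded)
}

#' Leave-one-out training sets
#'
#' Returns the partition with the genes of one genome removed from its own
#' clade's pooled gene set; all other clades are untouched.  If the genome
#' is not part of any retained training clade the partition is returned
#' unchanged.  Removing the genome must not empty its clade.
#'
#' @param partition a [CladePartition-class].
#' @param genomeId the genome to hold out.
#' @return A [CladePartition-class] of the leave-one-out training sets.
#' @export
leaveOneOutSets <- function(partition, genomeId) {
  stopifnot(is(partition, "CladePartition"))
  gi <- partition@alignment@geneInfo
  if (!genomeId %in% gi$genome_id)
    stop("genome '", genomeId, "' is not present in the alignment")
  if (!genomeId %in% names(partition@cladeOf)) return(partition)
  cl <- unname(partition@cladeOf[[genomeId]])
  sets <- partition@sets
  keep <- sets[[cl]][gi$genome_id[sets[[cl]]] != genomeId]
  if (length(keep) == 0L)
    stop("removing genome '", genomeId, "' leaves clade '", cl,
         "' without genes (degenerate clade)")
  sets[[cl]] <- keep
  new("CladePartition", alignment = partition@alignment, sets = sets,
      cladeOf = partition@cladeOf, excluded = partition@excluded)
}

.groupSummary <- function(seqs, info) {
  nonGap <- seqs != .GAP
  N <- sum(nonGap)
  baseCount <- vapply(.BASES, function(b) sum(seqs == b), numeric(1))
  data.frame(genomes = length(unique(info$genome_id)),
             genes = nrow(seqs),
             genesPerGenome = nrow(seqs) / length(unique(info$genome_id)),
             bases = N,
             basesPerGene = N / nrow(seqs),
             pctA = 100 * baseCount[["A"]] / N,
             pctU = 100 * baseCount[["U"]] / N,
             pctG = 100 * baseCount[["G"]] / N,
             pctC = 100 * baseCount[["C"]] / N,
             stringsAsFactors = FALSE)
}

#' @rdname complementSummary-methods
#' @export
setMethod("complementSummary", "CladePartition", function(x, ...) {
  res <- do.call(rbind, lapply(names(x@sets), function(cl) {
    idx <- x@sets[[cl]]
    cbind(data.frame(group = cl, stringsAsFactors = FALSE),
          .groupSummary(x@alignment@seqs[idx, , drop = FALSE],
                        x@alignment@geneInfo[idx, , drop = FALSE]))
  }))
  rownames(res) <- NULL
  res
})

#' @rdname complementSummary-methods
#' @export
setMethod("complementSummary", "SprinzlAlignment", function(x, by = c("all", "genome"), ...) {
  by <- match.arg(by)
  if (by == "all") {
    res <- cbind(data.frame(group = "all", stringsAsFactors = FALSE),
                 .groupSummary(x@seqs, x@geneInfo))
  } else {
    res <- do.call(rbind, lapply(genomeIds(x), function(g) {
      idx <- which(x@geneInfo$genome_id == g)
      cbind(data.frame(group = g, stringsAsFactors = FALSE),
            .groupSummary(x@seqs[idx, , drop = FALSE],
                          x@geneInfo[idx, , drop = FALSE]))
    }))
  }
  rownames(res) <- NULL
  res
})

#' Summary tables of tRNA gene complements
#'
#' @name complementSummary-methods
#' @aliases complementSummary
#' @description
#' Per group (clade, genome, or the pooled set), reports the number of
#' genomes (G), genes (T), genes per genome (T/G), total non-gap bases (N),
#' bases per gene (N/T) and the A/U/G/C percentages of non-gap bases.
#' Ratios are returned at full precision; use [formatComplementSummary()]
#' for the conventional two-decimal display.
#' @param x a [CladePartition-class] or [SprinzlAlignment-class].
#' @param by `"all"` for one pooled row or `"genome"` for one row per
#'   genome (alignment method only).
#' @param ... unused.
#' @return A data.frame with one row per group.
NULL

#' Format a complement summary for display
#'
#' Rounds ratio and percentage columns to two decimals, the conventional
#' display precision for complement summary tables.
#'
#' @param summary a data.frame from [complementSummary()].
#' @return The data.frame with rounded display columns.
#' @export
formatComplementSummary <- function(summary) {
  for (cl in c("genesPerGenome", "basesPerGene", "pctA", "pctU", "pctG", "pctC"))
    if (cl %in% names(summary)) summary[[cl]] <- round(summary[[cl]], 2)
  summary
}

#' Summary ratios from printed counts
#'
#' Computes the genes-per-genome (T/G) and bases-per-gene (N/T) ratios from
#' genome, gene and base counts, rounded to the two-decimal display
#' precision of complement summary tables.
#'
#' @param genomes genome count G.
#' @param genes gene count T.
#' @param bases non-gap base count N (optional).
#' @return A list with `genesPerGenome` and (when `bases` is given)
#'   `basesPerGene`.
#' @examples
#' summaryFromCounts(genomes = 11, genes = 555, bases = 40362)
#' @export
summaryFromCounts <- function(genomes, genes, bases = NULL) {
  out <- list(genesPerGenome = round(genes / genomes, 2))
  if (!is.null(bases)) out$basesPerGene <- round(bases / genes, 2)
  out
}
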