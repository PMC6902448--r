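# Functional typing by anticodon, prediction filtering and column pruning.

#' Assign functional types from anticodons
#'
#' Types each untyped gene by its anticodon: the anticodon is
#' reverse-complemented to its codon and translated with the standard
#' genetic code, yielding an elongator isoacceptor class.  Genes carrying
#' the CAU anticodon are ambiguous between elongator Met ("M"), initiator
#' ("X") and Ile-CAU ("J") and cannot be discriminated from sequence alone;
#' explicit labels are the supported path for them, with `cauPolicy`
#' controlling the fallback when no label is present.  Genes that already
#' carry an explicit functional type keep it.
#'
#' @param aln a [SprinzlAlignment-class].
#' @param cauPolicy what to do with unlabeled CAU-anticodon genes:
#'   `"labels_required"` (error, default), or `"default_M"`, `"default_X"`,
#'   `"default_J"` to assign that class.
#' @return The alignment with `functional_type` filled in.
#' @examples
#' aln <- sprinzlAlignment(c(g1 = "ACGUA", g2 = "ACGUA"),
#'                         coordinates = as.character(1:5),
#'                         genomeId = "G1", anticodon = c("GAA", "UGC"))
#' geneData(assignFunctionalTypes(aln))$functional_type  # "F", "A"
#' @export
assignFunctionalTypes <- function(aln,
                                  cauPolicy = c("labels_required", "default_M",
                                                "default_X", "default_J")) {
  cauPolicy <- match.arg(cauPolicy)
  gi <- aln@geneInfo
  todo <- which(is.na(gi$functional_type))
  if (length(todo) == 0L) return(aln)
  ac <- gi$anticodon[todo]
  if (anyNA(ac))
    stop("genes without an anticodon or an explicit functional type: ",
         paste(head(gi$gene_id[todo][is.na(ac)]), collapse = ", "))
  bad <- !grepl("^[ACGU]{3}$", ac)
  if (any(bad))
    stop("invalid anticodon '", ac[bad][1L], "' for gene '",
         gi$gene_id[todo][bad][1L], "'")
  isCAU <- ac == "CAU"
  if (any(!isCAU)) {
    acs <- Biostrings::RNAStringSet(ac[!isCAU])
    aa <- as.character(Biostrings::translate(Biostrings::reverseComplement(acs)))
    if (any(aa == "*")) {
      i <- which(aa == "*")[1L]
      stop("anticodon '", ac[!isCAU][i], "' of gene '",
           gi$gene_id[todo][!isCAU][i], "' maps to a stop codon")
    }
    gi$functional_type[todo[!isCAU]] <- aa
  }
  if (any(isCAU)) {
    if (cauPolicy == "labels_required")
      stop("CAU-anticodon genes without explicit functional type labels: ",
           paste(head(gi$gene_id[todo][isCAU]), collapse = ", "),
           " (set cauPolicy to resolve them)")
    gi$functional_type[todo[isCAU]] <-
      switch(cauPolicy, default_M = "M", default_X = "X", default_J = "J")
  }
  new("SprinzlAlignment", seqs = aln@seqs, geneInfo = gi)
}

#' Filter tRNA gene predictions
#'
#' Applies prediction-level false-positive filters: an anticodon whitelist
#' (genes whose anticodon is not on the list are discarded, mirroring the
#' removal of predictions with anticodons never observed in the target
#' genome family) and an intron blacklist (intron-flagged predictions are
#' discarded when their isotype is not known to carry introns).  Genes
#' named in `excludeGenes` are removed unconditionally, supporting manual
#' curation lists.  With no rules enabled the input is returned unchanged.
#'
#' @param aln a [SprinzlAlignment-class].
#' @param anticodonWhitelist character vector of permitted anticodons, or
#'   `NULL` to disable.  Genes with no recorded anticodon always pass.
#' @param intronBlacklist character vector of functional types for which
#'   intron-flagged predictions are rejected, or `NULL` to disable.
#' @param excludeGenes character vector of `gene_id`s to drop, or `NULL`.
#' @return A list with `alignment` (the filtered [SprinzlAlignment-class])
#'   and `rejections` (data.frame of `gene_id`, `rule`).
#' @export
filterPredictions <- function(aln, anticodonWhitelist = NULL,
                              intronBlacklist = NULL, excludeGenes = NULL) {
  gi <- aln@geneInfo
  rej <- data.frame(gene_id = character(0), rule = character(0),
                    stringsAsFactors = FALSE)
  drop <- rep(FALSE, nrow(gi))
  note <- function(idx, rule) {
    idx <- idx & !drop
    if (any(idx))
      rej <<- rbind(rej, data.frame(gene_id = gi$gene_id[idx], rule = rule,
                                    stringsAsFactors = FALSE))
    drop <<- drop | idx
  }
  if (!is.null(excludeGenes))
    note(gi$gene_id %in% excludeGenes, "exclude_genes")
  if (!is.null(anticodonWhitelist)) {
    if (!is.character(anticodonWhitelist) || length(anticodonWhitelist) == 0L)
      stop("anticodon whitelist must be a non-empty character vector")
    note(!is.na(gi$anticodon) & !(gi$anticodon %in% anticodonWhitelist),
         "anticodon_whitelist")
  }
  if (!is.null(intronBlacklist))
    note(gi$intron %in% TRUE & gi$functional_type %in% intronBlacklist,
         "intron_blacklist")
  list(alignment = aln[!drop, ], rejections = rej)
}

#' Read prediction-filter rules from a key-value config file
#'
#' The file holds `key = value` lines with keys `anticodon_whitelist`,
#' `intron_blacklist` and `exclude_genes`, each value a comma-separated
#' list.  Unknown keys or non key-value lines are a configuration error.
#'
#' @param path file path.
#' @return A named list with elements `anticodonWhitelist`,
#'   `intronBlacklist`, `excludeGenes` (each possibly `NULL`), suitable for
#'   `do.call(filterPredictions, c(list(aln), rules))`.
#' @export
readFilterRules <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  keys <- c(anticodon_whitelist = "anticodonWhitelist",
            intron_blacklist = "intronBlacklist",
            exclude_genes = "excludeGenes")
  out <- list(anticodonWhitelist = NULL, intronBlacklist = NULL,
              excludeGenes = NULL)
  for (l in ln) {
    if (!grepl("=", l, fixed = TRUE))
      stop("malformed filter config line: ", l)
    key <- trimws(sub("=.*", "", l))
    val <- trimws(sub("^[^=]*=", "", l))
    if (!key %in% names(keys))
      stop("unknown filter config key: ", key)
    out[[keys[[key]]]] <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
  }
  out
}

#' Prune alignment columns
#'
#' Removes every column whose gap fraction is at or above `gapThreshold`
#' (inclusive, so a threshold of 0.99 removes columns with 99% or more
#' gaps), then removes columns whose coordinate labels appear in
#' `dropCoordinates` (e.g. variable-arm or CCA-tail labels).  Gene
#' sequences are sliced consistently.  Pruning is idempotent at a fixed
#' threshold.
#'
#' @param aln a [SprinzlAlignment-class].
#' @param gapThreshold gap fraction at or above which a column is removed;
#'   in `(0, 1]` (default 0.99).
#' @param dropCoordinates coordinate labels to remove unconditionally.
#' @return The pruned [SprinzlAlignment-class].
#' @export
pruneColumns <- function(aln, gapThreshold = 0.99,
                         dropCoordinates = character(0)) {
  if (gapThreshold <= 0 || gapThreshold > 1)
    stop("gapThreshold must lie in (0, 1]")
  gapFrac <- colMeans(aln@seqs == .GAP)
  keep <- gapFrac < gapThreshold & !(colnames(aln@seqs) %in% dropCoordinates)
  if (!any(keep)) stop("pruning removed all alignment columns")
  aln[, which(keep)]
}
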