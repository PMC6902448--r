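# Reading and writing Sprinzl-aligned tRNA gene complements.
#
# Two plain-text formats are supported:
#
# * tabular: a first line "#coordinates: <lab1> <lab2> ..." followed by a
#   TSV with columns gene_id, genome_id, functional_type, anticodon,
#   aligned_seq and optionally intron.
#
# * Stockholm: sequences one per line, Sprinzl coordinate labels in a
#   file-level "#=GF SPRINZL_COORDS <lab1> <lab2> ..." annotation (labels
#   such as "20a" are multi-character, so they cannot live in a
#   one-character-per-column #=GC row), and per-gene metadata in
#   "#=GS <gene> GENOME|TYPE|AC|INTRON <value>" lines.

#' Read Sprinzl-aligned tRNA genes
#'
#' Reads an aligned tRNA gene complement with its Sprinzl coordinate frame
#' and per-gene metadata, normalizing sequences to the RNA alphabet
#' (case-folded, `T` to `U`, ambiguity codes to gaps).
#'
#' @param path file path.
#' @param format `"tabular"` or `"stockholm"` (see Details in
#'   [writeAlignedGenes()] for the layouts).
#' @return A [SprinzlAlignment-class].
#' @seealso [writeAlignedGenes()], [sprinzlAlignment()]
#' @export
readAlignedGenes <- function(path, format = c("tabular", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         tabular = .readTabular(path),
         stockholm = .readStockholm(path))
}

.readTabular <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^#\\s*coordinates:", first))
    stop("tabular alignment must start with a '#coordinates: ...' header line")
  coords <- strsplit(trimws(sub("^#\\s*coordinates:", "", first)), "\\s+")[[1L]]
  df <- read.delim(path, skip = 1L, colClasses = "character",
                   na.strings = c("", "NA"))
  need <- c("gene_id", "genome_id", "aligned_seq")
  if (!all(need %in% names(df)))
    stop("tabular alignment needs columns: ", paste(need, collapse = ", "))
  sprinzlAlignment(
    sequences = df$aligned_seq,
    coordinates = coords,
    genomeId = df$genome_id,
    geneId = df$gene_id,
    functionalType = if ("functional_type" %in% names(df)) df$functional_type else NA,
    anticodon = if ("anticodon" %in% names(df)) df$anticodon else NA,
    intron = if ("intron" %in% names(df)) as.logical(df$intron) else FALSE)
}

.readStockholm <- function(path) {
  ln <- readLines(path)
  coordLine <- grep("^#=GF\\s+SPRINZL_COORDS\\s+", ln, value = TRUE)
  if (length(coordLine) == 0L)
    stop("Stockholm alignment is missing the '#=GF SPRINZL_COORDS' coordinate row")
  coords <- strsplit(trimws(sub("^#=GF\\s+SPRINZL_COORDS\\s+", "", coordLine[1L])),
                     "\\s+")[[1L]]
  gs <- ln[grepl("^#=GS\\s+", ln)]
  meta <- list()
  for (l in gs) {
    p <- strsplit(trimws(sub("^#=GS\\s+", "", l)), "\\s+")[[1L]]
    if (length(p) < 3L) next
    id <- p[1L]; tag <- p[2L]; val <- paste(p[-(1:2)], collapse = " ")
    if (is.null(meta[[id]])) meta[[id]] <- list()
    meta[[id]][[tag]] <- val
  }
  body <- ln[!grepl("^#", ln) & !grepl("^//", ln) & nzchar(trimws(ln))]
  seqs <- character(0)
  for (l in body) {
    p <- strsplit(trimws(l), "\\s+")[[1L]]
    if (length(p) != 2L)
      stop("malformed Stockholm sequence line: ", l)
    seqs[p[1L]] <- paste0(if (p[1L] %in% names(seqs)) seqs[[p[1L]]] else "", p[2L])
  }
  if (length(seqs) == 0L) stop("no sequences found in Stockholm file")
  get <- function(id, tag, default = NA_character_) {
    v <- meta[[id]][[tag]]
    if (is.null(v)) default else v
  }
  ids <- names(seqs)
  sprinzlAlignment(
    sequences = unname(seqs),
    coordinates = coords,
    genomeId = vapply(ids, get, "", tag = "GENOME"),
    geneId = ids,
    functionalType = vapply(ids, get, "", tag = "TYPE"),
    anticodon = vapply(ids, get, "", tag = "AC"),
    intron = as.logical(vapply(ids, get, "", tag = "INTRON", default = "FALSE")))
}

#' Write Sprinzl-aligned tRNA genes
#'
#' Writes an alignment so that [readAlignedGenes()] reproduces sequences,
#' coordinates and gene metadata exactly.
#'
#' @details The tabular layout is a `#coordinates:` header line followed by
#' a TSV with columns `gene_id`, `genome_id`, `functional_type`,
#' `anticodon`, `aligned_seq`, `intron`.  The Stockholm layout stores the
#' coordinate labels in a `#=GF SPRINZL_COORDS` annotation and per-gene
#' genome/type/anticodon/intron metadata in `#=GS` lines.
#'
#' @param aln a [SprinzlAlignment-class].
#' @param path output file path.
#' @param format `"tabular"` or `"stockholm"`.
#' @return `path`, invisibly.
#' @export
writeAlignedGenes <- function(aln, path, format = c("tabular", "stockholm")) {
  format <- match.arg(format)
  stopifnot(is(aln, "SprinzlAlignment"))
  gi <- aln@geneInfo
  seqs <- apply(aln@seqs, 1L, paste, collapse = "")
  if (format == "tabular") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste("#coordinates:",
                     paste(sprinzlCoordinates(aln), collapse = " ")), con)
    df <- data.frame(gene_id = gi$gene_id, genome_id = gi$genome_id,
                     functional_type = gi$functional_type,
                     anticodon = gi$anticodon,
                     aligned_seq = unname(seqs),
                     intron = gi$intron,
                     stringsAsFactors = FALSE)
    suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE, na = ""))
  } else {
    out <- c("# STOCKHOLM 1.0",
             paste("#=GF SPRINZL_COORDS",
                   paste(sprinzlCoordinates(aln), collapse = " ")))
    for (i in seq_len(nrow(gi))) {
      id <- gi$gene_id[i]
      out <- c(out, paste("#=GS", id, "GENOME", gi$genome_id[i]))
      if (!is.na(gi$functional_type[i]))
        out <- c(out, paste("#=GS", id, "TYPE", gi$functional_type[i]))
      if (!is.na(gi$anticodon[i]))
        out <- c(out, paste("#=GS", id, "AC", gi$anticodon[i]))
      if (isTRUE(gi$intron[i]))
        out <- c(out, paste("#=GS", id, "INTRON", "TRUE"))
    }
    w <- max(nchar(gi$gene_id)) + 2L
    out <- c(out, paste0(formatC(gi$gene_id, width = -w), unname(seqs)), "//")
    writeLines(out, path)
  }
  invisible(path)
}
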