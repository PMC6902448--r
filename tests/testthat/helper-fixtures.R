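# Shared fixtures and independent brute-force oracles.  The oracles
# enumerate genes, features and classes directly from first principles and
# never call the package's vectorized estimation path.

# A small hand-built alignment: `spec` is a data.frame with columns
# gene, genome, type, seq (and optionally anticodon).
makeAln <- function(df, coords = NULL) {
  if (is.null(coords)) coords <- as.character(seq_len(nchar(df$seq[1])))
  sprinzlAlignment(df$seq, coords, genomeId = df$genome, geneId = df$gene,
                   functionalType = df$type,
                   anticodon = if ("anticodon" %in% names(df)) df$anticodon else NA)
}

uniformBackground <- function(classes = functionalClasses())
  stats::setNames(rep(1 / length(classes), length(classes)), classes)

# Brute-force Gorodkin-height logo for one gene set: loops over every
# (base, coordinate) feature and class, evaluating the definitions
# directly.  q: named background over the 22 classes (zeros allowed).
bruteLogo <- function(aln, q, correction = "none") {
  seqs <- aln@seqs
  info <- geneData(aln)
  classes <- functionalClasses()
  out <- list()
  for (co in colnames(seqs)) {
    for (b in c("A", "C", "G", "U")) {
      hit <- seqs[, co] == b
      n <- sum(hit)
      if (n == 0) next
      p <- numeric(length(classes))
      names(p) <- classes
      for (cl in classes) p[cl] <- sum(hit & info$functional_type == cl) / n
      raw <- 0
      for (cl in classes) if (p[cl] > 0) raw <- raw + p[cl] * log2(p[cl] / q[cl])
      corr <- switch(correction,
                     none = 0,
                     miller_madow = (sum(q > 0) - 1) / (2 * log(2) * n),
                     stop("unsupported in oracle"))
      D <- max(raw - corr, 0)
      ratio <- ifelse(q > 0, p / q, 0)
      h <- if (sum(ratio) > 0) D * ratio / sum(ratio) else ratio * 0
      out[[paste0(b, "@", co)]] <- list(n = n, D = D, h = h)
    }
  }
  out
}

# Brute-force Eq.-1 score of one genome against a brute-force logo:
# triple loop over genes, coordinates and the gene's class height.
bruteScore <- function(aln, genome, logo) {
  seqs <- aln@seqs
  info <- geneData(aln)
  rows <- which(info$genome_id == genome)
  total <- 0
  for (r in rows) {
    cls <- info$functional_type[r]
    for (co in colnames(seqs)) {
      b <- seqs[r, co]
      if (b == "-") next
      f <- paste0(b, "@", co)
      if (!is.null(logo[[f]])) total <- total + logo[[f]]$h[[cls]]
    }
  }
  total / length(rows)
}

# Exhaustive one-vs-all confusion metrics by direct tp/fp/fn/tn counting.
bruteConfusion <- function(truth, pred, labels) {
  res <- list()
  for (L in labels) {
    tp <- sum(truth == L & pred == L)
    fp <- sum(truth != L & pred == L)
    fn <- sum(truth == L & pred != L)
    tn <- sum(truth != L & pred != L)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    tnr <- if (tn + fp > 0) tn / (tn + fp) else 0
    res[[L]] <- c(precision = prec, recall = rec,
                  balancedAccuracy = (rec + tnr) / 2)
  }
  res
}

# A tiny linearly separable two-clade score fixture.
separableScores <- function(nPerClade = 8, margin = 4, seed = 1) {
  set.seed(seed)
  S <- rbind(matrix(rnorm(nPerClade * 2, margin), nPerClade, 2),
             matrix(rnorm(nPerClade * 2, -margin), nPerClade, 2))
  colnames(S) <- c("cladeA", "cladeB")
  rownames(S) <- paste0("g", seq_len(2 * nPerClade))
  attr(S, "labels") <- rep(c("cladeA", "cladeB"), each = nPerClade)
  S
}
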