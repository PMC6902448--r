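# Internal numeric core: per-genome feature-count arrays and vectorized
# Gorodkin-height computation.  Features are indexed base-major over the
# alignment columns, so a (4 x C x 22) count array flattens to the
# (feature x class) matrix used throughout with feature index
# b + 4 * (c - 1).

.featureNames <- function(coords)
  paste0(rep(.BASES, times = length(coords)), "@", rep(coords, each = 4L))

# Per-genome count arrays over (base, coordinate, class).
# Returns cnt (4 x C x 22 x G), classCnt (22 x G), genes (per-genome gene
# counts) and the genome order.
.countArrays <- function(seqs, info) {
  C <- ncol(seqs)
  genomes <- unique(info$genome_id)
  G <- length(genomes)
  gi <- match(info$genome_id, genomes)
  ci <- match(info$functional_type, .CLASSES)
  if (anyNA(ci))
    stop("genes without an assigned functional type: ",
         paste(head(info$gene_id[is.na(ci)]), collapse = ", "))
  key <- (gi - 1L) * 22L + ci
  cnt <- array(0, dim = c(4L, C, 22L, G),
               dimnames = list(.BASES, colnames(seqs), .CLASSES, genomes))
  for (b in 1:4) {
    hit <- seqs == .BASES[b]
    storage.mode(hit) <- "double"
    agg <- rowsum(hit, key)
    kk <- as.integer(rownames(agg))
    gg <- (kk - 1L) %/% 22L + 1L
    cc <- (kk - 1L) %% 22L + 1L
    for (r in seq_along(kk)) cnt[b, , cc[r], gg[r]] <- agg[r, ]
  }
  classCnt <- matrix(0, 22L, G, dimnames = list(.CLASSES, genomes))
  tb <- table(factor(ci, levels = seq_len(22L)), factor(gi, levels = seq_len(G)))
  classCnt[] <- as.numeric(tb)
  list(cnt = cnt, classCnt = classCnt, genes = colSums(classCnt),
       genomes = genomes)
}

# Exact expectation of the plug-in KL estimate under multinomial sampling
# of n observations from q, via binomial marginals (separable over
# classes).  Used as the small-sample information correction.
.exactKLBias <- function(n, q) {
  q <- q[q > 0]
  k <- seq_len(n)  # k = 0 contributes 0
  sum(vapply(q, function(qi) {
    sum(dbinom(k, n, qi) * (k / n) * log2((k / n) / qi))
  }, numeric(1)))
}

# Sample-size correction per feature.  The Miller-Madow-style term uses
# the background support (number of classes with q > 0), matching the
# first-order bias (K - 1)/(2 n ln 2) of the plug-in divergence; using the
# observed sample support instead under-corrects at small n and leaks
# training-set-size differences into leave-one-out scores.
.infoCorrection <- function(n, q, correction) {
  s <- sum(q > 0)
  switch(correction,
         none = rep(0, length(n)),
         miller_madow = ifelse(n > 0, (s - 1) / (2 * log(2) * pmax(n, 1)), 0),
         exact_small_n = {
           out <- numeric(length(n))
           small <- which(n > 0 & n <= 8)
           if (length(small)) {
             uniq <- unique(n[small])
             bias <- vapply(uniq, .exactKLBias, numeric(1), q = q)
             out[small] <- bias[match(n[small], uniq)]
           }
           big <- which(n > 8)
           out[big] <- (s - 1) / (2 * log(2) * n[big])
           out
         },
         stop("unknown correction: ", correction))
}

# Heights, information and support from a clade count array.
# cnt: (4 x C x 22) array; q: length-22 background (zeros allowed only for
# classes with zero counts); returns H (feature x class), D, n.
.logoCompute <- function(cnt, q, correction) {
  d <- dim(cnt)
  M <- matrix(cnt, nrow = d[1L] * d[2L], ncol = d[3L])
  n <- rowSums(M)
  p <- M / ifelse(n > 0, n, 1)
  qm <- matrix(q, nrow(M), ncol(M), byrow = TRUE)
  if (any(p > 0 & qm == 0))
    stop("class with nonzero conditional frequency has zero background probability")
  term <- p * (log2(p) - log2(qm))
  term[p == 0] <- 0
  Draw <- rowSums(term)
  corr <- .infoCorrection(n, q, correction)
  D <- pmax(Draw - corr, 0)
  D[n == 0] <- 0
  ratio <- p / qm
  ratio[p == 0] <- 0
  rs <- rowSums(ratio)
  H <- (D / ifelse(rs > 0, rs, 1)) * ratio
  list(H = H, D = D, n = n)
}

# Clade-level background distribution from class counts.
.backgroundFromCounts <- function(classCnt, source, pooledCnt = NULL) {
  switch(source,
         clade_frequencies = classCnt / sum(classCnt),
         uniform = {
           pres <- classCnt > 0
           ifelse(pres, 1 / sum(pres), 0)
         },
         pooled_frequencies = {
           stopifnot(!is.null(pooledCnt))
           pooledCnt / sum(pooledCnt)
         },
         stop("unknown background source: ", source))
}

# Sum per-genome count arrays over a set of genomes.
.sumOver <- function(cnt, members)
  rowSums(cnt[, , , members, drop = FALSE], dims = 3L)
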