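# Function-logo estimation: class-conditional profiles, feature
# information, Gorodkin heights and per-clade logos.

#' Class-conditional profile of a feature
#'
#' For feature `(base, coordinate)`, counts the genes whose aligned base at
#' that coordinate equals the base (gaps never match) and returns the
#' functional-class distribution among them.
#'
#' @param aln a [SprinzlAlignment-class] with functional types assigned.
#' @param base one of `A`, `C`, `G`, `U`.
#' @param coordinate a coordinate label of the alignment.
#' @param genes optional gene subset (indices or `gene_id`s).
#' @return A list with `n` (gene count carrying the feature) and `p`
#'   (named class distribution; empty when `n` is 0).
#' @export
classConditionalProfile <- function(aln, base, coordinate, genes = NULL) {
  stopifnot(is(aln, "SprinzlAlignment"), base %in% .BASES)
  if (!coordinate %in% colnames(aln@seqs))
    stop("coordinate '", coordinate, "' is not in the alignment")
  if (is.null(genes)) genes <- seq_len(nrow(aln@seqs))
  if (is.character(genes)) genes <- match(genes, rownames(aln@seqs))
  hit <- aln@seqs[genes, coordinate] == base
  n <- sum(hit)
  if (n == 0L) return(list(n = 0L, p = setNames(numeric(0), character(0))))
  cls <- aln@geneInfo$functional_type[genes][hit]
  tab <- table(cls)
  list(n = n, p = setNames(as.numeric(tab) / n, names(tab)))
}

#' Feature information in bits
#'
#' The information a feature carries about functional class: the
#' Kullback-Leibler divergence `sum_i p(i) log2(p(i)/q(i))` of the
#' class-conditional distribution `p` from the background `q` (with
#' `0 log 0 := 0`), minus a sample-size correction, clamped at zero.
#'
#' @param p named class-conditional distribution (classes with zero
#'   probability may be omitted).
#' @param n gene count the profile was estimated from (`n >= 1`).
#' @param q named background class distribution; every class with
#'   `p(i) > 0` must have `q(i) > 0`.
#' @param correction `"none"`, `"miller_madow"` (subtract
#'   `(|support(q)| - 1) / (2 ln 2 n)`, the first-order bias of the
#'   plug-in divergence) or `"exact_small_n"` (subtract the exact expected
#'   plug-in divergence under sampling from `q` for `n <= 8`, Miller-Madow
#'   above).
#' @return Corrected information in bits (non-negative scalar).
#' @examples
#' q <- setNames(rep(1/22, 22), functionalClasses())
#' featureInformation(c(L = 1), n = 10, q = q)  # log2(22) minus correction
#' @export
featureInformation <- function(p, n, q,
                               correction = c("none", "miller_madow",
                                              "exact_small_n")) {
  correction <- match.arg(correction)
  if (n < 1) stop("n must be >= 1")
  if (abs(sum(p) - 1) > 1e-9 && length(p) > 0)
    stop("p must sum to 1")
  if (abs(sum(q) - 1) > 1e-9) stop("q must sum to 1")
  sup <- names(p)[p > 0]
  if (!all(sup %in% names(q)[q > 0]))
    stop("class with nonzero conditional frequency has zero background probability")
  pp <- p[p > 0]
  raw <- sum(pp * log2(pp / q[names(pp)]))
  corr <- .infoCorrection(n, q, correction)
  max(raw - corr, 0)
}

#' Gorodkin heights
#'
#' Apportions a feature's information `D` over the functional classes by
#' background-normalized odds:
#' `h_i = D * (p(i)/q(i)) / sum_j (p(j)/q(j))`.  Heights are non-negative,
#' sum to `D`, and classes with `p(i) = 0` get height zero.
#'
#' @param p named class-conditional distribution.
#' @param q named background distribution.
#' @param D feature information in bits (`D >= 0`).
#' @return Named numeric vector of heights over `names(q)`.
#' @examples
#' q <- setNames(rep(0.25, 4), c("L", "F", "X", "J"))
#' gorodkinHeights(c(L = 0.5, F = 0.5), q, D = 1)  # 0.5 and 0.5
#' @export
gorodkinHeights <- function(p, q, D) {
  if (D < 0) stop("D must be non-negative")
  h <- setNames(numeric(length(q)), names(q))
  if (D == 0 || length(p) == 0) return(h)
  pp <- setNames(numeric(length(q)), names(q))
  pp[names(p)] <- p
  if (any(pp > 0 & q == 0))
    stop("class with nonzero conditional frequency has zero background probability")
  ratio <- ifelse(q > 0, pp / q, 0)
  s <- sum(ratio)
  if (s == 0) return(h)
  D * ratio / s
}

#' Estimate per-clade function logos
#'
#' For each retained clade, estimates Gorodkin heights for every feature
#' (base x Sprinzl coordinate) observed in the clade's pooled gene set,
#' apportioned over the 22 functional classes against a class background.
#' Deterministic given its inputs.
#'
#' @param partition a [CladePartition-class] with functional types
#'   assigned.
#' @param background class background source: `"clade_frequencies"` (the
#'   fraction of genes of each class in the clade's gene set, default),
#'   `"uniform"` (uniform over the classes present in the clade) or
#'   `"pooled_frequencies"` (class frequencies pooled over all retained
#'   clades).
#' @param correction sample-size correction, see [featureInformation()]
#'   (default `"miller_madow"`).
#' @return Named list of [FunctionLogo-class], one per retained clade.
#' @export
estimateCladeLogos <- function(partition,
                               background = c("clade_frequencies", "uniform",
                                              "pooled_frequencies"),
                               correction = c("miller_madow", "exact_small_n",
                                              "none")) {
  background <- match.arg(background)
  correction <- match.arg(correction)
  stopifnot(is(partition, "CladePartition"))
  aln <- partition@alignment
  fn <- .featureNames(colnames(aln@seqs))
  trainIdx <- sort(unlist(partition@sets, use.names = FALSE))
  ca <- .countArrays(aln@seqs[trainIdx, , drop = FALSE],
                     aln@geneInfo[trainIdx, , drop = FALSE])
  memberOf <- lapply(partition@sets, function(idx)
    unique(aln@geneInfo$genome_id[idx]))
  pooledCnt <- rowSums(ca$classCnt)
  logos <- lapply(names(partition@sets), function(cl) {
    members <- match(memberOf[[cl]], ca$genomes)
    cnt <- .sumOver(ca$cnt, members)
    classCnt <- rowSums(ca$classCnt[, members, drop = FALSE])
    q <- .backgroundFromCounts(classCnt, background, pooledCnt)
    res <- .logoCompute(cnt, q, correction)
    .makeLogo(cl, res, fn, q, colnames(aln@seqs))
  })
  names(logos) <- names(partition@sets)
  logos
}

.makeLogo <- function(clade, res, featureNames, q, coords) {
  keep <- which(res$n > 0)
  H <- res$H[keep, , drop = FALSE]
  rownames(H) <- featureNames[keep]
  colnames(H) <- .CLASSES
  new("FunctionLogo", clade = clade, heights = H,
      info = setNames(res$D[keep], featureNames[keep]),
      support = setNames(as.integer(res$n[keep]), featureNames[keep]),
      background = q, coordinates = coords)
}

#' Export / import a function logo table
#'
#' `exportLogoTable()` writes a logo as a TSV of
#' `(coordinate, base, class, height, info, support)` with full numeric
#' precision plus header comments carrying the clade label, coordinate
#' universe and background; `readLogoTable()` reproduces the logo exactly.
#' Only classes with positive height are written per feature; a feature
#' whose information is zero is kept via a single placeholder row with an
#' empty class.
#'
#' @param logo a [FunctionLogo-class].
#' @param path file path.
#' @return `exportLogoTable()` returns `path` invisibly; `readLogoTable()`
#'   returns a [FunctionLogo-class].
#' @export
exportLogoTable <- function(logo, path) {
  stopifnot(is(logo, "FunctionLogo"))
  num <- function(x) sprintf("%.17g", x)
  hdr <- c(paste("# clade:", logo@clade),
           paste("# coordinates:", paste(logo@coordinates, collapse = " ")),
           paste("# background:",
                 paste(sprintf("%s=%s", names(logo@background),
                               num(logo@background)), collapse = ",")))
  rows <- character(0)
  feats <- rownames(logo@heights)
  for (f in feats) {
    parts <- strsplit(f, "@", fixed = TRUE)[[1L]]
    h <- logo@heights[f, ]
    pos <- which(h > 0)
    if (length(pos)) {
      rows <- c(rows, sprintf("%s\t%s\t%s\t%s\t%s\t%d", parts[2L], parts[1L],
                              names(h)[pos], num(h[pos]), num(logo@info[[f]]),
                              logo@support[[f]]))
    } else {
      rows <- c(rows, sprintf("%s\t%s\t\t%s\t%s\t%d", parts[2L], parts[1L],
                              num(0), num(logo@info[[f]]), logo@support[[f]]))
    }
  }
  writeLines(c(hdr, "coordinate\tbase\tclass\theight\tinfo\tsupport", rows),
             path)
  invisible(path)
}

#' @rdname exportLogoTable
#' @export
readLogoTable <- function(path) {
  ln <- readLines(path)
  grab <- function(key) {
    x <- grep(paste0("^# ", key, ":"), ln, value = TRUE)
    if (!length(x)) stop("logo table is missing the '# ", key, ":' header")
    trimws(sub(paste0("^# ", key, ":"), "", x[1L]))
  }
  clade <- grab("clade")
  coords <- strsplit(grab("coordinates"), "\\s+")[[1L]]
  bg <- strsplit(strsplit(grab("background"), ",", fixed = TRUE)[[1L]], "=",
                 fixed = TRUE)
  q <- setNames(vapply(bg, function(x) as.numeric(x[2L]), numeric(1)),
                vapply(bg, `[`, "", 1L))
  q <- q[match(.CLASSES, names(q))]
  names(q) <- .CLASSES
  q[is.na(q)] <- 0
  body <- ln[!startsWith(ln, "#")]
  df <- read.delim(text = body, colClasses = c("character", "character",
                                               "character", "numeric",
                                               "numeric", "integer"),
                   na.strings = NULL)
  feats <- unique(paste0(df$base, "@", df$coordinate))
  H <- matrix(0, length(feats), length(.CLASSES),
              dimnames = list(feats, .CLASSES))
  info <- setNames(numeric(length(feats)), feats)
  supp <- setNames(integer(length(feats)), feats)
  fkey <- paste0(df$base, "@", df$coordinate)
  for (i in seq_len(nrow(df))) {
    f <- fkey[i]
    if (nzchar(df$class[i])) H[f, df$class[i]] <- df$height[i]
    info[[f]] <- df$info[i]
    supp[[f]] <- df$support[i]
  }
  new("FunctionLogo", clade = clade, heights = H, info = info,
      support = supp, background = q, coordinates = coords)
}
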