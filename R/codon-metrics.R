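## Codon-usage statistics: GC content, the effective number of codons (ENC)
## and its background-composition-corrected variant (ENC'), the organism-level
## translational-selection proxy ENC'_diff, and descriptive repertoire
## statistics (usage shift, variability, Hamming clustering).

#' GC content of a nucleotide sequence
#'
#' (#G + #C) / (#A + #C + #G + #T/U); ambiguity codes are ignored in both
#' numerator and denominator.
#'
#' @param sequence character string (DNA or RNA, any case) or anything
#'   coercible with \code{as.character}.
#' @return fraction in [0, 1].
#' @export
gcContent <- function(sequence) {
  s <- toupper(as.character(sequence))
  if (length(s) != 1L || !nzchar(s)) stop("empty sequence")
  b <- strsplit(chartr("U", "T", s), "")[[1]]
  n <- sum(b %in% c("A", "C", "G", "T"))
  if (n == 0) stop("sequence contains no unambiguous nucleotides")
  sum(b %in% c("G", "C")) / n
}

#' Codon counts and background composition of one gene
#'
#' Splits a coding sequence into codons, counts sense codons (stop codons
#' and codons with ambiguity codes are discarded) and records the background
#' nucleotide frequencies of the same gene (over all positions).
#'
#' @param sequence in-frame coding sequence.
#' @return list with \code{counts} (named integer over the 61 sense codons),
#'   \code{background} (named frequencies of A, C, G, U summing to 1) and
#'   \code{nCodons}.
#' @export
codonCounts <- function(sequence) {
  s <- rnaNormalize(as.character(sequence))
  if (!nzchar(s)) stop("empty sequence")
  n3 <- floor(nchar(s) / 3)
  if (n3 < 1) stop("sequence shorter than one codon")
  codons <- substring(s, 3 * seq_len(n3) - 2, 3 * seq_len(n3))
  sense <- senseCodons()$codon
  counts <- stats::setNames(integer(length(sense)), sense)
  tab <- table(codons[codons %in% sense])
  counts[names(tab)] <- as.integer(tab)
  bases <- strsplit(s, "")[[1]]
  bases <- bases[bases %in% .RNA_BASES]
  bg <- table(factor(bases, levels = .RNA_BASES))
  background <- stats::setNames(as.numeric(bg) / sum(bg), .RNA_BASES)
  list(counts = counts, background = background, nCodons = sum(counts))
}

## Wright's family layout: amino acids grouped by synonymous-codon count,
## 6-fold families intact. Built lazily (the code table lives in another
## source file).
.enc_families_wright <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- split(.sense_codon_table$codon,
                                        .sense_codon_table$aminoAcid)
    cache
  }
})

## Split layout for the background-corrected variant: the 6-fold families
## (Leu, Ser, Arg) are split into their 2-fold and 4-fold subfamilies so that
## codons within each family differ only at the third position, which is
## where the background expectation is defined. This gives 12 two-fold, one
## three-fold and 8 four-fold families, and preserves the maximum of 61.
.enc_families_split <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- .sense_codon_table
      fams <- split(sc$codon, paste(sc$aminoAcid, sc$quartet))
      cache <<- fams[vapply(fams, length, integer(1)) >= 2]
    }
    cache
  }
})

.family_sizes <- function(fams) vapply(fams, length, integer(1))

## mean of per-family homozygosities within each degeneracy class, with the
## fallback for classes left empty by low counts: a missing class mean is
## estimated as the average of the observed class means.
.class_means <- function(F, m, classes) {
  fbar <- vapply(classes, function(k) {
    v <- F[m == k & is.finite(F) & F > 0]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  names(fbar) <- as.character(classes)
  if (all(is.na(fbar))) stop("no usable codon family in gene")
  fbar[is.na(fbar)] <- mean(fbar, na.rm = TRUE)
  fbar
}

#' Effective number of codons (ENC)
#'
#' Wright's index: ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6 with per-family
#' homozygosity F = (n * sum(p^2) - 1) / (n - 1). Families with fewer than
#' two codon observations are excluded from their class mean; an empty class
#' mean is estimated as the average of the observed class means. The result
#' is clamped at 61. Genes with fewer than 100 usable codons trigger a
#' warning.
#'
#' @param counts output of [codonCounts()].
#' @return ENC value in [20, 61].
#' @export
enc <- function(counts) {
  cc <- counts$counts
  if (sum(cc) < 100)
    warning("fewer than 100 usable codons; ENC estimate is unstable")
  fams <- .enc_families_wright()
  m <- .family_sizes(fams)
  F <- vapply(fams, function(cod) {
    x <- cc[cod]
    n <- sum(x)
    if (n < 2) return(NA_real_)
    p <- x / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1))
  fbar <- .class_means(F, m, c(2L, 3L, 4L, 6L))
  val <- 2 + 9 / fbar[["2"]] + 1 / fbar[["3"]] + 5 / fbar[["4"]] +
    3 / fbar[["6"]]
  min(val, 61)
}

#' Background-corrected effective number of codons (ENC')
#'
#' Replaces Wright's homozygosity with a chi-square based homozygosity
#' F = (X2 + n - m) / (m * (n - 1)), where X2 = n * sum((p - e)^2 / e) and
#' the expected within-family frequencies e are derived from the gene's own
#' background nucleotide composition at the codon third position. The
#' 6-fold families are split into their 2-fold + 4-fold subfamilies, so
#' ENC' = 2 + 12/F2 + 1/F3 + 8/F4. When codon usage matches the background
#' expectation ENC' equals 61 (up to sampling noise; the value is not
#' clamped).
#'
#' @param counts output of [codonCounts()].
#' @param background optional override of the background nucleotide
#'   frequencies (named A/C/G/U, summing to 1); defaults to the gene's own.
#' @return ENC' value.
#' @export
encPrime <- function(counts, background = NULL) {
  cc <- counts$counts
  bg <- if (is.null(background)) counts$background else background
  stopifnot(all(.RNA_BASES %in% names(bg)))
  if (sum(cc) < 100)
    warning("fewer than 100 usable codons; ENC' estimate is unstable")
  fams <- .enc_families_split()
  m <- .family_sizes(fams)
  F <- vapply(fams, function(cod) {
    x <- cc[cod]
    n <- sum(x)
    if (n < 2) return(NA_real_)
    p <- x / n
    e <- bg[substr(cod, 3, 3)]
    if (any(e == 0 & p > 0))
      stop("degenerate background: zero expected frequency for used codon")
    e <- e / sum(e)
    X2 <- n * sum((p - e)^2 / e)
    mf <- length(cod)
    (X2 + n - mf) / (mf * (n - 1))
  }, numeric(1))
  fbar <- .class_means(F, m, c(2L, 3L, 4L))
  val <- 2 + 12 / fbar[["2"]] + 1 / fbar[["3"]] + 8 / fbar[["4"]]
  unname(val)
}

#' Organism-level translational-selection proxy ENC'_diff
#'
#' (mean ENC' of all genes - mean ENC' of ribosomal-protein genes) / mean
#' ENC' of all genes. Stronger codon bias in the highly expressed ribosomal
#' genes relative to the genomic average yields larger positive values.
#'
#' @param encValues numeric vector of per-gene ENC' values (all genes,
#'   ribosomal included).
#' @param isRibosomal logical vector marking the ribosomal-protein genes.
#' @return dimensionless value.
#' @export
encDiff <- function(encValues, isRibosomal) {
  stopifnot(length(encValues) == length(isRibosomal))
  if (!any(isRibosomal)) stop("no ribosomal genes")
  if (!length(encValues)) stop("no genes")
  meanAll <- mean(encValues)
  meanRibo <- mean(encValues[isRibosomal])
  (meanAll - meanRibo) / meanAll
}

#' Nearest-rank percentile
#'
#' The ceiling(p * n)-th order statistic.
#' @param x numeric vector.
#' @param p probability in (0, 1].
#' @return the percentile value.
#' @export
nearestRankPercentile <- function(x, p) {
  stopifnot(length(x) > 0, p > 0, p <= 1)
  sort(x)[max(1L, ceiling(p * length(x)))]
}

#' GC usage shift of a tRNA species
#'
#' Splits organisms into 'absent' and 'present' groups by the species'
#' presence column, tests for a GC-content difference between the groups
#' (two-sided Mann-Whitney; exact when the smaller group has <= 8
#' organisms), and if significant at \code{alpha} returns the usage shift:
#' the mean of the 75th nearest-rank percentile of GC in the absent group
#' and the 25th percentile in the present group.
#'
#' @param presence binary vector (1 = species present).
#' @param gc numeric GC contents, same order as \code{presence}.
#' @param alpha significance level for reporting a shift.
#' @return list with \code{shift} (NA when not significant or a group is
#'   empty) and \code{p} (NA when untestable).
#' @export
usageShift <- function(presence, gc, alpha = 0.05) {
  stopifnot(length(presence) == length(gc))
  absent <- gc[presence == 0]
  present <- gc[presence == 1]
  if (!length(absent) || !length(present))
    return(list(shift = NA_real_, p = NA_real_))
  exact <- min(length(absent), length(present)) <= 8
  p <- suppressWarnings(
    stats::wilcox.test(absent, present, exact = exact)$p.value)
  if (is.na(p) || p >= alpha) return(list(shift = NA_real_, p = p))
  list(shift = mean(c(nearestRankPercentile(absent, 0.75),
                      nearestRankPercentile(present, 0.25))),
       p = p)
}

#' Variability measure of a presence column
#'
#' The larger of the percentage of organisms possessing and lacking the
#' species; 100 for a constant column.
#'
#' @param presence binary vector.
#' @return percentage in [50, 100].
#' @export
variabilityMeasure <- function(presence) {
  if (!length(presence)) stop("empty presence column")
  f <- mean(presence == 1)
  100 * max(f, 1 - f)
}

#' Cluster tRNA species by Hamming distance between presence profiles
#'
#' Pairwise Hamming distances between species columns, agglomerative
#' clustering (average linkage), leaf order for plotting; organisms are
#' ordered separately by GC content when provided.
#'
#' @param x a [PresenceMatrix-class].
#' @param gc optional named numeric GC content per organism.
#' @param method linkage method passed to [stats::hclust()].
#' @return list with \code{speciesOrder}, \code{hclust}, \code{distances}
#'   (a \code{dist}), and \code{organismOrder}.
#' @export
hammingCluster <- function(x, gc = NULL, method = "average") {
  m <- as.matrix(x)
  if (ncol(m) < 2) stop("need at least 2 species")
  d <- stats::dist(t(m), method = "manhattan")  # Hamming for binary data
  hc <- stats::hclust(d, method = method)
  orgOrder <- rownames(m)
  if (!is.null(gc)) orgOrder <- rownames(m)[order(gc[rownames(m)])]
  list(speciesOrder = hc$labels[hc$order], hclust = hc, distances = d,
       organismOrder = orgOrder)
}

#' Z-normalize trait columns
#'
#' Centres to mean 0 and scales to sample (n-1) standard deviation 1.
#' @param x numeric vector.
#' @return normalized vector.
#' @export
zNormalize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("trait has zero variance")
  (x - mean(x)) / s
}

#' Assemble a per-organism trait table
#'
#' @param genomeSize,gc,encDiff named numeric vectors over the same
#'   organisms (bp, fraction, dimensionless).
#' @return data.frame with raw columns and z-normalized columns
#'   \code{genomeSize.z}, \code{gc.z}, \code{encDiff.z}.
#' @export
traitTable <- function(genomeSize, gc, encDiff) {
  orgs <- names(genomeSize)
  stopifnot(!is.null(orgs), setequal(orgs, names(gc)),
            setequal(orgs, names(encDiff)))
  data.frame(
    organism = orgs,
    genomeSize = unname(genomeSize[orgs]),
    gc = unname(gc[orgs]),
    encDiff = unname(encDiff[orgs]),
    genomeSize.z = zNormalize(unname(genomeSize[orgs])),
    gc.z = zNormalize(unname(gc[orgs])),
    encDiff.z = zNormalize(unname(encDiff[orgs])),
    stringsAsFactors = FALSE
  )
}
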