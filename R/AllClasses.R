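#' @import methods
#' @importFrom stats anova aov as.formula coef complete.cases cor lm lm.fit
#'   median model.matrix na.omit optimize p.adjust pchisq pf prcomp pt qnorm
#'   qt quantile rbinom rchisq rgamma rnorm runif sd setNames var
#' @importFrom utils head read.table write.table
NULL

#' SNP genotype matrix for inbred lines
#'
#' Lines-by-SNP genotype codes with a genomic map. Codes follow the marker
#' scoring convention for inbreds: \code{1} homozygous reference, \code{0}
#' heterozygous, \code{-1} homozygous alternate, \code{NA} missing. Positions
#' are 1-based and non-decreasing within each chromosome.
#'
#' @slot geno numeric matrix, lines x SNPs, entries in \{1, 0, -1, NA\}.
#' @slot chrom character vector of chromosome labels, one per SNP.
#' @slot pos integer vector of base-pair positions, one per SNP.
#' @slot ref,alt character vectors of reference / alternate alleles per SNP.
#'
#' @export
setClass("SnpMatrix",
  representation(geno = "matrix", chrom = "character", pos = "integer",
                 ref = "character", alt = "character"),
  validity = function(object) {
    g <- object@geno
    p <- ncol(g)
    if (length(object@chrom) != p) return("chrom length != number of SNPs")
    if (length(object@pos) != p)   return("pos length != number of SNPs")
    if (length(object@ref) != p)   return("ref length != number of SNPs")
    if (length(object@alt) != p)   return("alt length != number of SNPs")
    bad <- !(g %in% c(1, 0, -1)) & !is.na(g)
    if (any(bad)) return("genotype codes must be 1, 0, -1 or NA")
    for (ch in unique(object@chrom)) {
      if (is.unsorted(object@pos[object@chrom == ch]))
        return(sprintf("positions not non-decreasing on chromosome %s", ch))
    }
    TRUE
  })

#' Construct a SnpMatrix
#'
#' @param geno lines x SNPs matrix with codes in \{1, 0, -1, NA\};
#'   rownames are line ids, colnames SNP ids.
#' @param chrom chromosome label per SNP.
#' @param pos base-pair position per SNP (1-based).
#' @param ref,alt alleles per SNP; defaults "A"/"B" placeholders.
#' @return A \linkS4class{SnpMatrix}.
#' @export
SnpMatrix <- function(geno, chrom, pos, ref = NULL, alt = NULL) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("L%04d", seq_len(nrow(geno)))
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("S%s_%d", chrom, pos)
  if (is.null(ref)) ref <- rep("A", ncol(geno))
  if (is.null(alt)) alt <- rep("B", ncol(geno))
  new("SnpMatrix", geno = geno, chrom = as.character(chrom),
      pos = as.integer(pos), ref = as.character(ref), alt = as.character(alt))
}

#' @describeIn SnpMatrix-class genotype code matrix
#' @param x a SnpMatrix
#' @export
genoCodes <- function(x) x@geno

#' @describeIn SnpMatrix-class chromosome labels per SNP
#' @export
snpChrom <- function(x) x@chrom

#' @describeIn SnpMatrix-class base-pair positions per SNP
#' @export
snpPos <- function(x) x@pos

#' @describeIn SnpMatrix-class line identifiers
#' @export
lineIds <- function(x) rownames(x@geno)

#' @describeIn SnpMatrix-class SNP identifiers
#' @export
snpIds <- function(x) colnames(x@geno)

#' @describeIn SnpMatrix-class number of lines
#' @export
nLines <- function(x) nrow(x@geno)

#' @describeIn SnpMatrix-class number of SNPs
#' @export
nSnps <- function(x) ncol(x@geno)

#' Subset a SnpMatrix by lines and/or SNPs
#' @param x a SnpMatrix
#' @param i line index, j SNP index (as for matrices)
#' @param j see \code{i}
#' @param ... ignored
#' @param drop ignored; subsetting never drops to vector
#' @export
setMethod("[", "SnpMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@geno))
  if (missing(j)) j <- seq_len(ncol(x@geno))
  jj <- seq_len(ncol(x@geno))[j]   # normalise logical/negative indexing
  new("SnpMatrix", geno = x@geno[i, j, drop = FALSE],
      chrom = x@chrom[jj], pos = x@pos[jj],
      ref = x@ref[jj], alt = x@alt[jj])
})

setMethod("show", "SnpMatrix", function(object) {
  cat(sprintf("SnpMatrix: %d lines x %d SNPs on %d chromosome(s); %.1f%% missing\n",
              nrow(object@geno), ncol(object@geno),
              length(unique(object@chrom)),
              100 * mean(is.na(object@geno))))
})

#' Minor allele frequency per SNP
#'
#' Frequency of the rarer allele from the \{1, 0, -1\} codes
#' (heterozygotes contribute half a copy of each allele).
#' @param x a \linkS4class{SnpMatrix}
#' @return numeric vector, one MAF per SNP (NaN if fully missing).
#' @export
snpMaf <- function(x) {
  g <- x@geno
  p <- colMeans((g + 1) / 2, na.rm = TRUE)  # reference-allele frequency
  pmin(p, 1 - p)
}

#' Missing-data fraction per SNP
#' @param x a \linkS4class{SnpMatrix}
#' @export
snpMissingness <- function(x) colMeans(is.na(x@geno))

#' Haplotype-allele incidence matrix
#'
#' Binary lines x haplotype-allele matrix: entry 1 when a line carries the
#' column's haplotype allele of its block. Within a block every line has at
#' most one 1; lines with any missing member SNP have all zeros for that
#' block and are flagged in \code{missing}.
#'
#' @slot incidence numeric matrix, lines x haplotype alleles, entries \{0, 1\}.
#' @slot blockId character, block name per column.
#' @slot allele character, concatenated SNP allele string per column.
#' @slot missing logical matrix, lines x blocks: TRUE where the line's block
#'   genotype could not be called.
#' @export
setClass("HapMatrix",
  representation(incidence = "matrix", blockId = "character",
                 allele = "character", missing = "matrix"),
  validity = function(object) {
    if (length(object@blockId) != ncol(object@incidence))
      return("blockId length != number of columns")
    if (length(object@allele) != ncol(object@incidence))
      return("allele length != number of columns")
    if (!all(object@incidence %in% c(0, 1)))
      return("incidence entries must be 0/1")
    for (b in unique(object@blockId)) {
      sub <- object@incidence[, object@blockId == b, drop = FALSE]
      if (any(rowSums(sub) > 1))
        return(sprintf("line with >1 haplotype allele in block %s", b))
    }
    TRUE
  })

#' @describeIn HapMatrix-class the 0/1 incidence matrix
#' @param x a HapMatrix
#' @export
hapIncidence <- function(x) x@incidence

#' @describeIn HapMatrix-class block name per column
#' @export
hapBlockId <- function(x) x@blockId

#' @describeIn HapMatrix-class allele string per column
#' @export
hapAllele <- function(x) x@allele

setMethod("show", "HapMatrix", function(object) {
  cat(sprintf("HapMatrix: %d lines x %d haplotype alleles in %d blocks\n",
              nrow(object@incidence), ncol(object@incidence),
              length(unique(object@blockId))))
})
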