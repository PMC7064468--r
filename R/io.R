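#' Write genotypes as a biallelic VCF
#'
#' Inbred homozygous calls map to 0/0 (reference code 1) or 1/1
#' (alternate code -1); heterozygous codes to 0/1 and missing to ./.
#'
#' @param geno a \linkS4class{SnpMatrix}.
#' @param path output file (plain text .vcf).
#' @export
writeVcf <- function(geno, path) {
  g <- genoCodes(geno)
  gt <- matrix("./.", nrow(g), ncol(g))
  gt[!is.na(g) & g == 1] <- "0/0"
  gt[!is.na(g) & g == 0] <- "0/1"
  gt[!is.na(g) & g == -1] <- "1/1"
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(g)), collapse = "\t"))
  body <- vapply(seq_len(ncol(g)), function(j)
    paste(c(snpChrom(geno)[j], snpPos(geno)[j], snpIds(geno)[j],
            geno@ref[j], geno@alt[j], ".", "PASS", ".", "GT", gt[, j]),
          collapse = "\t"), character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genotypes from a biallelic VCF into a SnpMatrix
#'
#' Parses GT fields with vcfR; 0/0 -> 1, heterozygous -> 0, 1/1 -> -1,
#' missing -> NA. Multi-allelic records are rejected.
#'
#' @param path VCF file.
#' @return a \linkS4class{SnpMatrix}.
#' @export
readVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (any(grepl(",", fix[, "ALT"]))) stop("multi-allelic records not supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt %in% c("0/0", "0|0")] <- 1
  code[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 0
  code[gt %in% c("1/1", "1|1")] <- -1
  SnpMatrix(t(code), chrom = fix[, "CHROM"],
            pos = as.integer(fix[, "POS"]),
            ref = fix[, "REF"], alt = fix[, "ALT"])
}

#' Write genotypes as a HapMap-style tab-delimited matrix
#'
#' Columns: rs, alleles, chrom, pos, then one column per line with base
#' calls (reference or alternate base; "N" for missing/heterozygous).
#' @param geno a \linkS4class{SnpMatrix}.
#' @param path output TSV.
#' @export
writeHapMap <- function(geno, path) {
  g <- genoCodes(geno)
  calls <- sapply(seq_len(ncol(g)), function(j)
    ifelse(is.na(g[, j]) | g[, j] == 0, "N",
           ifelse(g[, j] == 1, geno@ref[j], geno@alt[j])))
  df <- data.frame(rs = snpIds(geno),
                   alleles = paste(geno@ref, geno@alt, sep = "/"),
                   chrom = snpChrom(geno), pos = snpPos(geno),
                   t(calls), check.names = FALSE)
  colnames(df)[-(1:4)] <- rownames(g)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a HapMap-style tab-delimited genotype matrix
#' @param path TSV written by \code{\link{writeHapMap}} (or equivalent
#'   rs/alleles/chrom/pos + one base-call column per line).
#' @return a \linkS4class{SnpMatrix}.
#' @export
readHapMap <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  al <- strsplit(df$alleles, "/")
  ref <- vapply(al, `[`, character(1), 1)
  alt <- vapply(al, `[`, character(1), 2)
  calls <- as.matrix(df[, -(1:4), drop = FALSE])
  code <- matrix(NA_real_, ncol(calls), nrow(calls),
                 dimnames = list(colnames(calls), df$rs))
  for (j in seq_len(nrow(calls))) {
    code[, j] <- ifelse(calls[j, ] == ref[j], 1,
                 ifelse(calls[j, ] == alt[j], -1, NA))
  }
  SnpMatrix(code, chrom = df$chrom, pos = as.integer(df$pos),
            ref = ref, alt = alt)
}

#' Write haplotype blocks as TSV
#' @param blocks from \code{\link{buildBlocks}}.
#' @param path output file.
#' @export
writeBlocks <- function(blocks, path) {
  df <- blocks
  df$snps <- vapply(blocks$snps, paste, character(1), collapse = ",")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulation truth as JSON
#' @param truth the truth list from \code{\link{simulateTrials}}.
#' @param path output .json.
#' @export
writeTruth <- function(truth, path) {
  truth$genetic_values <- NULL   # bulky; retained in memory only
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Write a haplotype incidence matrix as TSV
#'
#' One row per line, one column per haplotype allele (named
#' "<block>_<allele>"); entries 0/1.
#' @param H a \linkS4class{HapMatrix}.
#' @param path output TSV.
#' @export
writeHapMatrix <- function(H, path) {
  inc <- hapIncidence(H)
  df <- data.frame(line = rownames(inc), inc, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an ANOVA table as TSV
#'
#' Mirrors the standard layout: term, Df, Sum Sq, Mean Sq, F value, Pr(>F).
#' @param tab data.frame from \code{\link{anovaFactorial}}.
#' @param path output TSV.
#' @export
writeAnovaTable <- function(tab, path) {
  df <- data.frame(term = rownames(tab), tab, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
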