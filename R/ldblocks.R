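#' Filter SNPs on missingness and minor allele frequency
#'
#' Retains SNPs with a missing-data fraction at most \code{max_missing}
#' (a SNP at exactly the threshold is kept) and a minor allele frequency of
#' at least \code{maf_min}, preserving SNP order. The defaults (40\%
#' missingness, MAF >= 0.15) suit sparse genotyping-by-sequencing panels
#' pooled over several year cohorts, where a high panel-wide MAF floor keeps
#' per-cohort MAF above ~0.05.
#'
#' @param geno a \linkS4class{SnpMatrix}.
#' @param max_missing maximum tolerated missing fraction per SNP.
#' @param maf_min minimum minor allele frequency per SNP.
#' @return the filtered \linkS4class{SnpMatrix}; a warning (not an error) is
#'   emitted when nothing survives.
#' @export
filterSnps <- function(geno, max_missing = 0.40, maf_min = 0.15) {
  keep <- snpMissingness(geno) <= max_missing + 1e-12 &
          !is.na(snpMaf(geno)) & snpMaf(geno) >= maf_min - 1e-12
  if (!any(keep)) warning("no SNPs pass the filters; returning empty matrix")
  geno[, keep]
}

# 2x2 haplotype counts from homozygous calls of two SNPs in inbred lines;
# heterozygous (0) and missing calls are excluded (phase is otherwise known)
hapCounts <- function(gi, gj) {
  ok <- !is.na(gi) & !is.na(gj) & gi != 0 & gj != 0
  gi <- gi[ok]; gj <- gj[ok]
  c(n11 = sum(gi == 1 & gj == 1),  n12 = sum(gi == 1 & gj == -1),
    n21 = sum(gi == -1 & gj == 1), n22 = sum(gi == -1 & gj == -1))
}

#' D' with a likelihood-based 95\% confidence interval
#'
#' Computes the normalised linkage-disequilibrium coefficient
#' \eqn{D' = |D|/D_{max}} from phased haplotype counts (inbred lines:
#' homozygous calls only) and a confidence interval by evaluating the
#' multinomial likelihood of |D'| on a grid of 101 points in [0, 1] with
#' allele frequencies fixed at their sample estimates. The bounds are the
#' 5th and 95th cumulative-likelihood percentiles, the convention used by
#' Haploview/Gabriel-style block finders. The pair is classified via
#' \code{\link{classifyPair}}.
#'
#' @param geno a \linkS4class{SnpMatrix}.
#' @param i,j SNP column indices.
#' @param conf nominal coverage (only 0.95 is used by the block rules).
#' @param grid_n number of grid points on [0, 1] (default 101, i.e. 0.01
#'   resolution).
#' @return list: \code{D_prime}, \code{ci_low}, \code{ci_high},
#'   \code{n_informative}, \code{klass}, \code{flag}.
#' @export
dprimeCI <- function(geno, i, j, conf = 0.95, grid_n = 101L) {
  cnt <- hapCounts(genoCodes(geno)[, i], genoCodes(geno)[, j])
  dprimeCICounts(cnt, conf = conf, grid_n = grid_n)
}

#' @rdname dprimeCI
#' @param counts named or positional vector (n11, n12, n21, n22) of phased
#'   two-SNP haplotype counts (first allele = reference).
#' @export
dprimeCICounts <- function(counts, conf = 0.95, grid_n = 101L) {
  n <- sum(counts)
  out <- list(D_prime = NA_real_, ci_low = 0, ci_high = 1,
              n_informative = n, klass = "inconclusive", flag = "")
  if (n < 2) { out$flag <- "fewer than 2 informative lines"; return(out) }
  n11 <- counts[[1]]; n12 <- counts[[2]]; n21 <- counts[[3]]; n22 <- counts[[4]]
  p <- (n11 + n12) / n          # P(ref at SNP i)
  q <- (n11 + n21) / n          # P(ref at SNP j)
  if (p %in% c(0, 1) || q %in% c(0, 1)) {
    out$flag <- "monomorphic SNP among informative lines"; return(out)
  }
  D <- n11 / n - p * q
  s <- if (D >= 0) 1 else -1
  dmax <- if (D >= 0) min(p * (1 - q), (1 - p) * q)
          else        min(p * q, (1 - p) * (1 - q))
  out$D_prime <- abs(D) / dmax
  grid <- seq(0, 1, length.out = grid_n)
  ll <- vapply(grid, function(dp) {
    Dg <- s * dp * dmax
    pr <- c(p * q + Dg, p * (1 - q) - Dg, (1 - p) * q - Dg,
            (1 - p) * (1 - q) + Dg)
    pr <- pmax(pr, 1e-10)
    sum(c(n11, n12, n21, n22) * log(pr))
  }, numeric(1))
  lik <- exp(ll - max(ll))
  cum <- cumsum(lik) / sum(lik)
  alpha <- (1 - conf) / 2
  out$ci_low <- grid[which(cum >= alpha)[1]]
  out$ci_high <- grid[which(cum >= 1 - alpha)[1]]
  out$klass <- classifyPair(out)
  out
}

#' Classify a SNP pair from its D' confidence interval
#'
#' "Strong LD" requires the CI lower bound >= \code{lower_min} (0.6) and
#' upper bound >= \code{upper_min} (0.95); "strong recombination" is an
#' upper bound below \code{recomb_max} (0.9, the Gabriel convention);
#' everything else is "inconclusive".
#'
#' @param ld list with ci_low/ci_high (from \code{\link{dprimeCI}}) or the
#'   two bounds can be given directly.
#' @param lower_min,upper_min strong-LD thresholds on (ci_low, ci_high).
#' @param recomb_max strong-recombination threshold on ci_high.
#' @return one of \code{"strong LD"}, \code{"inconclusive"},
#'   \code{"strong recombination"}.
#' @export
classifyPair <- function(ld, lower_min = 0.6, upper_min = 0.95,
                         recomb_max = 0.9) {
  lo <- ld$ci_low; hi <- ld$ci_high
  if (isTRUE(nzchar(ld$flag))) return("inconclusive")
  if (lo >= lower_min - 1e-12 && hi >= upper_min - 1e-12) return("strong LD")
  if (hi < recomb_max) return("strong recombination")
  "inconclusive"
}

# pairwise classes within a window; rows indexed by (i, j) with i < j
pairClasses <- function(geno, max_span, lower_min, upper_min, recomb_max) {
  p <- nSnps(geno)
  cls <- vector("list", p)
  for (i in seq_len(p)) cls[[i]] <- character(0)
  for (i in seq_len(max(p - 1, 0))) {
    for (j in seq(i + 1, min(i + max_span - 1, p))) {
      ld <- dprimeCI(geno, i, j)
      cls[[i]][j - i] <- classifyPair(ld, lower_min, upper_min, recomb_max)
    }
  }
  cls
}

#' Build haplotype blocks from D' confidence intervals
#'
#' Scores every contiguous span of >= 2 SNPs (up to \code{max_span} SNPs,
#' within one chromosome): a span qualifies as a haplotype block when at
#' least \code{strong_frac} (95\%) of its informative pairwise comparisons
#' — i.e. excluding "inconclusive" pairs — are in "strong LD", and at least
#' one comparison is informative. Qualifying spans are accepted greedily,
#' longest first and leftmost on ties, without overlap. Accepted blocks are
#' named \code{HB<chrom>.<serial>} with the serial incrementing along the
#' chromosome in positional order.
#'
#' @param geno a filtered \linkS4class{SnpMatrix}, SNPs position-sorted
#'   within chromosome.
#' @param strong_frac minimum fraction of informative comparisons in strong
#'   LD.
#' @param lower_min,upper_min,recomb_max CI thresholds, see
#'   \code{\link{classifyPair}}.
#' @param max_span maximum number of SNPs per candidate span.
#' @return data.frame: name, chrom, first, last (global SNP column indices),
#'   n_snps, start, end (bp), snps (list column of SNP ids). Zero rows when
#'   no span qualifies.
#' @export
buildBlocks <- function(geno, strong_frac = 0.95, lower_min = 0.6,
                        upper_min = 0.95, recomb_max = 0.9, max_span = 50L) {
  res <- list()
  for (ch in unique(snpChrom(geno))) {
    idx <- which(snpChrom(geno) == ch)
    sub <- geno[, idx]
    p <- length(idx)
    if (p < 2) next
    cls <- pairClasses(sub, max_span, lower_min, upper_min, recomb_max)
    cand <- list()
    for (a in seq_len(p - 1)) {
      for (b in seq(a + 1, min(a + max_span - 1, p))) {
        # all pairs (i,j) with a <= i < j <= b
        cc <- unlist(lapply(a:(b - 1), function(i) cls[[i]][seq_len(b - i)]))
        inf <- cc[cc != "inconclusive"]
        if (length(inf) >= 1 && mean(inf == "strong LD") >= strong_frac - 1e-12)
          cand[[length(cand) + 1L]] <- c(a, b)
      }
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    ord <- order(-(cand[, 2] - cand[, 1]), cand[, 1])
    cand <- cand[ord, , drop = FALSE]
    used <- rep(FALSE, p); acc <- list()
    for (k in seq_len(nrow(cand))) {
      a <- cand[k, 1]; b <- cand[k, 2]
      if (!any(used[a:b])) { used[a:b] <- TRUE; acc[[length(acc) + 1]] <- c(a, b) }
    }
    acc <- do.call(rbind, acc)
    acc <- acc[order(acc[, 1]), , drop = FALSE]
    for (k in seq_len(nrow(acc))) {
      a <- acc[k, 1]; b <- acc[k, 2]
      res[[length(res) + 1L]] <- data.frame(
        name = sprintf("HB%s.%d", ch, k), chrom = ch,
        first = idx[a], last = idx[b], n_snps = b - a + 1,
        start = snpPos(geno)[idx[a]], end = snpPos(geno)[idx[b]],
        snps = I(list(snpIds(geno)[idx[a:b]])))
    }
  }
  if (!length(res))
    return(data.frame(name = character(0), chrom = character(0),
                      first = integer(0), last = integer(0),
                      n_snps = integer(0), start = integer(0),
                      end = integer(0), snps = I(list())))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Call per-line haplotype alleles within blocks
#'
#' For each block the member-SNP calls of a line are concatenated into an
#' allele string (reference/alternate base per SNP); heterozygous or
#' missing member calls make the whole block missing for that line (no
#' imputation). Allele strings with frequency below \code{hap_freq_min}
#' among called lines are pooled into a rare class and excluded from the
#' incidence columns. Returns the binary line x haplotype-allele matrix.
#'
#' @param geno the \linkS4class{SnpMatrix} the blocks were built from.
#' @param blocks data.frame from \code{\link{buildBlocks}}.
#' @param hap_freq_min frequency floor below which alleles are pooled.
#' @return a \linkS4class{HapMatrix}.
#' @export
callHaplotypes <- function(geno, blocks, hap_freq_min = 0.05) {
  g <- genoCodes(geno); n <- nrow(g)
  cols <- list(); blockId <- character(0); allele <- character(0)
  missing <- matrix(FALSE, n, nrow(blocks),
                    dimnames = list(rownames(g), blocks$name))
  for (k in seq_len(nrow(blocks))) {
    span <- blocks$first[k]:blocks$last[k]
    sub <- g[, span, drop = FALSE]
    ok <- rowSums(is.na(sub) | sub == 0) == 0
    missing[!ok, k] <- TRUE
    chars <- matrix("", n, length(span))
    for (s in seq_along(span)) {
      chars[, s] <- ifelse(is.na(sub[, s]) | sub[, s] == 0, "?",
                    ifelse(sub[, s] == 1, geno@ref[span[s]],
                           geno@alt[span[s]]))
    }
    str <- apply(chars, 1, paste0, collapse = "")
    str[!ok] <- NA
    tab <- table(str[ok])
    common <- names(tab)[tab / sum(ok) >= hap_freq_min - 1e-12]
    for (al in common) {
      cols[[length(cols) + 1L]] <- as.numeric(!is.na(str) & str == al)
      blockId <- c(blockId, blocks$name[k])
      allele <- c(allele, al)
    }
  }
  inc <- if (length(cols)) do.call(cbind, cols) else matrix(0, n, 0)
  rownames(inc) <- rownames(g)
  if (ncol(inc)) colnames(inc) <- paste(blockId, allele, sep = "_")
  new("HapMatrix", incidence = inc, blockId = blockId, allele = allele,
      missing = missing)
}
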