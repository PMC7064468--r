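#' Principal-component covariates with BIC-selected dimension
#'
#' Principal components of the column-centered genotype matrix (missing
#' calls mean-imputed for the PCA only). The number of components carried
#' into the mixed model is chosen by minimising the BIC of the regression
#' of the phenotype on the first k components, k = 0..max_pcs.
#'
#' @param geno a filtered \linkS4class{SnpMatrix}.
#' @param y phenotype vector aligned to lines (used only for the BIC
#'   choice); when NULL, k defaults to \code{max_pcs}.
#' @param max_pcs largest number of components considered (capped at
#'   n_lines - 2).
#' @return list: \code{scores} (lines x max_pcs matrix), \code{k} (chosen
#'   count), \code{bic} (BIC per k, named "0".."max_pcs").
#' @export
pcaCovariates <- function(geno, y = NULL, max_pcs = 10) {
  M <- genoCodes(geno)
  cm <- colMeans(M, na.rm = TRUE)
  idx <- which(is.na(M))
  if (length(idx)) M[idx] <- cm[(idx - 1) %/% nrow(M) + 1]
  max_pcs <- min(max_pcs, nrow(M) - 2, ncol(M))
  pc <- prcomp(M, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(max_pcs), drop = FALSE]
  if (is.null(y)) return(list(scores = scores, k = max_pcs, bic = NULL))
  stopifnot(length(y) == nrow(M))
  n <- length(y)
  bic <- vapply(0:max_pcs, function(k) {
    X <- cbind(1, scores[, seq_len(k), drop = FALSE])
    rss <- sum(lm.fit(X, y)$residuals^2)
    n * log(rss / n) + (k + 1) * log(n)
  }, numeric(1))
  names(bic) <- 0:max_pcs
  k <- which.min(bic) - 1L
  list(scores = scores, k = k, bic = bic)
}

#' VanRaden genomic relationship matrix
#'
#' \eqn{G = ZZ' / (2 \sum_k p_k (1 - p_k))} where Z is the 0/1/2
#' reference-allele dosage matrix column-centered by \eqn{2 p_k}. Missing
#' calls contribute zero after centering; monomorphic columns are dropped
#' with a warning. For a fully inbred panel the mean diagonal approaches
#' 1 + f = 2 on this (outbred) scale.
#'
#' @param geno a filtered \linkS4class{SnpMatrix}.
#' @return symmetric n x n matrix with line dimnames and attribute
#'   \code{method = "vanraden"}.
#' @export
vanRadenKinship <- function(geno) {
  M <- genoCodes(geno)
  X <- M + 1                      # reference-allele dosage 0/1/2 (het = 1)
  p <- colMeans(X, na.rm = TRUE) / 2
  mono <- p <= 0 | p >= 1 | is.na(p)
  if (any(mono)) {
    warning(sum(mono), " monomorphic column(s) dropped from kinship")
    X <- X[, !mono, drop = FALSE]; p <- p[!mono]
  }
  Z <- sweep(X, 2, 2 * p)
  Z[is.na(Z)] <- 0
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  G <- (G + t(G)) / 2
  attr(G, "method") <- "vanraden"
  G
}

# REML profile likelihood for y = Xb + u + e, u ~ N(0, lambda * sigma_e^2 K),
# via a single eigendecomposition of K (EMMA-style)
remlNull <- function(y, X, K) {
  ok <- complete.cases(y, X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]; K <- K[ok, ok]
  q0 <- qr(X)
  X <- X[, q0$pivot[seq_len(q0$rank)], drop = FALSE]
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 0); U <- eg$vectors
  ys <- crossprod(U, y); Xs <- crossprod(U, X)
  n <- length(ys); q <- ncol(Xs)
  negll <- function(loglam) {
    lam <- exp(loglam)
    w <- lam * d + 1
    yt <- ys / sqrt(w); Xt <- Xs / sqrt(w)
    fit <- lm.fit(Xt, yt)
    rss <- sum(fit$residuals^2)
    XtX <- crossprod(Xt)
    0.5 * ((n - q) * log(rss) + sum(log(w)) +
           determinant(XtX, logarithm = TRUE)$modulus)
  }
  opt <- optimize(negll, c(log(1e-6), log(1e6)))
  lam <- exp(opt$minimum)
  w <- lam * d + 1
  yt <- ys / sqrt(w); Xt <- Xs / sqrt(w)
  fit <- lm.fit(Xt, yt)
  sig_e <- sum(fit$residuals^2) / (n - ncol(Xt))
  list(lambda = lam, sigma2_e = sig_e, sigma2_g = lam * sig_e,
       U = U, d = d, X = X, y = y, ok = ok, reml = -opt$objective,
       beta = fit$coefficients)
}

#' Mixed-linear-model single-SNP association scan
#'
#' Per-trial scan of adjusted entry means with the model
#' y = Xb + m a + u + e, u ~ N(0, K sigma_g^2): fixed covariates (principal
#' components, phenology covariates, gene markers), a random polygenic term
#' with kinship covariance, and one marker at a time. Variance components
#' are estimated once by REML on the null model through a single
#' eigendecomposition of K and the ratio is reused for every marker
#' (the population-parameters-previously-determined approximation); set
#' \code{exact = TRUE} to re-estimate per marker. Marker p-values are
#' F-tests of the marker term; R2 is the marker sum of squares over the
#' total on the whitened scale. Missing marker calls are mean-imputed for
#' the scan; markers with no variation are skipped.
#'
#' @param y named numeric vector of adjusted means (one trial).
#' @param geno a \linkS4class{SnpMatrix} aligned to (a superset of) y.
#' @param K kinship from \code{\link{vanRadenKinship}} (identity allowed).
#' @param covars optional matrix/data.frame of fixed covariates aligned to
#'   lines (collinear columns are dropped with a warning).
#' @param exact re-estimate variance components for every marker.
#' @return data.frame: snp, chrom, pos, beta (per-code slope), effect
#'   (homozygote contrast, 2 beta), effect_pct (of the trial mean), p, R2,
#'   lambda.
#' @export
mlmScanSnp <- function(y, geno, K, covars = NULL, exact = FALSE) {
  ids <- intersect(names(y), lineIds(geno))
  y0 <- y[ids]
  M <- genoCodes(geno)[ids, , drop = FALSE]
  K <- K[ids, ids]
  X <- buildFixed(length(y0), covars, ids)
  nul <- remlNull(y0, X, K)
  U <- nul$U; w <- nul$lambda * nul$d + 1
  yt <- as.numeric(crossprod(U, nul$y)) / sqrt(w)
  Xt <- crossprod(U, nul$X) / sqrt(w)
  cm <- colMeans(M, na.rm = TRUE)
  idx <- which(is.na(M))
  if (length(idx)) M[idx] <- cm[(idx - 1) %/% nrow(M) + 1]
  keep <- apply(M, 2, var) > 1e-12
  Mt <- crossprod(U, M[, keep, drop = FALSE]) / sqrt(w)
  qrX <- qr(Xt)
  ry <- qr.resid(qrX, yt)
  rM <- qr.resid(qrX, Mt)
  smm <- colSums(rM^2); smy <- colSums(rM * ry)
  beta <- smy / smm
  ssm <- beta * smy
  n <- length(yt); q <- ncol(Xt)
  rss <- sum(ry^2) - ssm
  Fst <- ssm / (rss / (n - q - 1))
  p <- pf(Fst, 1, n - q - 1, lower.tail = FALSE)
  if (exact) {
    for (k in seq_along(beta)) {
      nk <- remlNull(y0, cbind(nul$X, M[, which(keep)[k]]), K)
      wk <- nk$lambda * nk$d + 1
      ytk <- crossprod(nk$U, nk$y) / sqrt(wk)
      Xtk <- crossprod(nk$U, nk$X) / sqrt(wk)
      fit <- lm.fit(Xtk, ytk)
      se2 <- sum(fit$residuals^2) / (length(ytk) - ncol(Xtk))
      XtXi <- chol2inv(chol(crossprod(Xtk)))
      tstat <- fit$coefficients[ncol(Xtk)] /
               sqrt(se2 * XtXi[ncol(Xtk), ncol(Xtk)])
      p[k] <- 2 * pt(abs(tstat), length(ytk) - ncol(Xtk), lower.tail = FALSE)
      beta[k] <- fit$coefficients[ncol(Xtk)]
    }
  }
  sstot <- sum((yt - mean(yt))^2)
  out <- data.frame(snp = snpIds(geno)[keep], chrom = snpChrom(geno)[keep],
                    pos = snpPos(geno)[keep], beta = beta,
                    effect = 2 * beta,
                    effect_pct = 100 * 2 * beta / mean(y0),
                    p = pmin(pmax(p, .Machine$double.xmin), 1),
                    R2 = pmin(ssm / sstot, 1), lambda = nul$lambda,
                    row.names = NULL)
  out
}

#' Mixed-linear-model haplotype-block association scan
#'
#' Omnibus F-test per haplotype block: the incidence columns of the
#' block's common alleles (most frequent allele dropped as reference,
#' giving a - 1 degrees of freedom for a alleles) are tested jointly in
#' the same whitened mixed model as \code{\link{mlmScanSnp}}. Lines whose
#' block call is missing or pooled as rare carry all-zero incidence and
#' act as reference-level observations. Per-allele effects are reported
#' descriptively as the carrier mean minus the block mean, in trait units
#' and as a percentage of the trial mean.
#'
#' @param y named numeric vector of adjusted means (one trial).
#' @param H a \linkS4class{HapMatrix}.
#' @param K kinship matrix.
#' @param covars optional fixed covariates.
#' @return data.frame: block, df, p, R2, plus attribute
#'   \code{"allele_effects"} (data.frame block, allele, n_carrier, effect,
#'   effect_pct).
#' @export
mlmScanHap <- function(y, H, K, covars = NULL) {
  ids <- intersect(names(y), rownames(hapIncidence(H)))
  y0 <- y[ids]
  inc <- hapIncidence(H)[ids, , drop = FALSE]
  K <- K[ids, ids]
  X <- buildFixed(length(y0), covars, ids)
  nul <- remlNull(y0, X, K)
  U <- nul$U; w <- nul$lambda * nul$d + 1
  yt <- as.numeric(crossprod(U, nul$y)) / sqrt(w)
  Xt <- crossprod(U, nul$X) / sqrt(w)
  qrX <- qr(Xt)
  ry <- qr.resid(qrX, yt)
  rss0 <- sum(ry^2)
  sstot <- sum((yt - mean(yt))^2)
  n <- length(yt); q <- ncol(Xt)
  blocks <- unique(hapBlockId(H))
  rows <- list(); eff <- list()
  for (b in blocks) {
    sel <- which(hapBlockId(H) == b)
    if (length(sel) < 2) next                     # single common allele
    frq <- colSums(inc[, sel, drop = FALSE])
    refcol <- sel[which.max(frq)]
    use <- setdiff(sel, refcol)
    Ht <- crossprod(U, inc[, use, drop = FALSE]) / sqrt(w)
    rH <- qr.resid(qrX, Ht)
    qrH <- qr(rH)
    rk <- qrH$rank
    if (rk < 1) next
    fit_res <- qr.resid(qrH, ry)
    rss1 <- sum(fit_res^2)
    df2 <- n - q - rk
    Fst <- ((rss0 - rss1) / rk) / (rss1 / df2)
    p <- pf(Fst, rk, df2, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      block = b, df = rk, p = max(p, .Machine$double.xmin),
      R2 = min((rss0 - rss1) / sstot, 1))
    called <- rowSums(inc[, sel, drop = FALSE]) > 0
    bm <- mean(y0[called])
    for (cc in sel) {
      car <- inc[, cc] == 1
      eff[[length(eff) + 1L]] <- data.frame(
        block = b, allele = hapAllele(H)[cc], n_carrier = sum(car),
        effect = mean(y0[car]) - bm,
        effect_pct = 100 * (mean(y0[car]) - bm) / mean(y0))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(block = character(0), df = integer(0),
                         p = numeric(0), R2 = numeric(0))
  attr(out, "allele_effects") <- if (length(eff)) do.call(rbind, eff)
                                 else NULL
  out
}

buildFixed <- function(n, covars, ids) {
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covars)) {
    C <- as.matrix(covars)
    if (!is.null(rownames(C))) C <- C[ids, , drop = FALSE]
    X <- cbind(X, C)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      warning("dropping ", ncol(X) - qx$rank, " collinear covariate column(s)")
      X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    }
  }
  X
}

#' Classify significant loci into cross-trial consistency groups
#'
#' Aggregates per-trial significance calls for each locus into one of four
#' groups: (1) associated in only one year cohort (EYT); (2) strictly
#' associated in a single environment across cohorts; (3) consistently
#' associated across cohorts and in multiple environments within each
#' significant cohort; (4) associated across cohorts but in varying
#' environments. Loci significant nowhere are excluded.
#'
#' @param results data.frame with columns locus, eyt, env, p (stacked over
#'   trials; the same locus set scanned in >= 2 trials).
#' @param p_threshold significance cutoff applied to \code{p}; the default
#'   is Bonferroni at alpha = 0.05 over the distinct loci scanned.
#' @return data.frame locus, group (1..4), n_eyt, n_env, n_trials.
#' @export
classifyGroups <- function(results, p_threshold = NULL) {
  if (is.null(p_threshold))
    p_threshold <- 0.05 / length(unique(results$locus))
  sig <- results[results$p < p_threshold, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(locus = character(0), group = integer(0),
                      n_eyt = integer(0), n_env = integer(0),
                      n_trials = integer(0)))
  out <- lapply(split(sig, sig$locus), function(s) {
    eyts <- unique(s$eyt); envs <- unique(s$env)
    grp <- if (length(eyts) == 1) 1L
           else if (length(envs) == 1) 2L
           else if (all(vapply(split(s$env, s$eyt),
                               function(z) length(unique(z)) >= 2,
                               logical(1)))) 3L
           else 4L
    data.frame(locus = s$locus[1], group = grp, n_eyt = length(eyts),
               n_env = length(envs), n_trials = nrow(s))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
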