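#' Additive (marker) relationship matrix
#'
#' \eqn{G_M = M M'} from the \{1, 0, -1\} marker codes; missing calls are
#' replaced by the column mean so they contribute nothing after centering
#' around it. With \code{scale = TRUE} (default) the matrix is divided by
#' \code{mean(diag(G))} so the mean diagonal is 1.
#'
#' @param geno a \linkS4class{SnpMatrix} or numeric score matrix.
#' @param scale rescale to unit mean diagonal.
#' @return symmetric n x n kernel with attribute \code{kind = "G_M"}.
#' @export
kernelAdditive <- function(geno, scale = TRUE) {
  M <- if (is(geno, "SnpMatrix")) genoCodes(geno) else as.matrix(geno)
  cm <- colMeans(M, na.rm = TRUE)
  idx <- which(is.na(M))
  if (length(idx)) M[idx] <- cm[(idx - 1) %/% nrow(M) + 1]
  if (all(apply(M, 2, var) < 1e-12) || sum(M^2) < 1e-12)
    stop("zero-variance score matrix")
  G <- tcrossprod(M)
  if (scale) G <- G / mean(diag(G))
  G <- (G + t(G)) / 2
  attr(G, "kind") <- "G_M"
  G
}

#' Haplotype-sharing relationship matrix
#'
#' \eqn{G_H = H H'} from the binary haplotype-allele incidence matrix;
#' entry (i, j) counts the haplotype alleles shared by lines i and j
#' (before scaling). All-zero rows (lines with no called block) trigger a
#' warning.
#'
#' @param H a \linkS4class{HapMatrix} or binary incidence matrix.
#' @param scale rescale to unit mean diagonal.
#' @return symmetric kernel with attribute \code{kind = "G_H"}.
#' @export
kernelHaplotype <- function(H, scale = TRUE) {
  inc <- if (is(H, "HapMatrix")) hapIncidence(H) else as.matrix(H)
  if (any(rowSums(inc) == 0))
    warning("line(s) with no called haplotype allele (all-zero row)")
  G <- tcrossprod(inc)
  if (scale) {
    md <- mean(diag(G))
    if (md < 1e-12) stop("empty incidence matrix")
    G <- G / md
  }
  G <- (G + t(G)) / 2
  attr(G, "kind") <- "G_H"
  G
}

#' Gaussian (RKHS) kernel from marker or haplotype scores
#'
#' \eqn{G_{ij} = \exp(-D_{ij}/\theta)} with
#' \eqn{D_{ij} = [(1/(4m)) \sum_k (S_{ik}-S_{jk})^2]^{1/2}} for marker
#' scores in \{1, 0, -1\} — the 1/(4m) normaliser maps D into [0, 1]
#' because opposite homozygotes differ by 2. For binary haplotype scores
#' the normaliser is 1/m so D again spans [0, 1]. The scale parameter
#' defaults to the median off-diagonal distance (self-tuning heuristic).
#'
#' @param scores \linkS4class{SnpMatrix}, \linkS4class{HapMatrix} or a
#'   numeric matrix; missing values mean-imputed.
#' @param theta positive scale parameter or \code{"auto"}.
#' @param normalizer \code{1/(4m)} for marker codes, \code{1/m} for binary
#'   scores; chosen automatically from the input class/range.
#' @return kernel with unit diagonal, entries in (0, 1], attributes
#'   \code{kind} (\code{"G_MG"} or \code{"G_HG"}) and \code{theta}.
#' @export
kernelGaussian <- function(scores, theta = "auto", normalizer = NULL) {
  hap <- is(scores, "HapMatrix")
  S <- if (is(scores, "SnpMatrix")) genoCodes(scores)
       else if (hap) hapIncidence(scores) else as.matrix(scores)
  cm <- colMeans(S, na.rm = TRUE)
  idx <- which(is.na(S))
  if (length(idx)) S[idx] <- cm[(idx - 1) %/% nrow(S) + 1]
  m <- ncol(S)
  stopifnot(m >= 1)
  if (is.null(normalizer))
    normalizer <- if (hap || all(S %in% c(0, 1))) 1 / m else 1 / (4 * m)
  sq <- rowSums(S^2)
  D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(S), 0) * normalizer
  D <- sqrt(D2)
  if (identical(theta, "auto")) theta <- median(D[upper.tri(D)])
  if (!is.numeric(theta) || theta <= 0)
    stop("theta must be a positive scale parameter")
  G <- exp(-D / theta)
  diag(G) <- 1
  G <- (G + t(G)) / 2
  attr(G, "kind") <- if (hap) "G_HG" else "G_MG"
  attr(G, "theta") <- theta
  G
}

#' Epistatic (additive-by-additive) kernel
#'
#' Hadamard square of a relationship matrix, rescaled to unit mean
#' diagonal — the classical additive-by-additive epistatic relationship
#' used as an extra RKHS random term.
#'
#' @param G a relationship matrix.
#' @return kernel with attribute \code{kind = "epistasis"}.
#' @export
kernelEpistasis <- function(G) {
  E <- G * G
  E <- E / mean(diag(E))
  attr(E, "kind") <- "epistasis"
  E
}

#' Prediction-model specifications
#'
#' The four standard configurations: (1) environment + additive marker
#' kernel (base); (2) environment + haplotype kernel + epistasis;
#' (3) environment + predefined marker columns as fixed effects +
#' marker Gaussian kernel + epistasis; (4) environment + predefined
#' haplotype columns as fixed effects + haplotype Gaussian kernel +
#' epistasis.
#'
#' @param id model id 1..4.
#' @return list: id, kernel kind, epistasis flag, fixed-locus flag.
#' @export
modelSpec <- function(id) {
  stopifnot(id %in% 1:4)
  switch(id,
    list(id = 1L, kernel = "G_M",  epistasis = FALSE, fixed_loci = FALSE),
    list(id = 2L, kernel = "G_H",  epistasis = TRUE,  fixed_loci = FALSE),
    list(id = 3L, kernel = "G_MG", epistasis = TRUE,  fixed_loci = TRUE),
    list(id = 4L, kernel = "G_HG", epistasis = TRUE,  fixed_loci = TRUE))
}

#' Assemble the kernel list for a model specification
#'
#' @param spec from \code{\link{modelSpec}}.
#' @param geno \linkS4class{SnpMatrix} (models 1, 3).
#' @param H \linkS4class{HapMatrix} (models 2, 4).
#' @param theta Gaussian-kernel scale, \code{"auto"} by default.
#' @return named list of kernels (main, and epistasis when the model
#'   carries it).
#' @export
modelKernels <- function(spec, geno = NULL, H = NULL, theta = "auto") {
  main <- switch(spec$kernel,
    G_M  = kernelAdditive(geno),
    G_H  = kernelHaplotype(H),
    G_MG = kernelGaussian(geno, theta),
    G_HG = kernelGaussian(H, theta))
  ids <- if (spec$kernel %in% c("G_M", "G_MG")) lineIds(geno)
         else rownames(hapIncidence(H))
  dimnames(main) <- list(ids, ids)
  ks <- list(main = main)
  if (spec$epistasis) {
    ks$epistasis <- kernelEpistasis(main)
    dimnames(ks$epistasis) <- dimnames(main)
  }
  ks
}

#' Default Gibbs-chain settings
#' @param iter total iterations, burn burn-in, thin kept every draw,
#'   seed RNG seed.
#' @param burn,seed see above.
#' @export
chainSettings <- function(iter = 6000, burn = 1000, seed = 1L)
  list(iter = as.integer(iter), burn = as.integer(burn),
       seed = as.integer(seed))

#' Fit a multi-kernel G-BLUP / RKHS model by Gibbs sampling
#'
#' Bayesian mixed model \eqn{y = X\beta + \sum_k Z u_k + \epsilon} with
#' flat priors on the fixed effects (one intercept per environment plus
#' optional predefined locus columns), independent random effects
#' \eqn{u_k \sim N(0, K_k \sigma_k^2)} for each supplied kernel, and
#' scaled-inverse-chi-squared priors on all variances. Each kernel is
#' eigendecomposed once on the training lines (non-PSD kernels are bent:
#' eigenvalues floored at 1e-6 with a warning) and its random effect is
#' sampled in the eigenbasis, where the conditional is diagonal for
#' balanced designs. Held-out lines are predicted through the conditional
#' expectation \eqn{K_{test,train} K_{train,train}^{-1} \bar u}.
#' Deterministic under a fixed chain seed.
#'
#' @param y data.frame with columns line, env, value: adjusted means
#'   stacked over the environments of one year cohort.
#' @param kernels named list of symmetric n x n matrices with line
#'   dimnames covering all lines to predict.
#' @param fixed optional matrix (lines x q, rownames = line ids) of
#'   predefined locus columns entering as fixed effects; collinear columns
#'   are pruned with a warning.
#' @param train character vector of training lines; everything else is
#'   masked from the likelihood and predicted. Default: all lines in y.
#' @param chain \code{\link{chainSettings}}.
#' @return list: \code{pred} (lines x env matrix of posterior-mean
#'   predictions for all kernel lines), \code{beta}, \code{varcomp},
#'   \code{u} (list per kernel, training lines), \code{chain}.
#' @export
fitModel <- function(y, kernels, fixed = NULL, train = NULL,
                     chain = chainSettings()) {
  stopifnot(is.list(kernels), length(kernels) >= 1,
            all(c("line", "env", "value") %in% names(y)))
  all_lines <- rownames(kernels[[1]])
  if (is.null(all_lines)) stop("kernels need line dimnames")
  envs <- sort(unique(as.character(y$env)))
  if (is.null(train)) train <- unique(as.character(y$line))
  train <- intersect(train, all_lines)
  obs <- y[y$line %in% train & !is.na(y$value), ]
  train <- intersect(train, unique(as.character(obs$line)))
  n_obs <- nrow(obs)
  li <- match(as.character(obs$line), train)
  # fixed design: env intercepts + optional locus columns
  X <- sapply(envs, function(ev) as.numeric(obs$env == ev))
  colnames(X) <- paste0("env:", envs)
  if (!is.null(fixed)) {
    Fm <- as.matrix(fixed)
    if (is.null(rownames(Fm))) stop("fixed needs line rownames")
    Xf <- Fm[as.character(obs$line), , drop = FALSE]
    X <- cbind(X, Xf)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      warning("pruning ", ncol(X) - qx$rank, " collinear fixed column(s)")
      X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    }
  }
  q <- ncol(X)
  # eigen-representation of each kernel on the training lines
  # per-line observation counts; balanced counts make W'W diagonal and let
  # all per-iteration products factor through the (smaller) line space
  cnt <- tabulate(li, nbins = length(train))
  KS <- lapply(kernels, function(K) {
    K <- (K + t(K)) / 2
    Kt <- K[train, train]
    eg <- eigen(Kt, symmetric = TRUE)
    if (min(eg$values) < -1e-8) {
      warning("non-PSD kernel bent (eigenvalue floor 1e-6)")
      eg$values <- pmax(eg$values, 1e-6)
    }
    keep <- eg$values > 1e-9 * max(eg$values)
    d <- eg$values[keep]; U <- eg$vectors[, keep, drop = FALSE]
    Us <- U * rep(sqrt(d), each = nrow(U))       # lines x m, = U diag(sqrt d)
    if (max(cnt) == min(cnt)) {                  # balanced: W'W = c * D
      list(K = K, U = U, d = d, Us = Us, W = NULL, WtW = NULL,
           wdiag = cnt[1] * d, m = length(d))
    } else {
      W <- Us[li, , drop = FALSE]
      WtW <- crossprod(W)
      diag_only <- max(abs(WtW - diag(diag(WtW)))) < 1e-8 * max(diag(WtW))
      list(K = K, U = U, d = d, Us = Us, W = W,
           WtW = if (diag_only) NULL else WtW,
           wdiag = diag(WtW), m = length(d))
    }
  })
  yv <- obs$value
  vy <- var(yv)
  nu0 <- 5
  S0e <- vy * 0.5 * (nu0 + 2) / nu0
  S0k <- vapply(KS, function(ks) vy * 0.5 * (nu0 + 2) / (nu0 * mean(ks$d)),
                numeric(1))
  XtX <- crossprod(X)
  Rx <- chol(XtX + diag(1e-8, q))
  withSeed(chain$seed, {
    beta <- qr.coef(qr(X), yv); beta[is.na(beta)] <- 0
    b <- lapply(KS, function(ks) numeric(ks$m))
    s2k <- rep(vy / (2 * length(KS)), length(KS))
    s2e <- vy / 2
    Wb <- lapply(KS, function(ks) numeric(n_obs))
    sum_beta <- 0 * beta
    sum_b <- lapply(KS, function(ks) numeric(ks$m))
    sum_s <- c(numeric(length(KS)), 0)
    kept <- 0L
    xb <- as.numeric(X %*% beta)
    resid <- yv - xb           # maintained incrementally: yv - xb - sum Wb
    for (it in seq_len(chain$iter)) {
      r_beta <- resid + xb
      mb <- backsolve(Rx, forwardsolve(t(Rx), crossprod(X, r_beta)))
      beta <- as.numeric(mb) + backsolve(Rx, rnorm(q)) * sqrt(s2e)
      xb_new <- as.numeric(X %*% beta)
      resid <- resid + xb - xb_new
      xb <- xb_new
      for (k in seq_along(KS)) {
        ks <- KS[[k]]
        r <- resid + Wb[[k]]
        rhs <- if (is.null(ks$W))
          crossprod(ks$Us, rowsum(r, li, reorder = TRUE)) / s2e
        else crossprod(ks$W, r) / s2e
        if (is.null(ks$WtW)) {
          prec <- ks$wdiag / s2e + 1 / s2k[k]
          b[[k]] <- as.numeric(rhs / prec + rnorm(ks$m) / sqrt(prec))
        } else {
          P <- ks$WtW / s2e + diag(1 / s2k[k], ks$m)
          Rp <- chol(P)
          mk <- backsolve(Rp, forwardsolve(t(Rp), rhs))
          b[[k]] <- as.numeric(mk + backsolve(Rp, rnorm(ks$m)))
        }
        Wb_new <- if (is.null(ks$W))
          as.numeric(ks$Us %*% b[[k]])[li]
        else as.numeric(ks$W %*% b[[k]])
        resid <- resid + Wb[[k]] - Wb_new
        Wb[[k]] <- Wb_new
        s2k[k] <- (sum(b[[k]]^2) + S0k[k] * nu0) /
                  rchisq(1, nu0 + ks$m)
      }
      s2e <- (sum(resid^2) + S0e * nu0) / rchisq(1, nu0 + n_obs)
      if (s2e > 1e6 * vy || any(s2k > 1e6 * vy))
        stop("divergent chain: variance exceeded 1e6 x phenotypic variance")
      if (it > chain$burn) {
        kept <- kept + 1L
        sum_beta <- sum_beta + beta
        for (k in seq_along(KS)) sum_b[[k]] <- sum_b[[k]] + b[[k]]
        sum_s <- sum_s + c(s2k, s2e)
      }
    }
    beta_hat <- sum_beta / kept
    b_hat <- lapply(sum_b, function(z) z / kept)
    varcomp <- sum_s / kept
    names(varcomp) <- c(paste0("sigma2_", names(kernels)), "sigma2_e")
    # genetic values for all lines: train via eigenbasis, others via the
    # conditional expectation K[new, train] K[train, train]^{-1} u
    u_all <- setNames(numeric(length(all_lines)), all_lines)
    for (k in seq_along(KS)) {
      ks <- KS[[k]]
      u_tr <- as.numeric(ks$U %*% (sqrt(ks$d) * b_hat[[k]]))
      u_all[train] <- u_all[train] + u_tr
      others <- setdiff(all_lines, train)
      if (length(others)) {
        proj <- ks$K[others, train, drop = FALSE] %*%
                (ks$U %*% (b_hat[[k]] / sqrt(ks$d)))
        u_all[others] <- u_all[others] + as.numeric(proj)
      }
    }
    names(beta_hat) <- colnames(X)
    envcols <- paste0("env:", envs)
    env_beta <- ifelse(envcols %in% names(beta_hat),
                       beta_hat[envcols], 0)
    pred <- outer(u_all, env_beta, "+")
    dimnames(pred) <- list(all_lines, envs)
    fcols <- setdiff(colnames(X), envcols)
    if (length(fcols)) {
      Fm <- as.matrix(fixed)
      contrib <- as.numeric(Fm[all_lines, fcols, drop = FALSE] %*%
                            beta_hat[fcols])
      pred <- pred + contrib
    }
    list(pred = pred, beta = beta_hat, varcomp = varcomp,
         u = setNames(b_hat, names(kernels)), chain = chain,
         train = train, envs = envs)
  })
}

#' Repeated whole-line cross-validation of a prediction model
#'
#' Per repeat, a random 10\% of lines is masked in every environment of
#' the cohort (prediction of untested lines), the model is refitted on the
#' remaining 90\%, and the prediction accuracy on the test set is
#' recorded: the Pearson correlation between observed and predicted
#' values, computed within each environment and averaged. The
#' within-environment definition matches how single-environment test sets
#' are scored and keeps the accuracy scale free of the (large)
#' environment-mean spread, which would otherwise dominate a pooled
#' correlation and mask model differences; set \code{pool_envs = TRUE}
#' for the pooled variant. The split sequence is derived deterministically
#' from \code{seed}, so models run with the same seed are compared on
#' byte-identical splits (hash returned for pairing checks).
#'
#' @param y data.frame line, env, value (one cohort).
#' @param kernels,fixed,chain passed to \code{\link{fitModel}}.
#' @param repeats number of random splits.
#' @param test_frac fraction of lines held out per repeat.
#' @param seed split-sequence seed.
#' @param pool_envs compute one pooled correlation over all test
#'   observations instead of the within-environment mean.
#' @return list of class \code{"CVResult"}: accuracies, mean, sd,
#'   n_repeats, splits_hash, flags.
#' @export
crossValidate <- function(y, kernels, fixed = NULL, repeats = 100,
                          test_frac = 0.10, seed = 1L,
                          chain = chainSettings(1500, 300),
                          pool_envs = FALSE) {
  lines <- sort(intersect(unique(as.character(y$line)),
                          rownames(kernels[[1]])))
  n <- length(lines)
  n_test <- max(1, round(test_frac * n))
  splits <- withSeed(stageSeed(seed, "split"), {
    lapply(seq_len(repeats), function(r) sort(sample(lines, n_test)))
  })
  acc <- numeric(repeats); flags <- character(repeats)
  for (r in seq_len(repeats)) {
    test <- splits[[r]]
    fit <- fitModel(y, kernels, fixed = fixed,
                    train = setdiff(lines, test),
                    chain = chainSettings(chain$iter, chain$burn,
                                          seed = chain$seed + r))
    ty <- y[y$line %in% test & !is.na(y$value), ]
    yhat <- fit$pred[cbind(as.character(ty$line), as.character(ty$env))]
    if (sd(yhat) < 1e-12) {
      acc[r] <- 0; flags[r] <- "constant predictions"
    } else if (pool_envs) {
      acc[r] <- cor(ty$value, yhat)
    } else {
      by_env <- vapply(split(seq_len(nrow(ty)), ty$env), function(ix) {
        if (length(ix) < 3 || sd(yhat[ix]) < 1e-12) NA_real_
        else cor(ty$value[ix], yhat[ix])
      }, numeric(1))
      acc[r] <- mean(by_env, na.rm = TRUE)
      if (all(is.na(by_env))) { acc[r] <- 0; flags[r] <- "constant predictions" }
    }
  }
  structure(list(accuracies = acc, mean = mean(acc), sd = sd(acc),
                 n_repeats = repeats,
                 splits_hash = paste(unlist(splits), collapse = "|"),
                 flags = flags),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("CVResult: %d repeats, mean accuracy %.3f (sd %.3f)\n",
              x$n_repeats, x$mean, x$sd))
  invisible(x)
}

#' Compare cross-validated models on paired splits
#'
#' All models must have been evaluated on identical split sequences
#' (checked by hash equality). Reports per-model mean accuracy, paired
#' mean difference against the first (base) model, the least significant
#' difference at alpha = 0.05 from the paired-repeat variance, and the
#' percent change versus the base model.
#'
#' @param results named list of \code{"CVResult"} objects; the first is
#'   the base model.
#' @param alpha significance level for the LSD.
#' @return data.frame model, mean, sd, diff_vs_base, lsd, pct_change,
#'   exceeds_lsd.
#' @export
compareModels <- function(results, alpha = 0.05) {
  stopifnot(length(results) >= 1)
  hashes <- vapply(results, function(r) r$splits_hash, character(1))
  if (length(unique(hashes)) != 1)
    stop("models were not evaluated on identical (paired) split sequences")
  base <- results[[1]]$accuracies
  R <- length(base)
  out <- lapply(seq_along(results), function(i) {
    a <- results[[i]]$accuracies
    d <- a - base
    sed <- if (i == 1) 0 else sd(d) / sqrt(R)
    lsd <- if (i == 1) 0 else qt(1 - alpha / 2, R - 1) * sed
    data.frame(model = names(results)[i] %||% paste0("model", i),
               mean = mean(a), sd = sd(a), diff_vs_base = mean(d),
               lsd = lsd,
               pct_change = 100 * (mean(a) - mean(base)) /
                            max(abs(mean(base)), 1e-12),
               exceeds_lsd = i > 1 && abs(mean(d)) > lsd)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Closed-form ridge/G-BLUP oracle predictions
#'
#' Deterministic single-kernel mixed-model predictions: variance ratio by
#' REML (eigendecomposition of the kernel), then
#' \eqn{\hat u = \lambda K (\lambda K + I)^{-1} (y - X\hat\beta)} and
#' predictions \eqn{X\hat\beta + \hat u}. Used as an independent check of
#' the Gibbs sampler in the single-kernel case.
#'
#' @param yv named phenotype vector (single environment).
#' @param K kernel with matching dimnames.
#' @return list: pred (named vector), lambda, beta.
#' @export
gblupRidgeOracle <- function(yv, K) {
  ids <- intersect(names(yv), rownames(K))
  yv <- yv[ids]; K <- K[ids, ids]
  X <- matrix(1, length(yv), 1)
  nul <- remlNull(yv, X, K)
  lam <- nul$lambda
  V <- lam * K + diag(length(yv))
  Vi <- solve(V)
  beta <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% yv))
  u <- lam * K %*% Vi %*% (yv - as.numeric(X %*% beta))
  pred <- as.numeric(X %*% beta) + as.numeric(u)
  list(pred = setNames(pred, ids), lambda = lam, beta = as.numeric(beta))
}
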