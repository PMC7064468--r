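test_that("VanRaden kinship matches a hand-computed small example", {
  # 4 lines x 3 SNPs, codes {1,-1}; dosage X = code + 1
  codes <- rbind(L1 = c(1, 1, -1), L2 = c(1, -1, -1),
                 L3 = c(-1, 1, 1), L4 = c(-1, -1, 1))
  g <- makeSnp(codes)
  X <- codes + 1
  p <- colMeans(X) / 2
  Z <- sweep(X, 2, 2 * p)
  G_hand <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  K <- vanRadenKinship(g)
  expect_equal(unclass(K), G_hand, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(isSymmetric(K))
})

test_that("duplicated lines have identical kinship rows and inbred diagonal is ~2", {
  cfg <- simConfig(n_lines = 300, n_chrom = 3, snps_per_chrom = 40, seed = 21)
  g <- simulateGenotypes(cfg)
  K <- vanRadenKinship(g)
  # fully inbred panel: mean diagonal near 1 + f = 2 on the outbred scale
  expect_lt(abs(mean(diag(K)) - 2), 0.1)
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  codes <- genoCodes(g); codes[2, ] <- codes[1, ]
  K2 <- vanRadenKinship(makeSnp(codes,
                                chrom = snpChrom(g), pos = snpPos(g)))
  expect_equal(K2[1, ], K2[2, ], tolerance = 1e-12, ignore_attr = TRUE)
  expect_warning(vanRadenKinship(makeSnp(cbind(rep(1, 10), c(1, rep(-1, 9))))),
                 "monomorphic")
})

test_that("PCA covariates separate founder groups and respect duplicates", {
  set.seed(22)
  grp1 <- matrix(rep(c(1, 1, -1, 1, -1, 1, 1, -1, 1, 1), each = 30), 30) +
          matrix(sample(c(0, 0, 0, -2), 300, replace = TRUE), 30)
  grp2 <- matrix(rep(c(-1, -1, 1, -1, 1, -1, -1, 1, -1, -1), each = 30), 30) +
          matrix(sample(c(0, 0, 0, 2), 300, replace = TRUE), 30)
  codes <- pmax(pmin(rbind(grp1, grp2), 1), -1)
  rownames(codes) <- sprintf("L%02d", 1:60)
  g <- makeSnp(codes)
  pc <- pcaCovariates(g, max_pcs = 4)
  s1 <- pc$scores[1:30, 1]; s2 <- pc$scores[31:60, 1]
  # PC1 separates the groups cleanly
  expect_true(max(min(s1) - max(s2), min(s2) - max(s1)) > 0)
  # duplicate lines get identical scores
  codes[2, ] <- codes[1, ]
  pc2 <- pcaCovariates(makeSnp(codes), max_pcs = 4)
  expect_equal(pc2$scores[1, ], pc2$scores[2, ], tolerance = 1e-10)
})

test_that("BIC picks zero components when the phenotype ignores structure", {
  hits <- 0; n_seed <- 15
  for (s in seq_len(n_seed)) {
    set.seed(700 + s)
    codes <- matrix(sample(c(1, -1), 120 * 50, replace = TRUE), 120)
    rownames(codes) <- sprintf("L%03d", 1:120)
    y <- rnorm(120)
    pc <- pcaCovariates(makeSnp(codes), y, max_pcs = 5)
    if (pc$k == 0) hits <- hits + 1
  }
  expect_gte(hits / n_seed, 0.8)
})

test_that("with identity kinship the MLM scan reproduces OLS p-values", {
  set.seed(23)
  cfg <- simConfig(n_lines = 120, n_chrom = 2, snps_per_chrom = 15, seed = 24)
  g <- simulateGenotypes(cfg)
  y <- setNames(rnorm(120, 5000, 400), lineIds(g))
  K <- diag(120); dimnames(K) <- list(lineIds(g), lineIds(g))
  scan <- mlmScanSnp(y, g, K)
  p_ols <- vapply(seq_len(nSnps(g)), function(j) {
    fit <- summary(lm(y ~ genoCodes(g)[, j]))
    fit$coefficients[2, 4]
  }, numeric(1))
  expect_equal(scan$p, p_ols, tolerance = 1e-6)
})

test_that("MLM p-values are invariant to allele-label swaps", {
  cfg <- simConfig(n_lines = 100, n_chrom = 1, snps_per_chrom = 10, seed = 25)
  g <- simulateGenotypes(cfg)
  y <- setNames(rnorm(100, 0, 1) + genoCodes(g)[, 3], lineIds(g))
  K <- vanRadenKinship(g)
  s1 <- mlmScanSnp(y, g, K)
  codes <- genoCodes(g); codes[, 3] <- -codes[, 3]
  s2 <- mlmScanSnp(y, makeSnp(codes, chrom = snpChrom(g), pos = snpPos(g)), K)
  expect_equal(s2$p, s1$p, tolerance = 1e-9)
  expect_equal(s2$beta[3], -s1$beta[3], tolerance = 1e-9)
})

test_that("a planted QTL is detected against a polygenic background", {
  # marker density matters here: with very few markers in the kinship the
  # tested block dominates K and the scan suffers proximal contamination
  hits <- 0; n_seed <- 10
  for (s in seq_len(n_seed)) {
    cfg <- simConfig(n_lines = 500, n_chrom = 4, snps_per_chrom = 250,
                     seed = 800 + s)
    g <- simulateGenotypes(cfg)
    set.seed(900 + s)
    M <- genoCodes(g)
    bt <- attr(g, "block_truth")
    b <- which(bt$start_idx <= 10 & bt$end_idx >= 10)
    excl <- bt$start_idx[b]:bt$end_idx[b]
    x <- M[, 10]
    u <- as.numeric(M[, -excl] %*% rnorm(ncol(M) - length(excl), 0, 1))
    u <- u / sd(u) * sqrt(0.3)
    qtl <- x / sd(x) * sqrt(0.1)
    y <- setNames(qtl + u + rnorm(500, 0, sqrt(0.6)), lineIds(g))
    K <- vanRadenKinship(g)
    if (mlmScanSnp(y, g, K)$p[10] < 1e-4) hits <- hits + 1
  }
  expect_gte(hits / n_seed, 0.9)
})

test_that("haplotype omnibus test nests the member-SNP tests", {
  cfg <- simConfig(n_lines = 250, n_chrom = 1, snps_per_chrom = 12,
                   block_size_range = c(3L, 3L), founders_per_block = 4,
                   seed = 26)
  g <- simulateGenotypes(cfg)
  bl <- buildBlocks(g)
  skip_if(nrow(bl) == 0, "no blocks formed under this seed")
  H <- callHaplotypes(g, bl, hap_freq_min = 0)
  set.seed(27)
  y <- setNames(rnorm(250, 5000, 300) + 100 * genoCodes(g)[, bl$first[1]],
                lineIds(g))
  K <- vanRadenKinship(g)
  hs <- mlmScanHap(y, H, K)
  ss <- mlmScanSnp(y, g, K)
  for (k in seq_len(nrow(bl))) {
    members <- bl$first[k]:bl$last[k]
    expect_gte(hs$R2[hs$block == bl$name[k]] + 1e-10,
               max(ss$R2[members]))
  }
})

test_that("a two-allele block's omnibus p equals the single-dummy test", {
  f <- rbind(c(1, 1), c(-1, -1))
  codes <- makeFounderPanel(150, f, seed = 9)
  rownames(codes) <- sprintf("L%03d", 1:150)
  g <- makeSnp(codes)
  bl <- buildBlocks(g)
  H <- callHaplotypes(g, bl, hap_freq_min = 0)
  set.seed(28)
  y <- setNames(rnorm(150) + 0.5 * codes[, 1], rownames(codes))
  K <- diag(150); dimnames(K) <- list(rownames(codes), rownames(codes))
  hs <- mlmScanHap(y, H, K)
  expect_equal(hs$df, 1)
  dummy <- hapIncidence(H)[, which.min(colSums(hapIncidence(H)))]
  p_t <- summary(lm(y ~ dummy))$coefficients[2, 4]
  expect_equal(hs$p, p_t, tolerance = 1e-6)
})

test_that("planted haplotype-allele effects are recovered within a point of truth", {
  errs <- vapply(1:20, function(s) {
    f <- rbind(c(1, 1), c(-1, -1), c(1, -1))
    codes <- makeFounderPanel(400, f, prob = c(0.4, 0.4, 0.2), seed = 40 + s)
    rownames(codes) <- sprintf("L%03d", 1:400)
    g <- makeSnp(codes)
    H <- callHaplotypes(g, data.frame(name = "HB1.1", chrom = "1",
                                      first = 1, last = 2, n_snps = 2,
                                      start = 100, end = 200,
                                      snps = I(list(c("a", "b")))),
                        hap_freq_min = 0.05)
    set.seed(70 + s)
    target <- hapIncidence(H)[, match("AA", hapAllele(H))]
    mu <- 5000
    # plant the allele so the carrier-vs-mean contrast is exactly 5% of mu
    delta <- 0.05 * mu / (1 - mean(target))
    y <- setNames(mu + delta * target + rnorm(400, 0, 150),
                  rownames(codes))
    K <- diag(400); dimnames(K) <- list(rownames(codes), rownames(codes))
    hs <- mlmScanHap(y, H, K)
    eff <- attr(hs, "allele_effects")
    eff$effect_pct[eff$allele == "AA"] - 5
  }, numeric(1))
  expect_lt(abs(mean(errs)), 1)
})

test_that("consistency groups follow their verbal definitions", {
  res <- data.frame(
    locus = c("A", "B", "B", "B", "C", "C", "C", "D", "D"),
    eyt = c("EYT1", "EYT1", "EYT2", "EYT3", "EYT1", "EYT1", "EYT2",
            "EYT1", "EYT2"),
    env = c("B-5IR", "HS", "HS", "HS", "SD", "HS", "SD", "SD", "HS"),
    p = 1e-8)
  extra <- data.frame(locus = "C", eyt = "EYT2", env = "HS", p = 1e-8)
  res <- rbind(res, extra)
  g <- classifyGroups(res, p_threshold = 1e-4)
  expect_equal(g$group[g$locus == "A"], 1)   # one EYT only
  expect_equal(g$group[g$locus == "B"], 2)   # single env across EYTs
  expect_equal(g$group[g$locus == "C"], 3)   # multiple envs in each EYT
  expect_equal(g$group[g$locus == "D"], 4)   # across EYTs, varying envs
  # non-significant loci are excluded
  none <- data.frame(locus = "Z", eyt = "EYT1", env = "HS", p = 0.5)
  expect_equal(nrow(classifyGroups(none, p_threshold = 1e-4)), 0)
})

test_that("group classification equals the enumeration oracle on all patterns", {
  eyts <- c("EYT1", "EYT2"); envs <- c("E1", "E2")
  grid <- expand.grid(eyt = eyts, env = envs, stringsAsFactors = FALSE)
  for (mask in 1:15) {
    sig <- as.logical(bitwAnd(mask, c(1, 2, 4, 8)))
    res <- data.frame(locus = "X", eyt = grid$eyt, env = grid$env,
                      p = ifelse(sig, 1e-9, 0.9))
    got <- classifyGroups(res, p_threshold = 1e-4)$group
    sig_mat <- matrix(sig, 2, 2, dimnames = list(eyts, envs))
    expect_equal(got, oracleGroup(sig_mat),
                 info = paste("pattern", mask))
  }
})
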