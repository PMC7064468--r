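test_that("the additive kernel matches hand computation and is PSD", {
  g <- makeSnp(rbind(L1 = 1, L2 = -1))
  G <- kernelAdditive(g, scale = FALSE)
  expect_equal(unclass(G), rbind(c(1, -1), c(-1, 1)), ignore_attr = TRUE)
  set.seed(71)
  codes <- matrix(sample(c(1, -1), 60 * 30, replace = TRUE), 60)
  rownames(codes) <- sprintf("L%02d", 1:60)
  G2 <- kernelAdditive(makeSnp(codes))
  expect_equal(mean(diag(G2)), 1, tolerance = 1e-12)
  expect_gte(min(eigen(G2, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  # duplicated lines: identical rows, off-diagonal equal to diagonal
  codes[2, ] <- codes[1, ]
  G3 <- kernelAdditive(makeSnp(codes), scale = FALSE)
  expect_equal(G3[1, 2], G3[1, 1])
  expect_error(kernelAdditive(makeSnp(matrix(1, 5, 3)), scale = FALSE),
               "zero-variance")
})

test_that("the haplotype kernel counts shared alleles", {
  inc <- rbind(L1 = c(1, 0, 1, 0), L2 = c(1, 0, 1, 0), L3 = c(0, 1, 0, 1))
  G <- kernelHaplotype(inc, scale = FALSE)
  # an all-zero row is flagged
  expect_warning(kernelHaplotype(rbind(inc, L4 = c(0, 0, 0, 0)),
                                 scale = FALSE), "all-zero row")
  expect_equal(G[1, 2], 2)   # shares both block alleles
  expect_equal(G[1, 3], 0)   # disjoint haplotypes
  set.seed(72)
  inc2 <- matrix(rbinom(40 * 6, 1, 0.5), 40)
  rownames(inc2) <- sprintf("L%02d", 1:40)
  G2 <- suppressWarnings(kernelHaplotype(inc2, scale = FALSE))
  brute <- matrix(0, 40, 40)
  for (i in 1:40) for (j in 1:40)
    brute[i, j] <- sum(inc2[i, ] == 1 & inc2[j, ] == 1)
  expect_equal(unclass(G2), brute, ignore_attr = TRUE)
})

test_that("the Gaussian kernel follows the normalised-distance formula", {
  # opposite homozygotes at every marker: D = 1 under 1/(4m)
  g <- makeSnp(rbind(L1 = c(1, 1, 1), L2 = c(-1, -1, -1)))
  G <- kernelGaussian(g, theta = 0.5)
  expect_equal(diag(G), c(1, 1), ignore_attr = TRUE)
  expect_equal(G[1, 2], exp(-1 / 0.5), tolerance = 1e-12)
  # binary haplotype scores use 1/m so D spans [0,1]
  inc <- rbind(L1 = c(1, 0), L2 = c(0, 1))
  Gh <- kernelGaussian(inc, theta = 1)
  expect_equal(Gh[1, 2], exp(-1), tolerance = 1e-12)
  # monotone: larger distance, smaller kernel entry
  set.seed(73)
  codes <- matrix(sample(c(1, -1), 30 * 20, replace = TRUE), 30)
  rownames(codes) <- sprintf("L%02d", 1:30)
  G2 <- kernelGaussian(makeSnp(codes))
  D <- as.matrix(dist(codes)) / sqrt(4 * 20)
  ut <- upper.tri(D)
  expect_equal(order(D[ut]), order(-G2[ut]))
  expect_true(all(G2 > 0 & G2 <= 1))
  expect_error(kernelGaussian(makeSnp(codes), theta = -1), "theta")
})

test_that("all four kernel builders yield symmetric PSD matrices", {
  cfg <- simConfig(n_lines = 60, n_chrom = 2, snps_per_chrom = 12, seed = 74)
  g <- simulateGenotypes(cfg)
  H <- callHaplotypes(g, buildBlocks(g), hap_freq_min = 0)
  for (k in list(kernelAdditive(g), kernelHaplotype(H),
                 kernelGaussian(g), kernelGaussian(H),
                 kernelEpistasis(kernelAdditive(g)))) {
    expect_true(isSymmetric(unclass(k), check.attributes = FALSE))
    expect_gte(min(eigen(k, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("model specifications carry the four standard configurations", {
  specs <- lapply(1:4, modelSpec)
  expect_equal(vapply(specs, `[[`, character(1), "kernel"),
               c("G_M", "G_H", "G_MG", "G_HG"))
  expect_equal(vapply(specs, `[[`, logical(1), "epistasis"),
               c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(vapply(specs, `[[`, logical(1), "fixed_loci"),
               c(FALSE, FALSE, TRUE, TRUE))
})

test_that("the Gibbs fit is deterministic under a fixed chain seed", {
  cfg <- simConfig(n_lines = 60, n_chrom = 1, snps_per_chrom = 10,
                   n_envs = 2, seed = 75)
  g <- simulateGenotypes(cfg)
  sim <- simulateTrials(g, cfg)
  adj <- adjustAllTrials(sim$records)
  ydf <- data.frame(line = adj$line, env = adj$env, value = adj$value)
  ks <- modelKernels(modelSpec(1), geno = g)
  f1 <- fitModel(ydf, ks, chain = chainSettings(400, 100, seed = 5))
  f2 <- fitModel(ydf, ks, chain = chainSettings(400, 100, seed = 5))
  expect_identical(f1$pred, f2$pred)
  expect_identical(f1$varcomp, f2$varcomp)
})

test_that("single-kernel posterior means agree with the ridge oracle", {
  cfg <- simConfig(n_lines = 150, n_chrom = 3, snps_per_chrom = 20, seed = 76)
  g <- simulateGenotypes(cfg)
  M <- genoCodes(g)
  set.seed(77)
  u <- as.numeric(M %*% rnorm(ncol(M), 0, 30))
  yv <- setNames(5000 + u + rnorm(150, 0, sd(u)), lineIds(g))
  G <- kernelAdditive(g)
  dimnames(G) <- list(lineIds(g), lineIds(g))
  fit <- fitModel(data.frame(line = names(yv), env = "E1", value = yv),
                  list(main = G), chain = chainSettings(3000, 500, seed = 6))
  orc <- gblupRidgeOracle(yv, G)
  expect_gte(cor(fit$pred[names(yv), "E1"], orc$pred[names(yv)]), 0.999)
})

test_that("an identity kernel transfers nothing to held-out lines", {
  set.seed(78)
  lines <- sprintf("L%03d", 1:120)
  K <- diag(120); dimnames(K) <- list(lines, lines)
  y <- data.frame(line = rep(lines, 2), env = rep(c("E1", "E2"), each = 120),
                  value = rnorm(240, 100, 10))
  fit <- fitModel(y, list(main = K), train = lines[1:100],
                  chain = chainSettings(400, 100, seed = 7))
  # held-out lines all get the environment mean: zero spread
  expect_lt(sd(fit$pred[lines[101:120], "E1"]), 1e-8)
})

test_that("a planted fixed-effect column is recovered within 25%", {
  errs <- vapply(1:5, function(s) {
    cfg <- simConfig(n_lines = 200, n_chrom = 2, snps_per_chrom = 15,
                     seed = 790 + s)
    g <- simulateGenotypes(cfg)
    M <- genoCodes(g)
    set.seed(890 + s)
    x <- M[, 5]
    beta_true <- sqrt(0.10) / sd(x)
    u <- as.numeric(M[, -(1:9)] %*% rnorm(ncol(M) - 9, 0, 1))
    u <- u / sd(u) * sqrt(0.40)
    yv <- setNames(beta_true * x + u + rnorm(200, 0, sqrt(0.50)),
                   lineIds(g))
    G <- kernelAdditive(g[, -(1:9)])
    dimnames(G) <- list(lineIds(g), lineIds(g))
    fx <- matrix(x, dimnames = list(lineIds(g), "qtl"))
    fit <- fitModel(data.frame(line = names(yv), env = "E1", value = yv),
                    list(main = G), fixed = fx,
                    chain = chainSettings(1500, 300, seed = 8))
    (fit$beta[["qtl"]] - beta_true) / beta_true
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.25)
})

test_that("cross-validation is deterministic and near zero for pure noise", {
  set.seed(80)
  lines <- sprintf("L%03d", 1:100)
  codes <- matrix(sample(c(1, -1), 100 * 40, replace = TRUE), 100,
                  dimnames = list(lines, NULL))
  G <- kernelAdditive(codes)
  dimnames(G) <- list(lines, lines)
  y <- data.frame(line = rep(lines, 2), env = rep(c("E1", "E2"), each = 100),
                  value = rnorm(200))
  cv1 <- crossValidate(y, list(main = G), repeats = 6, seed = 3,
                       chain = chainSettings(300, 100))
  cv2 <- crossValidate(y, list(main = G), repeats = 6, seed = 3,
                       chain = chainSettings(300, 100))
  expect_identical(cv1$accuracies, cv2$accuracies)
  # pure noise: mean accuracy within 2 / sqrt(n_test * repeats) of zero
  expect_lt(abs(cv1$mean), 2 / sqrt(10 * 6) + 0.15)
})

test_that("model comparison requires paired splits and recovers differences", {
  mk <- function(acc, hash = "h") structure(
    list(accuracies = acc, mean = mean(acc), sd = sd(acc),
         n_repeats = length(acc), splits_hash = hash,
         flags = character(length(acc))), class = "CVResult")
  base <- mk(c(0.40, 0.42, 0.38, 0.41))
  up <- mk(c(0.40, 0.42, 0.38, 0.41) + 0.05)
  tab <- compareModels(list(model1 = base, model2 = up))
  expect_equal(tab$diff_vs_base, c(0, 0.05), tolerance = 1e-12)
  expect_true(tab$exceeds_lsd[2])      # constant offset, zero paired sd
  same <- compareModels(list(a = base, b = base))
  expect_equal(same$diff_vs_base[2], 0)
  expect_false(same$exceeds_lsd[2])
  expect_error(compareModels(list(a = base, b = mk(base$accuracies, "other"))),
               "paired")
})

test_that("model-1 accuracy rises with heritability", {
  means <- vapply(c(0.15, 0.7), function(h2) {
    accs <- vapply(1:2, function(s) {
      cfg <- simConfig(n_lines = 120, n_chrom = 2, snps_per_chrom = 15,
                       n_envs = 2, gxe_ratio = 0.3, h2_target = h2,
                       seed = 810 + s)
      g <- simulateGenotypes(cfg)
      sim <- simulateTrials(g, cfg)
      adj <- adjustAllTrials(sim$records)
      ydf <- data.frame(line = adj$line, env = adj$env, value = adj$value)
      ks <- modelKernels(modelSpec(1), geno = g)
      crossValidate(ydf, ks, repeats = 4, seed = 5,
                    chain = chainSettings(400, 100))$mean
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  expect_gt(means[2], means[1])
})
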