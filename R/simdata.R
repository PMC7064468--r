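#' Simulation configuration for synthetic trial data
#'
#' Bundles every knob of the synthetic-data generator: genome layout
#' (chromosomes, SNPs, LD-block sizes, founder-haplotype pool), panel size,
#' trial structure (years x environments, replicates, incomplete blocks,
#' repeated checks) and the genetic architecture (additive QTL with
#' environment-specific effect patterns, two-locus epistasis, polygenic
#' background, genotype-by-environment deviations, target heritability).
#'
#' Defaults emulate a spring-wheat elite-yield-trial setting: five
#' contrasting environments (two irrigated, mild/severe drought, heat) with
#' means of roughly 7.0, 6.7, 3.9, 2.5 and 3.5 t/ha, three replications in
#' an alpha-lattice layout with two repeated checks, LD blocks of 2--9 SNPs,
#' and strong G x E.
#'
#' @param n_lines number of inbred (fully homozygous) lines.
#' @param n_chrom number of chromosomes.
#' @param snps_per_chrom SNPs per chromosome.
#' @param block_size_range length-2 integer vector: min/max SNPs per LD block.
#' @param founders_per_block size of the founder-haplotype pool per block
#'   (2--4 gives the strong within-block LD the block finder assumes).
#' @param maf_min minimum minor-allele frequency enforced on every simulated
#'   SNP by rejection sampling, in (0, 0.5).
#' @param missing_rate fraction of genotype calls masked at random.
#' @param n_years number of trial years (one elite-yield-trial cohort each).
#' @param n_envs number of environments per year.
#' @param env_means trait mean per environment (kg/ha), recycled to n_envs.
#' @param n_reps replicates per trial.
#' @param block_size_field entries per incomplete block (each block also
#'   receives one check plot).
#' @param n_checks number of repeated check entries (>= 2).
#' @param qtl_spec list of QTL, each \code{list(locus =, effects =, share =)}
#'   for a genotyped-SNP QTL (SNP index, per-environment effect pattern —
#'   recycled and scaled internally — and share of total genetic variance),
#'   or \code{list(block =, founder =, effects =, share =)} for a hidden
#'   causal variant carried by one founder haplotype of an LD block, which
#'   single markers tag only through LD.
#' @param epistasis_spec list of \code{list(loci = c(i, j), effect =)} with
#'   the interaction effect in trait units applied to the coded product.
#' @param poly_share share of genetic variance assigned to the polygenic term.
#' @param gxe_ratio sd of line-by-environment deviations relative to the
#'   total genetic sd (strong G x E by default).
#' @param gen_sd total genetic standard deviation in trait units (kg/ha).
#' @param rep_sd,block_sd_field standard deviations of replicate and
#'   incomplete-block effects (kg/ha).
#' @param h2_target target across-environment broad-sense heritability,
#'   strictly inside (0, 1).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return A validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(n_lines = 200, n_chrom = 3, snps_per_chrom = 40,
                      block_size_range = c(2L, 9L), founders_per_block = 3,
                      maf_min = 0.15, missing_rate = 0,
                      n_years = 1, n_envs = 5,
                      env_means = c(7000, 6700, 3900, 2500, 3500),
                      n_reps = 3, block_size_field = 6, n_checks = 2,
                      qtl_spec = list(), epistasis_spec = list(),
                      poly_share = NULL, gxe_ratio = 0.8, gen_sd = 400,
                      rep_sd = 100, block_sd_field = 200,
                      h2_target = 0.5, seed = 1L) {
  cfg <- list(n_lines = as.integer(n_lines), n_chrom = as.integer(n_chrom),
              snps_per_chrom = as.integer(snps_per_chrom),
              block_size_range = as.integer(block_size_range),
              founders_per_block = as.integer(founders_per_block),
              maf_min = maf_min, missing_rate = missing_rate,
              n_years = as.integer(n_years), n_envs = as.integer(n_envs),
              env_means = rep_len(env_means, n_envs),
              n_reps = as.integer(n_reps),
              block_size_field = as.integer(block_size_field),
              n_checks = as.integer(n_checks),
              qtl_spec = qtl_spec, epistasis_spec = epistasis_spec,
              poly_share = poly_share, gxe_ratio = gxe_ratio,
              gen_sd = gen_sd, rep_sd = rep_sd,
              block_sd_field = block_sd_field,
              h2_target = h2_target, seed = as.integer(seed))
  qtl_share <- sum(vapply(qtl_spec, function(q) q$share, numeric(1)))
  if (is.null(cfg$poly_share)) cfg$poly_share <- max(0, 1 - qtl_share)
  stopifnot(cfg$maf_min >= 0, cfg$maf_min < 0.5,
            all(c(cfg$n_lines, cfg$n_chrom, cfg$snps_per_chrom, cfg$n_years,
                  cfg$n_envs, cfg$n_reps, cfg$block_size_field) >= 1),
            cfg$n_checks >= 2,
            length(cfg$block_size_range) == 2,
            cfg$block_size_range[1] >= 2,
            cfg$block_size_range[1] <= cfg$block_size_range[2])
  if (qtl_share + cfg$poly_share > 1 + 1e-8)
    stop("variance shares (QTL + polygenic) must sum to <= 1")
  if (cfg$h2_target <= 0 || cfg$h2_target >= 1)
    stop("h2_target must lie strictly inside (0, 1)")
  class(cfg) <- "SimConfig"
  cfg
}

# deterministic per-stage seed derived from the global seed, kept < 2^31
stageSeed <- function(seed, stage) {
  offsets <- c(genotypes = 101L, trials = 211L, missing = 307L, split = 401L,
               chain = 503L)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else {
    on.exit(rm(".Random.seed", envir = .GlobalEnv))
  }
  set.seed(seed)
  expr
}

#' Simulate inbred genotypes with block-structured linkage disequilibrium
#'
#' Chromosomes are tiled with LD blocks whose sizes are drawn from
#' \code{cfg$block_size_range}. Within a block each line inherits one
#' haplotype from a small founder pool, giving strong within-block D';
#' founder assignment is independent across blocks, so between-block LD is
#' near zero. Every SNP is polymorphic across founders and blocks are
#' rejection-sampled until all SNP minor-allele frequencies reach
#' \code{cfg$maf_min}. Genotypes are fully homozygous, coded \{1, -1\}
#' (0 never occurs); optional missingness is injected uniformly at random.
#'
#' @param cfg a \code{\link{simConfig}} object.
#' @return A \linkS4class{SnpMatrix} with attribute \code{"block_truth"}: a
#'   data.frame of the generating block memberships (chrom, block serial,
#'   SNP indices).
#' @export
simulateGenotypes <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (cfg$founders_per_block < 2 && cfg$maf_min > 0)
    stop("impossible MAF constraint: a single founder haplotype per block ",
         "makes every SNP monomorphic; increase founders_per_block or set ",
         "maf_min = 0")
  withSeed(stageSeed(cfg$seed, "genotypes"), {
    n <- cfg$n_lines
    geno <- NULL; chrom <- character(0); pos <- integer(0)
    truth <- list(); founder_assign <- NULL
    for (ch in seq_len(cfg$n_chrom)) {
      done <- 0L; serial <- 0L; p_ch <- cfg$snps_per_chrom
      while (done < p_ch) {
        sizes <- seq(cfg$block_size_range[1], cfg$block_size_range[2])
        L <- sizes[sample.int(length(sizes), 1)]
        L <- min(L, p_ch - done)
        if (L < 1) break
        blk <- simulateBlock(n, L, cfg$founders_per_block, cfg$maf_min)
        serial <- serial + 1L
        truth[[length(truth) + 1L]] <-
          data.frame(chrom = as.character(ch), serial = serial,
                     start_idx = length(chrom) + 1L,
                     end_idx = length(chrom) + L)
        founder_assign <- cbind(founder_assign,
                                attr(blk, "founder") %||% rep(1L, n))
        geno <- cbind(geno, unclass(blk))
        chrom <- c(chrom, rep(as.character(ch), L))
        pos <- c(pos, (done + seq_len(L)) * 1000L)
        done <- done + L
      }
    }
    if (cfg$missing_rate > 0) {
      mask <- matrix(runif(length(geno)) < cfg$missing_rate, nrow(geno))
      geno[mask] <- NA
    }
    rownames(geno) <- sprintf("L%04d", seq_len(n))
    colnames(geno) <- sprintf("S%s_%d", chrom, pos)
    out <- SnpMatrix(geno, chrom, pos,
                     ref = rep("A", length(pos)), alt = rep("T", length(pos)))
    attr(out, "block_truth") <- do.call(rbind, truth)
    rownames(founder_assign) <- rownames(geno)
    attr(out, "founder_truth") <- founder_assign
    out
  })
}

# one LD block: founder haplotypes in {1,-1}, every SNP polymorphic across
# founders; lines sample a founder; rejection until all MAF >= maf_min
simulateBlock <- function(n, L, n_founder, maf_min, max_try = 500) {
  if (n_founder < 2) {
    # single-founder pool: monomorphic block (only legal when maf_min == 0)
    return(matrix(rep(sample(c(1, -1), L, replace = TRUE), each = n), n, L))
  }
  for (try in seq_len(max_try)) {
    founders <- matrix(sample(c(1, -1), n_founder * L, replace = TRUE),
                       n_founder, L)
    if (any(abs(colSums(founders)) == n_founder)) next  # monomorphic column
    w <- rgamma(n_founder, 5); w <- w / sum(w)
    idx <- sample.int(n_founder, n, replace = TRUE, prob = w)
    blk <- founders[idx, , drop = FALSE]
    maf <- pmin(colMeans(blk == 1), colMeans(blk == -1))
    if (all(maf >= maf_min)) return(structure(blk, founder = idx))
  }
  stop("impossible MAF constraint: could not reach maf_min = ", maf_min,
       " with ", n_founder, " founder haplotypes after ", max_try, " tries")
}

#' Simulate multi-environment trial phenotypes with known genetic truth
#'
#' Builds an alpha-lattice-style layout per trial (= year cohort x
#' environment): entries are randomised into incomplete blocks of
#' \code{cfg$block_size_field} entries within each replicate, and every
#' incomplete block additionally carries one plot of a repeated check
#' (checks alternate so each trial contains all checks). Plot values are
#'
#' \deqn{y = \mu_{env} + rep + block + g_{i,env} + \epsilon}
#'
#' where the genetic value \eqn{g_{i,env}} sums environment-specific
#' additive QTL effects, planted two-locus epistasis, a polygenic term and
#' a line-by-environment normal deviation. The residual variance is tuned
#' so the across-environment broad-sense heritability of entry means
#' matches \code{cfg$h2_target}. Checks are two designated entries with
#' fixed genetic values not driven by any QTL.
#'
#' @param geno a \linkS4class{SnpMatrix} from \code{\link{simulateGenotypes}}
#'   (QTL loci must be non-missing).
#' @param cfg the \code{\link{simConfig}} used.
#' @return list with \code{records} (tidy plot-level data.frame: line, eyt,
#'   env, rep, block, trait, value, is_check) and \code{truth} (QTL loci and
#'   per-env effects, epistatic pairs, polygenic values, realized per-env and
#'   across-env heritability, genetic values).
#' @export
simulateTrials <- function(geno, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (cfg$h2_target <= 0 || cfg$h2_target >= 1)
    stop("h2_target on the boundary {0,1} is rejected")
  M <- genoCodes(geno)
  n <- nrow(M); e <- cfg$n_envs; r <- cfg$n_reps
  # a QTL is either a genotyped SNP (locus = SNP index) or a hidden causal
  # variant carried by one founder haplotype of an LD block (block = block
  # index, founder = founder id): the latter is tagged only imperfectly by
  # single markers, the regime where haplotype models pay off
  is_hap <- vapply(cfg$qtl_spec, function(q) !is.null(q$block), logical(1))
  qtl_loci <- vapply(cfg$qtl_spec, function(q)
    as.integer(q$locus %||% NA_integer_), integer(1))
  fa <- attr(geno, "founder_truth")
  bt <- attr(geno, "block_truth")
  if (any(is_hap) && is.null(fa))
    stop("haplotype-level QTL need founder assignments from simulateGenotypes")
  if (length(qtl_loci[!is_hap]) && any(is.na(M[, qtl_loci[!is_hap]])))
    stop("genotypes must be complete at QTL loci")
  qtl_x <- matrix(0, n, length(cfg$qtl_spec))
  qtl_founder <- rep(NA_integer_, length(cfg$qtl_spec))
  for (k in seq_along(cfg$qtl_spec)) {
    q <- cfg$qtl_spec[[k]]
    if (is_hap[k]) {
      # the causal unit is a haplotype allele: the observed allele string
      # of the block's member SNPs (what callHaplotypes scores), carrying
      # a hidden variant. A string-class indicator is linear in the
      # member SNPs whenever the block's distinct strings are affinely
      # independent; haplotype-only signal therefore needs more common
      # string classes than SNPs + 1 (e.g. a 2-SNP block with all four
      # corner strings common).
      span <- bt$start_idx[q$block]:bt$end_idx[q$block]
      pat <- apply(M[, span, drop = FALSE], 1, paste, collapse = "/")
      if (!is.null(q$founder)) {
        fcol <- fa[, q$block]
        cls <- pat[match(q$founder, fcol)]
      } else {
        # default: the common string class least tagged by the member
        # SNPs jointly (multiple R2) — the missing-heritability regime
        cand <- names(which(table(pat) / n >= 0.05))
        tag <- vapply(cand, function(cl) {
          xf <- as.numeric(pat == cl)
          fit <- lm.fit(cbind(1, M[, span, drop = FALSE]), xf)
          1 - sum(fit$residuals^2) / sum((xf - mean(xf))^2)
        }, numeric(1))
        cls <- cand[which.min(tag)]
      }
      qtl_founder[k] <- match(cls, sort(unique(pat)))
      qtl_x[, k] <- as.numeric(pat == cls)
    } else {
      qtl_x[, k] <- M[, q$locus]
    }
  }
  withSeed(stageSeed(cfg$seed, "trials"), {
    VG <- cfg$gen_sd^2
    # additive env-specific QTL effects, scaled to the requested shares
    beta <- matrix(0, length(cfg$qtl_spec), e)
    for (k in seq_along(cfg$qtl_spec)) {
      q <- cfg$qtl_spec[[k]]
      w <- rep_len(q$effects, e)
      vx <- var(qtl_x[, k])
      if (vx < 1e-12) stop("QTL ", k, " is monomorphic")
      if (mean(w^2) > 0 && q$share > 0)
        beta[k, ] <- w * sqrt(q$share * VG / (vx * mean(w^2)))
    }
    g_add <- matrix(0, n, e)
    for (k in seq_len(ncol(qtl_x)))
      g_add <- g_add + outer(qtl_x[, k], beta[k, ])
    g_epi <- numeric(n)
    for (ep in cfg$epistasis_spec)
      g_epi <- g_epi + ep$effect * M[, ep$loci[1]] * M[, ep$loci[2]]
    # polygenic term is marker-driven (u = Mc a, iid normal marker effects)
    # so that genomic kernels can capture it; markers in a block that hosts
    # a planted QTL are excluded to keep the planted shares interpretable
    excl <- integer(0)
    for (k in seq_along(cfg$qtl_spec)) {
      q <- cfg$qtl_spec[[k]]
      if (is.null(bt)) { excl <- c(excl, qtl_loci[k]); next }
      hit <- if (is_hap[k]) seq_len(nrow(bt)) == q$block
             else bt$start_idx <= qtl_loci[k] & bt$end_idx >= qtl_loci[k]
      excl <- c(excl, unlist(mapply(seq, bt$start_idx[hit],
                                    bt$end_idx[hit], SIMPLIFY = FALSE)))
    }
    excl <- excl[!is.na(excl)]
    basis <- setdiff(seq_len(ncol(M)), excl)
    if (length(basis) && cfg$poly_share > 0) {
      Mc <- M[, basis, drop = FALSE]
      cm <- colMeans(Mc, na.rm = TRUE)
      idx <- which(is.na(Mc))
      if (length(idx)) Mc[idx] <- cm[(idx - 1) %/% nrow(Mc) + 1]
      u <- as.numeric(Mc %*% rnorm(length(basis)))
      su <- sd(u)
      u <- if (su > 0) u / su * sqrt(cfg$poly_share * VG) else
           rnorm(n, 0, sqrt(cfg$poly_share * VG))
    } else u <- rnorm(n, 0, sqrt(cfg$poly_share * VG))
    dev <- matrix(rnorm(n * e, 0, cfg$gxe_ratio * cfg$gen_sd), n, e)
    G <- g_add + g_epi + u + dev           # line x env genetic values
    rownames(G) <- rownames(M)
    # realized components on the two-way line x env decomposition
    gm <- rowMeans(G)
    sigG2 <- var(gm)
    sigGE2 <- mean((G - outer(gm, rep(1, e)) -
                    outer(rep(1, n), colMeans(G)) + mean(G))^2) * n * e /
              ((n - 1) * (e - 1))
    h2 <- cfg$h2_target
    sigE2 <- max(e * r * sigG2 * (1 - h2) / h2 - r * sigGE2, 1e-6 * VG)
    # checks: fixed genetic values, evenly spread around zero
    chk_val <- seq(-1, 1, length.out = cfg$n_checks) * cfg$gen_sd / 2
    chk_ids <- sprintf("CHK%d", seq_len(cfg$n_checks))
    line_ids <- rownames(M)
    recs <- vector("list", cfg$n_years * e)
    ri <- 0
    env_names <- if (e == 5) c("B-5IR", "F-5IR", "B-2IR", "SD", "HS")
                 else sprintf("ENV%d", seq_len(e))
    n_blk <- ceiling(n / cfg$block_size_field)
    for (yr in seq_len(cfg$n_years)) {
      eyt <- sprintf("EYT%d", yr)
      for (ev in seq_len(e)) {
        mu <- cfg$env_means[ev]
        rep_eff <- rnorm(r, 0, cfg$rep_sd)
        per_rep <- vector("list", r)
        for (rp in seq_len(r)) {
          ord <- sample.int(n)
          blk_of <- rep(seq_len(n_blk), each = cfg$block_size_field)[1:n]
          blk_eff <- rnorm(n_blk, 0, cfg$block_sd_field)
          entry_y <- mu + rep_eff[rp] + blk_eff[blk_of] + G[ord, ev] +
                     rnorm(n, 0, sqrt(sigE2))
          # one check plot per incomplete block, alternating check entries
          chk_idx <- ((seq_len(n_blk) - 1L + rp) %% cfg$n_checks) + 1L
          chk_y <- mu + rep_eff[rp] + blk_eff + chk_val[chk_idx] +
                   rnorm(n_blk, 0, sqrt(sigE2))
          per_rep[[rp]] <- data.frame(
            line = c(line_ids[ord], chk_ids[chk_idx]),
            eyt = eyt, env = env_names[ev], rep = rp,
            block = c(blk_of, seq_len(n_blk)), trait = "GY",
            value = c(entry_y, chk_y),
            is_check = rep(c(FALSE, TRUE), c(n, n_blk)))
        }
        ri <- ri + 1
        recs[[ri]] <- do.call(rbind, per_rep)
      }
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    h2_env <- vapply(seq_len(e), function(ev)
      var(G[, ev]) / (var(G[, ev]) + sigE2), numeric(1))
    H2 <- sigG2 / (sigG2 + sigGE2 / e + sigE2 / (e * r))
    truth <- list(qtl_loci = qtl_loci, qtl_is_hap = is_hap,
                  qtl_founder = qtl_founder,
                  qtl_scores = qtl_x, qtl_effects = beta,
                  epistatic_pairs = cfg$epistasis_spec,
                  polygenic_values = setNames(u, line_ids),
                  genetic_values = G, sigma2_e = sigE2,
                  realized_h2 = h2_env, realized_H2_across = H2,
                  check_values = setNames(chk_val, chk_ids))
    stopifnot(all(is.finite(unlist(truth$qtl_effects))),
              all(is.na(qtl_loci) |
                  (qtl_loci >= 1 & qtl_loci <= ncol(M))))
    list(records = records, truth = truth)
  })
}

#' Validate a plot-level phenotype records data.frame
#'
#' Checks the tidy plot-record contract used throughout the package: the
#' required columns are present, every (eyt, env) trial contains at least
#' two distinct check lines, and values are finite or NA.
#'
#' @param records data.frame with columns line, eyt, env, rep, block, trait,
#'   value, is_check.
#' @return the records, invisibly, or an error describing the violation.
#' @export
validatePhenoRecords <- function(records) {
  need <- c("line", "eyt", "env", "rep", "block", "trait", "value", "is_check")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(is.infinite(records$value))) stop("non-finite trait values present")
  tr <- unique(records[, c("eyt", "env")])
  for (i in seq_len(nrow(tr))) {
    sub <- records[records$eyt == tr$eyt[i] & records$env == tr$env[i], ]
    if (length(unique(sub$line[sub$is_check])) < 2)
      stop(sprintf("trial (%s, %s) has fewer than 2 distinct check lines",
                   tr$eyt[i], tr$env[i]))
  }
  invisible(records)
}
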