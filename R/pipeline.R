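#' Validate pipeline input files
#'
#' Schema checks for the pipeline inputs: the VCF must be biallelic with
#' positions sorted within chromosome; the phenotype CSV must carry the
#' tidy plot-record columns and at least two distinct checks per trial.
#' Messages are collected into an itemised report rather than failing at
#' the first problem.
#'
#' @param geno_path VCF file (optional, NULL to skip).
#' @param pheno_path phenotype CSV (optional).
#' @return character vector of problems (empty when everything is clean),
#'   with attribute \code{"ok"}.
#' @export
validateInputs <- function(geno_path = NULL, pheno_path = NULL) {
  problems <- character(0)
  if (!is.null(geno_path)) {
    if (!file.exists(geno_path)) {
      problems <- c(problems, sprintf("genotype file not found: %s", geno_path))
    } else {
      fix <- try(vcfR::getFIX(vcfR::read.vcfR(geno_path, verbose = FALSE)),
                 silent = TRUE)
      if (inherits(fix, "try-error")) {
        problems <- c(problems, sprintf("genotype file unreadable: %s",
                                        conditionMessage(attr(fix, "condition"))))
      } else {
        multi <- grepl(",", fix[, "ALT"])
        if (any(multi))
          problems <- c(problems,
            sprintf("multi-allelic record at %s:%s",
                    fix[multi, "CHROM"][1], fix[multi, "POS"][1]))
        for (ch in unique(fix[, "CHROM"])) {
          p <- as.integer(fix[fix[, "CHROM"] == ch, "POS"])
          if (is.unsorted(p)) {
            first <- which(diff(p) < 0)[1] + 1
            problems <- c(problems,
              sprintf("unsorted VCF: chromosome %s, record %d (pos %d)",
                      ch, first, p[first]))
          }
        }
      }
    }
  }
  if (!is.null(pheno_path)) {
    if (!file.exists(pheno_path)) {
      problems <- c(problems, sprintf("phenotype file not found: %s", pheno_path))
    } else {
      ph <- try(utils::read.csv(pheno_path), silent = TRUE)
      if (inherits(ph, "try-error")) {
        problems <- c(problems, "phenotype file unreadable")
      } else {
        v <- try(validatePhenoRecords(ph), silent = TRUE)
        if (inherits(v, "try-error"))
          problems <- c(problems,
                        conditionMessage(attr(v, "condition")))
      }
    }
  }
  structure(problems, ok = length(problems) == 0)
}

#' Run the full synthetic-to-prediction pipeline
#'
#' Executes the stages in dependency order — simulate genotypes and
#' trials, adjust plot data, stability indices, SNP filtering, haplotype
#' blocks and calls, kinship, SNP and haplotype association scans,
#' epistasis scan, and four-model cross-validated genomic prediction —
#' writing per-stage outputs under \code{out_dir} and returning a run
#' manifest. A single global seed fans out to a named substream per
#' stage, so inserting a stage never perturbs the randomness of the
#' others. Reruns with the same config are bit-identical.
#'
#' @param config list (or path to a YAML file) with optional entries:
#'   \code{sim} (arguments to \code{\link{simConfig}}), \code{stages}
#'   (character subset of the stage names to run), \code{cv}
#'   (repeats, test_frac, chain_iter, chain_burn), \code{assoc}
#'   (p_threshold), \code{seed}.
#' @param out_dir output directory (created if needed).
#' @return manifest list: per-stage output paths, seeds, summary numbers.
#' @export
runPipeline <- function(config = list(), out_dir = tempfile("hapmet_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% c("simulate", "adjust", "stability",
                                 "blocks", "gwas", "epistasis", "predict",
                                 "compare")
  manifest <- list(seed = seed, out_dir = out_dir, stages = list())
  cfg <- do.call(simConfig, c(config$sim %||% list(), list(seed = seed)))
  stage <- function(name, expr) {
    if (!(name %in% stages)) return(NULL)
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- res
    res
  }
  geno <- NULL; sim <- NULL
  stage("simulate", {
    geno <- simulateGenotypes(cfg)
    sim <- simulateTrials(geno, cfg)
    writeVcf(geno, file.path(out_dir, "genotypes.vcf"))
    utils::write.csv(sim$records, file.path(out_dir, "phenotypes.csv"),
                     row.names = FALSE)
    writeTruth(sim$truth, file.path(out_dir, "truth.json"))
    list(files = c("genotypes.vcf", "phenotypes.csv", "truth.json"),
         n_lines = nLines(geno), n_snps = nSnps(geno))
  })
  trials <- unique(sim$records[, c("eyt", "env")])
  adj <- NULL
  stage("adjust", {
    adj <- do.call(rbind, lapply(seq_len(nrow(trials)), function(i)
      adjustBlockEffects(sim$records, trials$eyt[i], trials$env[i])))
    utils::write.csv(adj, file.path(out_dir, "adjusted_means.csv"),
                     row.names = FALSE)
    h2 <- vapply(unique(trials$eyt), function(ey)
      as.numeric(broadSenseH2(sim$records[sim$records$eyt == ey, ])),
      numeric(1))
    list(files = "adjusted_means.csv", h2 = h2)
  })
  stage("stability", {
    res <- lapply(unique(adj$eyt), function(ey) {
      a <- adj[adj$eyt == ey, ]
      pi_r <- superiorityIndex(a)
      if (length(unique(a$env)) >= 3) {        # ER needs >= 3 environments
        er_r <- eberhartRussell(a)
        pi_r <- merge(pi_r, er_r[, c("line", "ER_slope", "ER_dev")],
                      by = "line")
      }
      cbind(eyt = ey, pi_r)
    })
    res <- do.call(rbind, res)
    utils::write.csv(res, file.path(out_dir, "stability.csv"),
                     row.names = FALSE)
    list(files = "stability.csv", n = nrow(res))
  })
  filt <- NULL; blocks <- NULL; H <- NULL
  stage("blocks", {
    filt <- filterSnps(geno)
    blocks <- buildBlocks(filt)
    H <- callHaplotypes(filt, blocks)
    writeBlocks(blocks, file.path(out_dir, "blocks.tsv"))
    list(files = "blocks.tsv", n_blocks = nrow(blocks),
         n_haplotypes = ncol(hapIncidence(H)))
  })
  scan <- NULL
  stage("gwas", {
    K <- vanRadenKinship(filt)
    res <- list()
    for (i in seq_len(nrow(trials))) {
      a <- adj[adj$eyt == trials$eyt[i] & adj$env == trials$env[i], ]
      yv <- setNames(a$value, a$line)
      s <- mlmScanSnp(yv, filt, K)
      res[[i]] <- data.frame(locus = s$snp, eyt = trials$eyt[i],
                             env = trials$env[i], p = s$p, R2 = s$R2)
    }
    scan <- do.call(rbind, res)
    groups <- classifyGroups(scan, config$assoc$p_threshold %||% NULL)
    utils::write.table(scan, file.path(out_dir, "gwas.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(files = "gwas.tsv", n_sig_loci = nrow(groups))
  })
  stage("epistasis", {
    a <- adj[adj$eyt == trials$eyt[1] & adj$env == trials$env[1], ]
    yv <- setNames(a$value, a$line)
    # one representative SNP per generating block keeps the tuple count small
    reps <- if (nrow(blocks)) blocks$first else seq_len(min(nSnps(filt), 20))
    er <- interactionScan(yv, filt[, reps], order = 2)
    utils::write.table(er, file.path(out_dir, "epistasis.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(files = "epistasis.tsv", n_sig = nrow(er),
         n_tuples = attr(er, "n_tuples"))
  })
  cvres <- NULL
  stage("predict", {
    cvcfg <- config$cv %||% list()
    repeats <- cvcfg$repeats %||% 10
    ch <- chainSettings(cvcfg$chain_iter %||% 800,
                        cvcfg$chain_burn %||% 200, seed)
    ey1 <- trials$eyt[1]
    a <- adj[adj$eyt == ey1, ]
    ydf <- data.frame(line = a$line, env = a$env, value = a$value)
    k1 <- modelKernels(modelSpec(1), geno = filt)
    k2 <- modelKernels(modelSpec(2), H = H)
    cvres <- list(
      model1 = crossValidate(ydf, k1, repeats = repeats, seed = seed,
                             chain = ch),
      model2 = crossValidate(ydf, k2, repeats = repeats, seed = seed,
                             chain = ch))
    list(mean_accuracy = vapply(cvres, function(r) r$mean, numeric(1)))
  })
  stage("compare", {
    tab <- compareModels(cvres)
    utils::write.table(tab, file.path(out_dir, "model_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(files = "model_comparison.tsv",
         best = tab$model[which.max(tab$mean)])
  })
  manifest$n_stages <- length(manifest$stages)
  manifest
}
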