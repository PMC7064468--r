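# Small in-code fixture builders shared across test files.

# SnpMatrix from a plain code matrix, single chromosome unless given
makeSnp <- function(codes, chrom = NULL, pos = NULL) {
  codes <- as.matrix(codes)
  if (is.null(chrom)) chrom <- rep("1", ncol(codes))
  if (is.null(pos)) pos <- seq_len(ncol(codes)) * 100L
  SnpMatrix(codes, chrom = chrom, pos = pos,
            ref = rep("A", ncol(codes)), alt = rep("T", ncol(codes)))
}

# inbred codes: n lines drawn from founder haplotypes (rows of `founders`)
makeFounderPanel <- function(n, founders, prob = NULL, seed = 1) {
  idx <- withr::with_seed(seed,
    sample.int(nrow(founders), n, replace = TRUE, prob = prob))
  founders[idx, , drop = FALSE]
}

# minimal plot-record table for one trial: values indexed [rep, block, entry]
makeTrialRecords <- function(entry_vals, check_vals, eyt = "EYT1",
                             env = "E1", trait = "GY") {
  # entry_vals: list over reps of list over blocks of named entry vectors
  # check_vals: same shape, named check vectors
  rows <- list()
  for (rp in seq_along(entry_vals)) {
    for (bk in seq_along(entry_vals[[rp]])) {
      ev <- entry_vals[[rp]][[bk]]; cv <- check_vals[[rp]][[bk]]
      rows[[length(rows) + 1]] <- data.frame(
        line = c(names(ev), names(cv)), eyt = eyt, env = env, rep = rp,
        block = bk, trait = trait, value = c(ev, cv),
        is_check = rep(c(FALSE, TRUE), c(length(ev), length(cv))))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# adjusted means for all trials of one simulated cohort
adjustAllTrials <- function(records, eyt = "EYT1") {
  envs <- unique(records$env[records$eyt == eyt])
  do.call(rbind, lapply(envs, function(e)
    adjustBlockEffects(records, eyt, e)))
}
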