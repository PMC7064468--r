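#' Check-based adjustment of grain yield for incomplete-block effects
#'
#' Moving-check adjustment of plot-level yield within one trial: for every
#' incomplete block inside each replicate, the deviation of the block's
#' check mean from the trial-wide check mean is subtracted from all entry
#' plots in that block, and the per-line mean over replicates is returned.
#' When check values do not differ between blocks the adjustment is the
#' identity and the result is the raw replicate mean.
#'
#' @param records tidy plot-level records (see
#'   \code{\link{validatePhenoRecords}}).
#' @param eyt,env identify the trial to adjust.
#' @param trait trait name, default \code{"GY"}.
#' @return data.frame with columns line, eyt, env, value (adjusted mean over
#'   replicates); check entries are excluded from the output.
#' @export
adjustBlockEffects <- function(records, eyt, env, trait = "GY") {
  sub <- records[records$eyt == eyt & records$env == env &
                 records$trait == trait, ]
  if (!nrow(sub)) stop(sprintf("no records for trial (%s, %s)", eyt, env))
  chk <- sub[sub$is_check & !is.na(sub$value), ]
  if (!nrow(chk)) stop(sprintf("trial (%s, %s) has no check plots", eyt, env))
  trial_chk_mean <- mean(chk$value)
  adj <- sub
  for (rp in unique(sub$rep)) {
    for (bk in unique(sub$block[sub$rep == rp])) {
      sel <- sub$rep == rp & sub$block == bk
      csel <- sel & sub$is_check & !is.na(sub$value)
      if (!any(csel))
        stop(sprintf("block %s in replicate %s of trial (%s, %s) contains no check plot",
                     bk, rp, eyt, env))
      adj$value[sel] <- sub$value[sel] - (mean(sub$value[csel]) - trial_chk_mean)
    }
  }
  ent <- adj[!adj$is_check, ]
  agg <- tapply(ent$value, ent$line, mean, na.rm = TRUE)
  data.frame(line = names(agg), eyt = eyt, env = env,
             value = as.numeric(agg), row.names = NULL)
}

#' Check-mean adjustment for covariate traits across trials
#'
#' Puts a covariate trait (days to heading, plant height) measured in many
#' trials on a common scale: \eqn{Y = (Y_{ij} - Y_i) + Y_{all}}, where
#' \eqn{Y_{ij}} is the entry value in a trial, \eqn{Y_i} the mean of that
#' trial's checks and \eqn{Y_{all}} the mean of checks over all trials.
#' With a single trial the output equals the input.
#'
#' @param records tidy plot-level records.
#' @param trait covariate trait name (\code{"DH"} or \code{"PH"}).
#' @return data.frame line, eyt, env, value with the adjusted entry means.
#' @export
adjustCovariateMeans <- function(records, trait) {
  sub <- records[records$trait == trait, ]
  if (!nrow(sub)) stop("no records for trait ", trait)
  chk <- sub[sub$is_check & !is.na(sub$value), ]
  if (!nrow(chk)) stop("no check plots for trait ", trait)
  y_all <- mean(chk$value)
  key <- interaction(sub$eyt, sub$env, drop = TRUE)
  out <- lapply(levels(key), function(k) {
    tr <- sub[key == k, ]
    ck <- tr[tr$is_check & !is.na(tr$value), ]
    if (!nrow(ck)) stop("trial ", k, " has no checks for trait ", trait)
    y_i <- mean(ck$value)
    ent <- tr[!tr$is_check, ]
    agg <- tapply(ent$value, ent$line, mean, na.rm = TRUE)
    data.frame(line = names(agg), eyt = tr$eyt[1], env = tr$env[1],
               value = as.numeric(agg) - y_i + y_all, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Reshape adjusted per-trial means into a line x trial matrix
#'
#' @param adj data.frame line/eyt/env/value as returned by the adjustment
#'   operators (rows from several trials may be concatenated).
#' @return numeric matrix lines x trials with dimnames; attribute
#'   \code{"trials"} holds the (eyt, env) metadata per column.
#' @export
adjMeansMatrix <- function(adj) {
  trial <- paste(adj$eyt, adj$env, sep = ":")
  lines <- sort(unique(adj$line)); trials <- unique(trial)
  m <- matrix(NA_real_, length(lines), length(trials),
              dimnames = list(lines, trials))
  m[cbind(match(adj$line, lines), match(trial, trials))] <- adj$value
  attr(m, "trials") <- data.frame(
    trial = trials,
    eyt = sub(":.*$", "", trials),
    env = sub("^[^:]*:", "", trials))
  m
}

#' Factorial ANOVA of plot-level yield across environments
#'
#' Fixed-effects least-squares ANOVA of plot values within one year cohort
#' with terms Rep, Geno, Env and Geno:Env, each tested against the single
#' residual mean square.
#'
#' @param records tidy plot-level records for one EYT (checks excluded
#'   automatically); must have >= 2 levels of every factor.
#' @param trait trait name.
#' @return data.frame rows Rep, Geno, Env, Geno:Env, Residuals with columns
#'   Df, Sum Sq, Mean Sq, F value, Pr(>F).
#' @export
anovaFactorial <- function(records, trait = "GY") {
  d <- records[records$trait == trait & !records$is_check &
               !is.na(records$value), ]
  d$line <- factor(d$line); d$env <- factor(d$env); d$rep <- factor(d$rep)
  for (f in c("line", "env", "rep"))
    if (nlevels(d[[f]]) < 2) stop("factor ", f, " has fewer than 2 levels")
  fit <- aov(value ~ rep + line + env + line:env, data = d)
  tab <- summary(fit)[[1]]
  rownames(tab) <- trimws(rownames(tab))
  map <- c(rep = "Rep", line = "Geno", env = "Env", `line:env` = "Geno:Env",
           Residuals = "Residuals")
  rownames(tab) <- map[rownames(tab)]
  as.data.frame(tab[c("Rep", "Geno", "Env", "Geno:Env", "Residuals"), ])
}

#' Broad-sense heritability across environments
#'
#' Entry-mean broad-sense heritability from the expected mean squares of
#' \code{\link{anovaFactorial}}:
#' \deqn{H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{GE}/e +
#'   \sigma^2_\epsilon/(e r))}
#' with \eqn{\sigma^2_G = (MS_G - MS_{GE})/(re)},
#' \eqn{\sigma^2_{GE} = (MS_{GE} - MS_\epsilon)/r} and e environments,
#' r replicates. Negative component estimates are clipped at zero with a
#' warning; the result is clipped to [0, 1].
#'
#' @param records tidy plot-level records for one EYT.
#' @param trait trait name.
#' @return heritability in [0, 1], with attribute \code{"components"}.
#' @export
broadSenseH2 <- function(records, trait = "GY") {
  d <- records[records$trait == trait & !records$is_check, ]
  e <- length(unique(d$env)); r <- length(unique(d$rep))
  if (e < 2 || r < 2) stop("need >= 2 environments and >= 2 replicates")
  tab <- anovaFactorial(records, trait)
  msG <- tab["Geno", "Mean Sq"]; msGE <- tab["Geno:Env", "Mean Sq"]
  msE <- tab["Residuals", "Mean Sq"]
  sG2 <- (msG - msGE) / (r * e); sGE2 <- (msGE - msE) / r
  if (sG2 < 0 || sGE2 < 0)
    warning("negative variance-component estimate clipped at 0")
  sG2 <- max(sG2, 0); sGE2 <- max(sGE2, 0)
  h2 <- sG2 / (sG2 + sGE2 / e + msE / (e * r))
  h2 <- min(max(h2, 0), 1)
  attr(h2, "components") <- c(sigma2_G = sG2, sigma2_GE = sGE2,
                              sigma2_e = msE)
  h2
}
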