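#' Two- and three-locus epistatic interaction scan
#'
#' Ordinary-least-squares scan of adjusted entry means over locus tuples:
#' for each pair (or triple) the full model with main effects and the
#' highest-order interaction term is compared by F-test against the model
#' without that term. For order 3 all main effects and two-way products
#' are included, so the test isolates the three-way signal. The additional
#' variance explained is the sequential \eqn{\Delta R^2 = R^2_{full} -
#' R^2_{mains}} (mains fitted first). Tuples with any genotype-combination
#' cell count below \code{min_cell} are skipped with a reason.
#'
#' Scores may be SNP codes (a \linkS4class{SnpMatrix} or numeric matrix) or
#' haplotype incidence columns pruned to one score per block.
#'
#' @param y named numeric vector of adjusted means.
#' @param scores numeric matrix (lines x loci) of locus scores, or a
#'   \linkS4class{SnpMatrix}.
#' @param order 2 or 3.
#' @param p_cut report tuples with interaction p below this (default 0.001).
#' @param pairs optional integer matrix (rows = tuples) restricting the
#'   scan; default all \eqn{\binom{L}{order}} tuples.
#' @param min_cell minimum observations per genotype combination.
#' @return data.frame loci (comma-joined ids), p, deltaR2 for reported
#'   tuples; attribute \code{"skipped"} counts tuples skipped for sparse
#'   cells, attribute \code{"n_tested"} the number of tuples tested.
#' @export
interactionScan <- function(y, scores, order = 2, p_cut = 0.001,
                            pairs = NULL, min_cell = 5) {
  stopifnot(order %in% c(2, 3))
  S <- if (is(scores, "SnpMatrix")) genoCodes(scores) else as.matrix(scores)
  ids <- intersect(names(y), rownames(S))
  yv <- y[ids]; S <- S[ids, , drop = FALSE]
  L <- ncol(S)
  lab <- colnames(S)
  if (is.null(lab)) lab <- paste0("locus", seq_len(L))
  if (is.null(pairs)) {
    pairs <- t(utils::combn(L, order))
  }
  n <- length(yv)
  rows <- list(); skipped <- 0L; tested <- 0L
  if (sd(yv) < 1e-12)
    return(structure(data.frame(loci = character(0), p = numeric(0),
                                deltaR2 = numeric(0)),
                     skipped = 0L, n_tested = 0L, n_tuples = nrow(pairs)))
  sstot <- sum((yv - mean(yv))^2)
  for (r in seq_len(nrow(pairs))) {
    tup <- pairs[r, ]
    Xm <- S[, tup, drop = FALSE]
    cc <- complete.cases(Xm)
    Xm <- Xm[cc, , drop = FALSE]; yy <- yv[cc]
    cell <- table(apply(Xm, 1, paste, collapse = "/"))
    if (any(cell < min_cell)) { skipped <- skipped + 1L; next }
    tested <- tested + 1L
    if (order == 2) {
      Xmain <- cbind(1, Xm)
      Xfull <- cbind(Xmain, Xm[, 1] * Xm[, 2])
    } else {
      Xmain <- cbind(1, Xm, Xm[, 1] * Xm[, 2], Xm[, 1] * Xm[, 3],
                     Xm[, 2] * Xm[, 3])
      Xfull <- cbind(Xmain, Xm[, 1] * Xm[, 2] * Xm[, 3])
    }
    q0 <- qr(Xmain); q1 <- qr(Xfull)
    rss0 <- sum(qr.resid(q0, yy)^2)
    rss1 <- sum(qr.resid(q1, yy)^2)
    df1 <- q1$rank - q0$rank
    df2 <- length(yy) - q1$rank
    if (df1 < 1 || df2 < 1) { skipped <- skipped + 1L; next }
    Fst <- ((rss0 - rss1) / df1) / (rss1 / df2)
    p <- pf(Fst, df1, df2, lower.tail = FALSE)
    if (p < p_cut) {
      ss0 <- sum((yy - mean(yy))^2)
      rows[[length(rows) + 1L]] <- data.frame(
        loci = paste(lab[tup], collapse = ","),
        p = p, deltaR2 = max((rss0 - rss1) / ss0, 0))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(loci = character(0), p = numeric(0),
                         deltaR2 = numeric(0))
  structure(out, skipped = skipped, n_tested = tested,
            n_tuples = nrow(pairs))
}

#' Summarise epistatic variance per trial
#'
#' Mean and range of the additional variance (\code{deltaR2}) explained by
#' significant interaction tuples, per trial.
#'
#' @param results data.frame from \code{\link{interactionScan}} with an
#'   optional \code{trial} column (a single unnamed trial otherwise).
#' @return data.frame trial, n, mean_deltaR2, min_deltaR2, max_deltaR2;
#'   zero rows for empty input.
#' @export
epistaticVarianceSummary <- function(results) {
  if (!nrow(results))
    return(data.frame(trial = character(0), n = integer(0),
                      mean_deltaR2 = numeric(0), min_deltaR2 = numeric(0),
                      max_deltaR2 = numeric(0)))
  if (is.null(results$trial)) results$trial <- "all"
  out <- lapply(split(results, results$trial), function(s)
    data.frame(trial = s$trial[1], n = nrow(s),
               mean_deltaR2 = mean(s$deltaR2),
               min_deltaR2 = min(s$deltaR2),
               max_deltaR2 = max(s$deltaR2)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
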