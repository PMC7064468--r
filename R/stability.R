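#' Lin-Binns superiority index
#'
#' \eqn{P_i = \sum_j (X_{ij} - M_j)^2 / (2E)}, where \eqn{X_{ij}} is line
#' i's adjusted mean in environment j, \eqn{M_j} the maximum over lines in
#' that environment and E the number of environments. Low Pi marks lines
#' that are both high-yielding and stable; Pi = 0 exactly when the line
#' attains the environment maximum everywhere. The denominator 2E follows
#' Lin & Binns (1988); note that variants with 2(E-1) exist in the
#' literature.
#'
#' Lines missing in some environments are scored over the available ones
#' with E reduced accordingly and flagged in the output.
#'
#' @param adj line x environment matrix of adjusted means for one year
#'   cohort (see \code{\link{adjMeansMatrix}}), or a data.frame
#'   line/eyt/env/value restricted to one cohort.
#' @return data.frame line, Pi, mean_gy, n_env, incomplete.
#' @export
superiorityIndex <- function(adj) {
  X <- asEnvMatrix(adj)
  if (ncol(X) < 2) stop("need >= 2 environments")
  Mj <- apply(X, 2, max, na.rm = TRUE)
  dev2 <- sweep(X, 2, Mj)^2
  E_i <- rowSums(!is.na(X))
  pi_i <- rowSums(dev2, na.rm = TRUE) / (2 * E_i)
  data.frame(line = rownames(X), Pi = pi_i,
             mean_gy = rowMeans(X, na.rm = TRUE), n_env = E_i,
             incomplete = E_i < ncol(X), row.names = NULL)
}

#' Eberhart-Russell stability regression
#'
#' Regresses each line's adjusted means on the environmental index
#' \eqn{I_j} (environment mean over lines minus grand mean): the slope
#' \eqn{b_i = \sum_j X_{ij} I_j / \sum_j I_j^2} is the stability
#' coefficient (b = 1 denotes average stability) and the mean squared
#' deviation from the fitted regression is returned as \code{ER_dev}.
#'
#' @param adj as in \code{\link{superiorityIndex}}; needs >= 3 environments.
#' @return data.frame line, ER_slope, ER_dev, mean_gy.
#' @export
eberhartRussell <- function(adj) {
  X <- asEnvMatrix(adj)
  if (ncol(X) < 3) stop("need >= 3 environments")
  I_j <- colMeans(X, na.rm = TRUE) - mean(colMeans(X, na.rm = TRUE))
  if (sum(I_j^2) < 1e-12)
    stop("environmental index identically zero; slope undefined")
  b <- as.numeric((X %*% I_j) / sum(I_j^2))
  fitted <- rowMeans(X) + outer(b, I_j)
  dev <- rowMeans((X - fitted)^2)
  data.frame(line = rownames(X), ER_slope = b, ER_dev = dev,
             mean_gy = rowMeans(X), row.names = NULL)
}

#' Correlation of stability indices with mean yield
#'
#' Pearson correlations of mean yield with -Pi (sign flipped so that
#' positive correlation means "high yielders are also stable/superior")
#' and with the Eberhart-Russell slope. Degenerate inputs (zero variance
#' in an index or fewer than 3 lines) yield an NA with a flag.
#'
#' @param pi_res output of \code{\link{superiorityIndex}}.
#' @param er_res output of \code{\link{eberhartRussell}} (optional).
#' @return data.frame index, cor, flag; sign conventions in column
#'   \code{note}.
#' @export
stabilityVsMean <- function(pi_res, er_res = NULL) {
  corOr <- function(x, y) {
    if (length(x) < 2 || sd(x) < 1e-12 || sd(y) < 1e-12)
      return(c(NA_real_, TRUE))
    c(cor(x, y), FALSE)
  }
  rows <- list()
  p <- corOr(-pi_res$Pi, pi_res$mean_gy)
  rows[[1]] <- data.frame(index = "Pi", cor = p[1], degenerate = as.logical(p[2]),
                          note = "cor(mean GY, -Pi): positive = stable high yielders")
  if (!is.null(er_res)) {
    q <- corOr(er_res$ER_slope, er_res$mean_gy)
    rows[[2]] <- data.frame(index = "ER", cor = q[1], degenerate = as.logical(q[2]),
                            note = "cor(mean GY, ER slope)")
  }
  do.call(rbind, rows)
}

# accept either a line x env matrix or tidy line/env/value rows
asEnvMatrix <- function(adj) {
  if (is.matrix(adj)) return(adj)
  stopifnot(all(c("line", "env", "value") %in% names(adj)))
  lines <- unique(adj$line); envs <- unique(adj$env)
  X <- matrix(NA_real_, length(lines), length(envs),
              dimnames = list(lines, envs))
  X[cbind(match(adj$line, lines), match(adj$env, envs))] <- adj$value
  X
}
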