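## Normal distribution model (NORM) imputation.
##
## Each genotype-attribute vector across environments is modelled as iid
## N(mu_ik, sigma2_ik); the environment effects have already been removed by
## column standardization, so a common scalar mean is appropriate. Missing
## cells and wholly missing columns are treated identically (a missing column
## contributes one missing entry to each of the I vectors).

#' Fit the NORM parameters for one genotype-attribute vector
#'
#' \code{normMLE} computes the maximum-likelihood estimates: the observed-entry
#' mean, and the mean squared deviation (divisor the observed count, not
#' \eqn{n - 1}). \code{normGibbs} estimates the same parameters as post-burn-in
#' means of the conjugate Gibbs chain under Jeffreys' prior
#' \eqn{f(\mu, \sigma^2) = 1/\sigma^2}: \eqn{\sigma^2 \mid \mu \sim
#' IG(n/2,\, n V_\mu/2)} and \eqn{\mu \mid \sigma^2 \sim N(\bar x,\,
#' \sigma^2/n)}. Under missingness \eqn{n} is the observed count.
#'
#' @param x numeric vector for one genotype and attribute across environments;
#'   \code{NA} entries are dropped.
#' @param nSamples total Gibbs draws (default 5500).
#' @param burn burn-in draws discarded (default 500).
#' @param seed optional seed set before the chain is run.
#' @return list with elements \code{mu}, \code{sigma2}, \code{n}, \code{method}.
#' @examples
#' normMLE(c(-1, 0, 1))            # mu 0, sigma2 2/3
#' normGibbs(c(-1, 0, 1, 2), seed = 1)
#' @export
normMLE <- function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2L) stop("need at least 2 observed entries to fit NORM")
    mu <- mean(x)
    list(mu = mu, sigma2 = sum((x - mu)^2) / n, n = n, method = "mle")
}

#' @rdname normMLE
#' @export
normGibbs <- function(x, nSamples = 5500L, burn = 500L, seed = NULL) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) stop("need at least 2 observed entries to fit NORM")
    stopifnot(nSamples > burn, burn >= 0L)
    if (!is.null(seed)) set.seed(seed)
    fit <- gibbs_norm_cpp(x, as.integer(nSamples), as.integer(burn))
    list(mu = fit$mu, sigma2 = fit$sigma2, n = length(x), method = "gibbs")
}

#' Draw NORM imputations for missing entries of one vector
#'
#' Each missing entry gets \eqn{\hat\mu + z\,\hat\sigma} with an independent
#' standard normal \eqn{z} per entry per imputation.
#'
#' @param params fit from \code{\link{normMLE}} or \code{\link{normGibbs}}.
#' @param nMissing number of missing entries to draw.
#' @return numeric vector of length \code{nMissing}.
#' @export
normDraw <- function(params, nMissing) {
    params$mu + rnorm(nMissing) * sqrt(params$sigma2)
}

#' NORM multiple imputation over a standardized MET array
#'
#' Fits one NORM model per genotype-attribute vector (MLE, or conjugate Gibbs
#' posterior means when \code{bayes = TRUE}) and draws \eqn{H} independent
#' imputations of every missing entry. Vectors left with a single observed
#' value (possible at high missingness) fall back to that value as the mean
#' with unit variance on the standardized scale.
#'
#' @param std a \code{\linkS4class{StandardizedMET}} with missing entries.
#' @param H number of imputations (default 100).
#' @param bayes use the Gibbs posterior-mean fit instead of the MLE.
#' @param nSamples,burn Gibbs chain length and burn-in (defaults 5500/500).
#' @param seed master seed.
#' @param cells optional precomputed \code{M x 3} missing-entry index.
#' @return an \code{\linkS4class{ImputationResult}}.
#' @export
normImpute <- function(std, H = 100L, bayes = FALSE, nSamples = 5500L,
                       burn = 500L, seed = 1L, cells = NULL) {
    stopifnot(is(std, "StandardizedMET"), H >= 1L)
    if (is.null(cells)) cells <- which(is.na(std@values), arr.ind = TRUE)
    colnames(cells) <- c("i", "j", "k")
    v <- std@values
    d <- dim(v)
    seeds <- childSeeds(seed, 2L)
    ## one fit per (i, k) vector that has missing entries
    ik <- unique(cbind(cells[, 1L], cells[, 3L]))
    mu <- sig <- matrix(NA_real_, d[1L], d[3L])
    set.seed(seeds[1L])
    for (r in seq_len(nrow(ik))) {
        i <- ik[r, 1L]; k <- ik[r, 2L]
        x <- v[i, , k]
        nobs <- sum(!is.na(x))
        if (nobs >= 2L) {
            fit <- if (bayes) normGibbs(x, nSamples, burn) else normMLE(x)
            mu[i, k] <- fit$mu; sig[i, k] <- sqrt(fit$sigma2)
        } else {
            ## degenerate vector: single observed value; unit standardized scale
            mu[i, k] <- x[!is.na(x)][1L]
            sig[i, k] <- 1
        }
    }
    set.seed(seeds[2L])
    M <- nrow(cells)
    muv <- mu[cbind(cells[, 1L], cells[, 3L])]
    sgv <- sig[cbind(cells[, 1L], cells[, 3L])]
    est <- matrix(rnorm(H * M), H, M) * rep(sgv, each = H) + rep(muv, each = H)
    .finishResult(std, est, cells, if (bayes) "norm-ba" else "norm-nba", H, seed)
}
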