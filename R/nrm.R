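## Normal regression model (NRM) imputation.
##
## Each standardized column x_jk is regressed on a design matrix built from
## the rest of the I x JK wide matrix (four options for which columns enter),
## with missing predictor entries substituted by zero so they do not
## contribute. Cells are imputed from the fitted regression (Eq 2 style:
## prediction plus Gaussian noise); wholly missing columns are imputed through
## the within-environment attribute correlation matrix R, by the average- or
## linear-correlation rule.

#' Build an NRM design matrix for one target column
#'
#' Option 1 uses all other \eqn{JK - 1} wide-matrix columns; option 2 drops
#' the whole target environment (\eqn{K(J-1)} columns); option 3 is option 2
#' plus the target environment's other-attribute columns scaled by their
#' within-environment correlation with the target attribute (\eqn{KJ - 1}
#' columns); option 4 keeps only the target environment's other-attribute
#' columns (\eqn{K - 1}). Missing entries appear as exact zeros.
#'
#' @param std a \code{\linkS4class{StandardizedMET}}.
#' @param target integer pair \code{c(j, k)}: the environment and attribute of
#'   the column being modelled.
#' @param option design option, 1-4.
#' @param R the correlation matrix from \code{\link{correlationR}}; required
#'   for option 3.
#' @return numeric \code{I x N} matrix. Rows align with genotypes; split into
#'   observed/missing blocks by the target column's mask.
#' @export
buildDesign <- function(std, target, option = 3L, R = NULL) {
    v <- std@values
    d <- dim(v)
    I <- d[1L]; J <- d[2L]; K <- d[3L]
    j <- target[1L]; k <- target[2L]
    wide <- matrix(v, I, J * K)
    Z <- wide; Z[is.na(Z)] <- 0
    tcol <- jkIndex(j, k, J)
    envcols <- jkIndex(j, seq_len(K), J)
    option <- as.integer(option)
    if (option == 1L) {
        X <- Z[, -tcol, drop = FALSE]
    } else if (option == 2L) {
        X <- Z[, -envcols, drop = FALSE]
    } else if (option == 3L) {
        if (is.null(R)) stop("option 3 requires the correlation matrix R")
        others <- setdiff(seq_len(K), k)
        r <- vapply(others, function(kp) R[j, pairIndex(k, kp, K)], numeric(1L))
        if (anyNA(r)) {
            allZero <- vapply(others[is.na(r)], function(kp)
                all(Z[, jkIndex(j, kp, J)] == 0), logical(1L))
            if (!all(allZero))
                stop("correlation r_kk'(j) unavailable for target (", j, ",", k,
                     "); if the attribute is wholly missing in this ",
                     "environment use the missing-column rules")
            r[is.na(r)] <- 0   # wholly missing columns are all-zero anyway
        }
        scaled <- Z[, jkIndex(j, others, J), drop = FALSE] *
            rep(r, each = I)
        X <- cbind(Z[, -envcols, drop = FALSE], scaled)
    } else if (option == 4L) {
        X <- Z[, setdiff(envcols, tcol), drop = FALSE]
    } else stop("design option must be 1, 2, 3 or 4")
    X
}

#' Fit the NRM by maximum likelihood
#'
#' Least squares of the observed responses on the matching design rows, with
#' the residual variance using denominator (observed count \eqn{- 2}).
#' Rank-deficient designs (possible for option 1 when \eqn{N} exceeds the
#' observed count) are solved by pseudoinverse.
#'
#' @param y observed responses (no \code{NA}).
#' @param X design block for the observed rows (\code{length(y)} rows).
#' @return list with \code{beta}, \code{sigma2}, \code{method = "mle"}.
#' @examples
#' nrmMLE(c(2, 4, 6), cbind(c(1, 2, 3)))$beta  # 2
#' @export
nrmMLE <- function(y, X) {
    X <- as.matrix(X)
    n <- length(y)
    if (n < 3L) stop("need at least 3 observed responses to fit the NRM")
    beta <- pinvSolve(X, y)
    beta[is.na(beta)] <- 0
    rss <- sum((y - drop(X %*% beta))^2)
    list(beta = beta, sigma2 = rss / (n - 2L), method = "mle")
}

#' Fit the NRM by conjugate Gibbs sampling
#'
#' Priors \eqn{\beta \sim N(0, \tau^2 I)} and \eqn{\sigma^2 \sim
#' IG(\nu_0/2, S_0/2)} with \eqn{\nu_0 = 4, S_0 = 2} (prior mean of
#' \eqn{\sigma^2} equal to 1, the standardized-column variance) and
#' \eqn{\tau^2 = 1}. Estimates are post-burn-in means. The \eqn{\tau^2} ridge
#' keeps the conditional proper even for rank-deficient designs.
#'
#' @inheritParams nrmMLE
#' @param tau2,nu0,S0 prior hyper-parameters.
#' @param nSamples,burn chain length and burn-in (defaults 5500/500).
#' @param seed optional seed set before the chain is run.
#' @return list with \code{beta}, \code{sigma2}, \code{method = "gibbs"}.
#' @export
nrmGibbs <- function(y, X, tau2 = 1, nu0 = 4, S0 = 2, nSamples = 5500L,
                     burn = 500L, seed = NULL) {
    X <- as.matrix(X)
    if (length(y) < 3L) stop("need at least 3 observed responses to fit the NRM")
    stopifnot(nSamples > burn, burn >= 0L)
    if (!is.null(seed)) set.seed(seed)
    fit <- gibbs_reg_cpp(y, X, tau2, nu0, S0, as.integer(nSamples),
                         as.integer(burn))
    list(beta = fit$beta, sigma2 = fit$sigma2, method = "gibbs")
}

#' Within-environment attribute-pair correlation matrix R
#'
#' For every environment \eqn{j} and attribute pair \eqn{(k, k')}, the Pearson
#' correlation over jointly observed genotypes, assembled as a \eqn{J \times
#' K(K-1)/2} matrix in the fixed pair order \eqn{(1,2), (1,3), \ldots,
#' (K-1,K)}. Entries with fewer than 3 jointly observed genotypes (including
#' every pair touching a wholly missing column) are \code{NA}.
#'
#' @param std a \code{\linkS4class{StandardizedMET}}.
#' @param warn warn when a pair is dropped for having under 3 joint
#'   observations while both columns have data.
#' @return numeric \code{J x K(K-1)/2} matrix with pair-label column names.
#' @export
correlationR <- function(std, warn = TRUE) {
    v <- std@values
    d <- dim(v)
    J <- d[2L]; K <- d[3L]
    if (K < 2L) {
        return(matrix(numeric(0L), J, 0L))
    }
    pairs <- utils::combn(K, 2L)
    R <- matrix(NA_real_, J, ncol(pairs))
    colnames(R) <- paste0(dimnames(v)[[3L]][pairs[1L, ]], "-",
                          dimnames(v)[[3L]][pairs[2L, ]])
    rownames(R) <- dimnames(v)[[2L]]
    warned <- FALSE
    for (j in seq_len(J)) {
        slab <- v[, j, , drop = TRUE]
        if (is.null(dim(slab))) slab <- matrix(slab, ncol = K)
        obs <- !is.na(slab)
        counts <- crossprod(obs * 1)
        suppressWarnings(cm <- cor(slab, use = "pairwise.complete.obs"))
        for (p in seq_len(ncol(pairs))) {
            a <- pairs[1L, p]; b <- pairs[2L, p]
            if (counts[a, b] >= 3L && is.finite(cm[a, b])) {
                R[j, p] <- cm[a, b]
            } else if (warn && !warned &&
                       sum(obs[, a]) > 0L && sum(obs[, b]) > 0L) {
                warning("attribute pair(s) with fewer than 3 jointly observed ",
                        "genotypes marked NA in R")
                warned <- TRUE
            }
        }
    }
    R
}

#' Index of an attribute pair in the columns of R
#'
#' @param k,kp attribute indices (order-free).
#' @param K number of attributes.
#' @return column index into the matrix returned by \code{\link{correlationR}}.
#' @export
pairIndex <- function(k, kp, K) {
    a <- min(k, kp); b <- max(k, kp)
    ## pairs (1,2)..(1,K), (2,3)..(2,K), ... in combn order
    (a - 1L) * K - (a * (a - 1L)) %/% 2L + (b - a)
}

#' Impute NRM cells from a fitted model
#'
#' Each missing entry gets its regression prediction plus fresh standard
#' normal noise scaled by \eqn{\hat\sigma}.
#'
#' @param params fit from \code{\link{nrmMLE}} or \code{\link{nrmGibbs}}.
#' @param Xm design block for the missing rows.
#' @return numeric vector of imputed values, one per missing row.
#' @export
imputeCellsNRM <- function(params, Xm) {
    Xm <- as.matrix(Xm)
    drop(Xm %*% params$beta) + rnorm(nrow(Xm)) * sqrt(params$sigma2)
}

## Deterministic part of the average-correlation column prediction.
## Returns list(pred = I-vector, rbar = named averages).
.columnAvgPred <- function(std, target, R) {
    v <- std@values
    d <- dim(v)
    K <- d[3L]
    if (K < 2L) stop("cannot impute a missing column with a single attribute")
    jp <- target[1L]; kp <- target[2L]
    others <- setdiff(seq_len(K), kp)
    rbar <- vapply(others, function(k) {
        rs <- R[-jp, pairIndex(k, kp, K)]
        rs <- rs[!is.na(rs)]
        if (!length(rs))
            stop("no environment provides a correlation for attribute pair (",
                 k, ",", kp, ")")
        mean(rs)
    }, numeric(1L))
    donor <- v[, jp, others, drop = FALSE]
    donor[is.na(donor)] <- 0
    pred <- drop(matrix(donor, d[1L], length(others)) %*% rbar) / (K - 1L)
    list(pred = pred, r = rbar)
}

#' Impute a wholly missing column via average correlations
#'
#' The unavailable correlations between the missing attribute \eqn{k'} and the
#' others in environment \eqn{j'} are replaced by their averages over the
#' other environments; the column is then predicted as \eqn{\sum_k \bar
#' r_{kk'} \tilde x_{j'k} / (K - 1)} plus noise \eqn{z\,\bar\sigma}.
#'
#' @param std a \code{\linkS4class{StandardizedMET}}.
#' @param target \code{c(j', k')} of the wholly missing column.
#' @param R matrix from \code{\link{correlationR}}.
#' @param sigmaBar average fitted residual SD over the non-missing columns
#'   (see \code{\link{sigmaBarNRM}}).
#' @param seed optional seed.
#' @param noise add the \eqn{z\,\bar\sigma} term (disable for the PMM
#'   prediction step).
#' @return numeric vector of \eqn{I} imputed values.
#' @export
imputeColumnAvg <- function(std, target, R, sigmaBar, seed = NULL,
                            noise = TRUE) {
    if (!is.null(seed)) set.seed(seed)
    p <- .columnAvgPred(std, target, R)
    if (noise) p$pred + rnorm(length(p$pred)) * sigmaBar else p$pred
}

## Deterministic part of the linear-correlation column prediction.
.columnLinregPred <- function(std, target, R) {
    v <- std@values
    d <- dim(v)
    K <- d[3L]
    if (K < 2L) stop("cannot impute a missing column with a single attribute")
    jp <- target[1L]; kp <- target[2L]
    rTarget <- R[jp, ]
    obsSlots <- which(!is.na(rTarget))
    missSlots <- which(is.na(rTarget))
    complete <- setdiff(which(rowSums(is.na(R)) == 0L), jp)
    if (length(complete) < 2L)
        stop("fewer than 2 environments with complete correlation rows; ",
             "use the average-correlation rule instead")
    ## One through-origin slope per donor environment (r'_j = beta_jj' r_j is
    ## dimensionally ambiguous in the source; this regression layout is a
    ## documented package choice - see the methods vignette).
    preds <- vapply(complete, function(jd) {
        rj <- R[jd, ]
        slope <- if (length(obsSlots)) {
            denom <- sum(rj[obsSlots]^2)
            if (denom > 0) sum(rTarget[obsSlots] * rj[obsSlots]) / denom else 0
        } else 0
        slope * rj[missSlots]
    }, numeric(length(missSlots)))
    rhat <- if (length(missSlots) == 1L) mean(preds) else rowMeans(matrix(
        preds, nrow = length(missSlots)))
    rfull <- rTarget
    rfull[missSlots] <- rhat
    others <- setdiff(seq_len(K), kp)
    rvec <- vapply(others, function(k) rfull[pairIndex(k, kp, K)], numeric(1L))
    donor <- v[, jp, others, drop = FALSE]
    donor[is.na(donor)] <- 0
    pred <- drop(matrix(donor, d[1L], length(others)) %*% rvec) / (K - 1L)
    list(pred = pred, r = rvec)
}

#' Impute a wholly missing column via linearly regressed correlations
#'
#' The missing entries of row \eqn{j'} of \code{R} are predicted by
#' through-origin regression of that row's observed entries on each complete
#' donor row, averaging predictions over donors; the column prediction then
#' follows the same form as the average-correlation rule.
#'
#' @inheritParams imputeColumnAvg
#' @return numeric vector of \eqn{I} imputed values.
#' @export
imputeColumnLinreg <- function(std, target, R, sigmaBar, seed = NULL,
                               noise = TRUE) {
    if (!is.null(seed)) set.seed(seed)
    p <- .columnLinregPred(std, target, R)
    if (noise) p$pred + rnorm(length(p$pred)) * sigmaBar else p$pred
}

#' Average fitted residual SD over the non-missing columns
#'
#' Fits the option-4 (within-environment) regression by MLE to every column
#' with observed data and averages the residual standard deviations. This is
#' the \eqn{\bar\sigma} that scales the noise of the missing-column rules.
#'
#' @param std a \code{\linkS4class{StandardizedMET}}.
#' @return scalar \eqn{\bar\sigma} (\code{NA} when \eqn{K = 1}).
#' @export
sigmaBarNRM <- function(std) {
    v <- std@values
    d <- dim(v)
    if (d[3L] < 2L) return(NA_real_)
    sds <- c()
    for (k in seq_len(d[3L])) {
        for (j in seq_len(d[2L])) {
            y <- v[, j, k]
            obs <- !is.na(y)
            if (sum(obs) < 3L) next
            X <- buildDesign(std, c(j, k), option = 4L)
            fit <- nrmMLE(y[obs], X[obs, , drop = FALSE])
            sds <- c(sds, sqrt(fit$sigma2))
        }
    }
    if (!length(sds)) NA_real_ else mean(sds)
}

#' NRM multiple imputation over a standardized MET array
#'
#' Columns with observed data and missing cells are imputed from the fitted
#' regression (design per \code{option}; MLE or Gibbs posterior means per
#' \code{bayes}), with fresh noise per imputation. Wholly missing columns are
#' imputed by the average- or linear-correlation rule with noise scaled by
#' \eqn{\bar\sigma}. Estimation is performed once per column; the \eqn{H}
#' imputations differ by their noise draws.
#'
#' @inheritParams normImpute
#' @param option design option 1-4 for the cell regressions (default 3).
#' @param columnRule \code{"avg"} (default) or \code{"linreg"} for wholly
#'   missing columns.
#' @param tau2 prior variance of the regression coefficients (Bayes only).
#' @return an \code{\linkS4class{ImputationResult}}.
#' @export
nrmImpute <- function(std, H = 100L, option = 3L, bayes = FALSE,
                      columnRule = c("avg", "linreg"), nSamples = 5500L,
                      burn = 500L, tau2 = 1, seed = 1L, cells = NULL) {
    stopifnot(is(std, "StandardizedMET"), H >= 1L)
    columnRule <- match.arg(columnRule)
    if (is.null(cells)) cells <- which(is.na(std@values), arr.ind = TRUE)
    colnames(cells) <- c("i", "j", "k")
    v <- std@values
    d <- dim(v)
    K <- d[3L]
    seeds <- childSeeds(seed, 2L)
    R <- if (K >= 2L) correlationR(std, warn = FALSE) else NULL
    sigmaBar <- sigmaBarNRM(std)
    pred <- sig <- rep(NA_real_, nrow(cells))
    jk <- unique(cells[, c(2L, 3L), drop = FALSE])
    set.seed(seeds[1L])
    for (r in seq_len(nrow(jk))) {
        j <- jk[r, 1L]; k <- jk[r, 2L]
        y <- v[, j, k]
        obs <- !is.na(y)
        rows <- which(cells[, 2L] == j & cells[, 3L] == k)
        if (!any(obs)) {
            ## wholly missing column
            p <- if (columnRule == "avg") .columnAvgPred(std, c(j, k), R)
                 else .columnLinregPred(std, c(j, k), R)
            pred[rows] <- p$pred[cells[rows, 1L]]
            sig[rows] <- sigmaBar
        } else {
            X <- buildDesign(std, c(j, k), option = option, R = R)
            fit <- if (bayes)
                nrmGibbs(y[obs], X[obs, , drop = FALSE], tau2 = tau2,
                         nSamples = nSamples, burn = burn)
            else nrmMLE(y[obs], X[obs, , drop = FALSE])
            mrows <- cells[rows, 1L]
            pred[rows] <- drop(X[mrows, , drop = FALSE] %*% fit$beta)
            sig[rows] <- sqrt(fit$sigma2)
        }
    }
    set.seed(seeds[2L])
    M <- nrow(cells)
    est <- matrix(rnorm(H * M), H, M) * rep(sig, each = H) +
        rep(pred, each = H)
    .finishResult(std, est, cells,
                  if (bayes) "nrm-ba" else "nrm-nba", H, seed)
}
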