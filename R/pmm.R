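## Predictive mean matching (PMM) imputation.
##
## For each imputation the NRM regression is refitted on a bootstrap sample of
## the observed responses; predicted values of observed and missing entries
## are compared by the d^2 distance and one of the C closest actual observed
## values is donated. A separate matching scheme handles wholly missing
## columns through the correlation-based column prediction.

#' Donor candidate sets by the d-squared distance
#'
#' For each missing-row prediction, ranks the observed-row predictions by
#' \eqn{d^2_{(ii')} = (\hat x^{obs}_i - \hat x^m_{i'})^2 / \sigma^2} and
#' returns the indices of the \code{C} smallest (ties broken by index, so the
#' sets are deterministic given the predictions). When \eqn{\sigma^2 = 0}
#' the unscaled squared difference is used (ordering is unchanged by the
#' positive scale factor).
#'
#' @param predObs predictions for the observed (donor) entries.
#' @param predMis predictions for the missing entries.
#' @param sigma2 residual variance scaling \eqn{d^2}.
#' @param C donor pool size; pools shrink (with a warning from the caller)
#'   when fewer donors exist.
#' @return list of integer index vectors into \code{predObs}, one per missing
#'   entry.
#' @export
pmmDonorSets <- function(predObs, predMis, sigma2, C = 3L) {
    s <- if (is.finite(sigma2) && sigma2 > 0) sigma2 else 1
    C <- min(C, length(predObs))
    lapply(predMis, function(pm) {
        d2 <- (predObs - pm)^2 / s
        order(d2)[seq_len(C)]     # order() is stable: ties fall to low index
    })
}

#' PMM imputation of the missing cells of one column
#'
#' Per imputation: draw a bootstrap sample (with replacement, size equal to
#' the observed count) of the observed rows jointly with their design rows;
#' fit the NRM on the bootstrap block; predict bootstrap-observed and missing
#' rows; donate the actual observed value of one of the \code{C} nearest
#' predictions, drawn uniformly.
#'
#' @param y the target column (length \eqn{I}, \code{NA} for missing).
#' @param X design matrix for the column (\eqn{I} rows).
#' @param H number of imputations.
#' @param C donor pool size (default 3).
#' @param bayes fit by Gibbs posterior means instead of MLE.
#' @param nSamples,burn Gibbs chain controls.
#' @param tau2 prior coefficient variance (Bayes only).
#' @return numeric \code{H x} (number missing) matrix of donated values.
#' @export
pmmImputeCells <- function(y, X, H = 1L, C = 3L, bayes = FALSE,
                           nSamples = 5500L, burn = 500L, tau2 = 1) {
    obs <- which(!is.na(y))
    mis <- which(is.na(y))
    if (length(obs) < 3L)
        stop("need at least 3 observed values in the column for PMM")
    if (length(unique(y[obs])) < C)
        warning("fewer than C distinct observed values; donor pool reduced")
    out <- matrix(NA_real_, H, length(mis))
    Xm <- X[mis, , drop = FALSE]
    for (h in seq_len(H)) {
        boot <- sample(obs, length(obs), replace = TRUE)
        yb <- y[boot]
        Xb <- X[boot, , drop = FALSE]
        fit <- if (bayes)
            nrmGibbs(yb, Xb, tau2 = tau2, nSamples = nSamples, burn = burn)
        else nrmMLE(yb, Xb)
        predObs <- drop(Xb %*% fit$beta)
        predMis <- drop(Xm %*% fit$beta)
        sets <- pmmDonorSets(predObs, predMis, fit$sigma2, C)
        out[h, ] <- vapply(sets, function(s)
            yb[s[sample.int(length(s), 1L)]], numeric(1L))
    }
    out
}

#' PMM imputation of a wholly missing column
#'
#' The missing column is predicted by the average-correlation rule (no noise
#' term). For each donor attribute in a randomly drawn subset, that
#' attribute's column in the target environment is predicted from a design of
#' the subset's columns over the other environments; matching then donates,
#' per genotype, the actual observed value among the \code{C} donor entries
#' whose predictions are closest.
#'
#' @param std a \code{\linkS4class{StandardizedMET}}.
#' @param target \code{c(j', k')} of the wholly missing column.
#' @param R matrix from \code{\link{correlationR}}.
#' @param H number of imputations.
#' @param C donor pool size.
#' @param bayes,nSamples,burn,tau2 as in \code{\link{pmmImputeCells}}.
#' @return numeric \code{H x I} matrix of donated values.
#' @export
pmmImputeColumn <- function(std, target, R, H = 1L, C = 3L, bayes = FALSE,
                            nSamples = 5500L, burn = 500L, tau2 = 1) {
    v <- std@values
    d <- dim(v)
    I <- d[1L]; J <- d[2L]; K <- d[3L]
    jp <- target[1L]; kp <- target[2L]
    if (K < 2L) stop("cannot impute a missing column with a single attribute")
    eligible <- setdiff(which(colSums(!is.na(v[, jp, , drop = FALSE])) > 0L), kp)
    if (!length(eligible)) stop("no eligible donor attribute in environment ", jp)
    predMis <- .columnAvgPred(std, c(jp, kp), R)$pred
    wide <- matrix(v, I, J * K)
    Z <- wide; Z[is.na(Z)] <- 0
    out <- matrix(NA_real_, H, I)
    for (h in seq_len(H)) {
        nk <- sample.int(max(K - 1L, 1L), 1L)
        Nk <- sort(sample(setdiff(seq_len(K), kp), min(nk, K - 1L)))
        donors <- intersect(Nk, eligible)
        if (!length(donors)) donors <- eligible
        ## design: the subset's columns over the other J-1 environments
        dcols <- as.vector(vapply(Nk, function(k)
            jkIndex(setdiff(seq_len(J), jp), k, J), integer(J - 1L)))
        Xd <- Z[, dcols, drop = FALSE]
        donorPred <- donorActual <- donorIdx <- NULL
        for (k in donors) {
            yk <- v[, jp, k]
            obsk <- which(!is.na(yk))
            if (length(obsk) < 3L) next
            fit <- if (bayes)
                nrmGibbs(yk[obsk], Xd[obsk, , drop = FALSE], tau2 = tau2,
                         nSamples = nSamples, burn = burn)
            else nrmMLE(yk[obsk], Xd[obsk, , drop = FALSE])
            pk <- drop(Xd[obsk, , drop = FALSE] %*% fit$beta)
            donorPred <- c(donorPred, pk)
            donorActual <- c(donorActual, yk[obsk])
        }
        if (is.null(donorPred))
            stop("no donor attribute with >= 3 observed values in environment ",
                 jp)
        sets <- pmmDonorSets(donorPred, predMis, sigma2 = 1, C = C)
        out[h, ] <- vapply(sets, function(s)
            donorActual[s[sample.int(length(s), 1L)]], numeric(1L))
    }
    out
}

#' PMM multiple imputation over a standardized MET array
#'
#' Applies \code{\link{pmmImputeCells}} to every column with observed data and
#' missing cells and \code{\link{pmmImputeColumn}} to wholly missing columns.
#' Every imputed value is an actual observed value of the array (donor
#' realism).
#'
#' @inheritParams normImpute
#' @param C donor pool size (default 3).
#' @param option design option for the cell regressions. Default 4 (the
#'   within-environment attribute design): PMM refits its regression on every
#'   bootstrap draw of every imputation, and the compact design keeps that
#'   affordable while using exactly the within-environment information the
#'   missing-column scheme relies on.
#' @param tau2 prior coefficient variance (Bayes only).
#' @return an \code{\linkS4class{ImputationResult}}.
#' @export
pmmImpute <- function(std, H = 100L, C = 3L, option = 4L, bayes = FALSE,
                      nSamples = 5500L, burn = 500L, tau2 = 1, seed = 1L,
                      cells = NULL) {
    stopifnot(is(std, "StandardizedMET"), H >= 1L)
    if (is.null(cells)) cells <- which(is.na(std@values), arr.ind = TRUE)
    colnames(cells) <- c("i", "j", "k")
    v <- std@values
    K <- dim(v)[3L]
    R <- if (K >= 2L) correlationR(std, warn = FALSE) else NULL
    est <- matrix(NA_real_, H, nrow(cells))
    jk <- unique(cells[, c(2L, 3L), drop = FALSE])
    set.seed(seed)
    for (r in seq_len(nrow(jk))) {
        j <- jk[r, 1L]; k <- jk[r, 2L]
        y <- v[, j, k]
        rows <- which(cells[, 2L] == j & cells[, 3L] == k)
        if (all(is.na(y))) {
            vals <- pmmImputeColumn(std, c(j, k), R, H = H, C = C,
                                    bayes = bayes, nSamples = nSamples,
                                    burn = burn, tau2 = tau2)
            est[, rows] <- vals[, cells[rows, 1L], drop = FALSE]
        } else {
            X <- buildDesign(std, c(j, k), option = option, R = R)
            vals <- pmmImputeCells(y, X, H = H, C = C, bayes = bayes,
                                   nSamples = nSamples, burn = burn,
                                   tau2 = tau2)
            mis <- which(is.na(y))
            est[, rows] <- vals[, match(cells[rows, 1L], mis), drop = FALSE]
        }
    }
    .finishResult(std, est, cells, if (bayes) "pmm-ba" else "pmm-nba", H, seed)
}
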