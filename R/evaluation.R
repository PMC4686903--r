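## Rubin's-rules pooling, confidence-interval coverage and NRMSE: the
## machinery used to compare the imputation methods against known deleted
## values.

#' Pool multiply imputed estimates by Rubin's rules
#'
#' Given \eqn{H} imputation vectors \eqn{\hat Q_h} (one entry per missing
#' value) and the within-imputation variances \eqn{U_h}, computes
#' \eqn{\bar U = H^{-1}\sum U_h}, the per-value between-imputation variance
#' \eqn{B = (H-1)^{-1}\sum_h (\hat Q_h - \bar Q)^2}, the total variance
#' \eqn{T = \bar U + (1 + 1/H) B} and the degrees of freedom \eqn{\nu_H =
#' (H-1)\,[1 + \bar U / ((1 + H^{-1}) B)]^2}. Here \eqn{U_h} is the variance
#' of the imputed missing-value estimates within imputation \eqn{h} (the
#' convention of the evaluation protocol, not the classical sampling
#' variance), and \eqn{B}, \eqn{T}, \eqn{\nu_H} are per missing value.
#'
#' @param estimates numeric \code{H x M} matrix of per-imputation estimates.
#' @param withinVars optional numeric vector of length \code{H}; defaults to
#'   the row-wise variance of \code{estimates}.
#' @return list with \code{Qbar} (length \code{M}), \code{Ubar} (scalar),
#'   \code{B}, \code{T}, \code{nu} (length \code{M}), and \code{H}.
#' @examples
#' est <- matrix(rnorm(10), 5, 2)
#' rubinPool(est)
#' @export
rubinPool <- function(estimates, withinVars = NULL) {
    estimates <- as.matrix(estimates)
    H <- nrow(estimates)
    if (H < 2L) stop("Rubin pooling needs H >= 2 imputations (B is undefined)")
    if (is.null(withinVars))
        withinVars <- apply(estimates, 1L, var)
    stopifnot(length(withinVars) == H)
    Qbar <- colMeans(estimates)
    B <- apply(estimates, 2L, var)
    Ubar <- mean(withinVars)
    Tt <- Ubar + (1 + 1 / H) * B
    nu <- (H - 1) * (1 + Ubar / ((1 + 1 / H) * B))^2
    list(Qbar = Qbar, Ubar = Ubar, B = B, T = Tt, nu = nu, H = H)
}

#' Coverage of Rubin's-rules confidence intervals
#'
#' For each missing value, the interval \eqn{\bar Q \pm t_{\nu_H, 1-\alpha/2}
#' \sqrt{T}}; coverage is the percentage of values whose true (deleted) value
#' lies inside. Values with \eqn{B = 0} (all imputations identical) fall back
#' to a normal-quantile interval on \eqn{\bar U} alone, with a warning.
#'
#' @param truth numeric vector of the true standardized values of the missing
#'   entries.
#' @param estimates numeric \code{H x M} matrix of per-imputation estimates.
#' @param withinVars optional length-\code{H} within-imputation variances (see
#'   \code{\link{rubinPool}}).
#' @param level confidence level (default 0.95).
#' @return list with \code{coverage} (percent), \code{covered} (logical
#'   vector), \code{lower}, \code{upper}, and the \code{\link{rubinPool}}
#'   output under \code{pool}.
#' @export
coverageCI <- function(truth, estimates, withinVars = NULL, level = 0.95) {
    pool <- rubinPool(estimates, withinVars)
    stopifnot(length(truth) == length(pool$Qbar))
    alpha <- 1 - level
    degenerate <- pool$B <= 0 | !is.finite(pool$nu)
    if (any(degenerate))
        warning(sum(degenerate), " value(s) with zero between-imputation ",
                "variance; normal interval on Ubar used")
    half <- numeric(length(pool$Qbar))
    ok <- !degenerate
    half[ok] <- qt(1 - alpha / 2, pool$nu[ok]) * sqrt(pool$T[ok])
    half[degenerate] <- qnorm(1 - alpha / 2) * sqrt(pool$Ubar)
    lower <- pool$Qbar - half
    upper <- pool$Qbar + half
    covered <- truth >= lower & truth <= upper
    list(coverage = 100 * mean(covered), covered = covered,
         lower = lower, upper = upper, pool = pool)
}

#' Normalized root mean squared error against the original array
#'
#' The completed array is re-standardized column-wise (its columns are no
#' longer exactly centred/scaled after imputation) and compared with the
#' standardized original over \emph{all} entries:
#' \deqn{NRMSE = \sqrt{\mathrm{mean}[(\tilde x_{ijk} - \hat{\tilde x}_{ijk})^2]
#'   / \mathrm{Var}(\tilde x_{ijk})}.}
#' Zero iff the completion reproduces the original standardized array; by the
#' re-standardization it is invariant to per-column affine changes of the
#' estimate.
#'
#' @param original a fully observed \code{\linkS4class{METArray}} (raw scale)
#'   or \code{\linkS4class{StandardizedMET}}.
#' @param completed a completed array on the standardized scale: a
#'   \code{\linkS4class{StandardizedMET}}, \code{\linkS4class{METArray}} or
#'   plain array with no missing entries.
#' @return scalar NRMSE.
#' @export
nrmse <- function(original, completed) {
    orig <- if (is(original, "StandardizedMET")) original@values
            else standardizeMET(original)@values
    est <- if (is(completed, "METArray")) completed@values else completed
    stopifnot(all(dim(orig) == dim(est)))
    ## re-standardize the completed array column-wise
    d <- dim(est)
    m <- matrix(est, d[1L], d[2L] * d[3L])
    mu <- colMeans(m)
    sdv <- apply(m, 2L, sd)
    sdv[sdv == 0] <- 1
    z <- sweep(sweep(m, 2L, mu, "-"), 2L, sdv, "/")
    dim(z) <- d
    keep <- !is.na(orig)     # wholly missing original columns are undefined
    sqrt(mean((orig[keep] - z[keep])^2) / var(orig[keep]))
}

#' Randomly pool imputations into H averaged sets
#'
#' Implements the 100-into-5x20 protocol: the raw imputations are randomly
#' allocated into \code{H} equal sets and averaged within set, giving the
#' final \code{H} pooled imputations per missing value.
#'
#' @param estimates numeric (raw imputations \code{x M}) matrix.
#' @param H number of pooled sets (default 5); must divide the row count.
#' @param seed optional seed for the random allocation.
#' @return numeric \code{H x M} matrix of pooled estimates.
#' @export
poolImputations <- function(estimates, H = 5L, seed = NULL) {
    n <- nrow(estimates)
    stopifnot(n %% H == 0L)
    if (!is.null(seed)) set.seed(seed)
    alloc <- split(sample.int(n), rep(seq_len(H), each = n %/% H))
    out <- matrix(NA_real_, H, ncol(estimates))
    for (h in seq_len(H))
        out[h, ] <- colMeans(estimates[alloc[[h]], , drop = FALSE], na.rm = TRUE)
    out
}
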