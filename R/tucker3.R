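## EM single imputation inside a Tucker3 three-mode model: alternate between
## refitting the component matrices / core by alternating least squares on the
## completed array and refilling the missing entries with the model
## reconstruction. Used as the single-imputation comparator in the NRMSE
## study.

## Mode-n unfolding of a three-way array (mode indexes the rows).
.unfold <- function(a, mode) {
    d <- dim(a)
    perm <- switch(mode, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                   `3` = c(3L, 1L, 2L))
    matrix(aperm(a, perm), d[mode], prod(d[-mode]))
}

## Leading r left singular vectors.
.leftSV <- function(m, r) {
    svd(m, nu = r, nv = 0L)$u
}

#' Tucker3 reconstruction from component matrices and core
#'
#' @param A,B,C component matrices (\code{I x P}, \code{J x Q}, \code{K x R}).
#' @param core numeric \code{P x Q x R} core array.
#' @return the reconstructed \code{I x J x K} array.
#' @export
tucker3Reconstruct <- function(A, B, C, core) {
    d <- c(nrow(A), nrow(B), nrow(C))
    g1 <- matrix(core, ncol(A), ncol(B) * ncol(C))
    x1 <- A %*% g1 %*% t(kronecker(C, B))
    array(x1, d)
}

#' EM / Tucker3 single imputation
#'
#' Missing entries are initialized at 0 (the standardized-scale mean); each EM
#' sweep refits a Tucker3 model of core dimension \code{dims} by one
#' alternating-least-squares pass (component matrices from the leading
#' singular vectors of the mode unfoldings, core by projection) and refills
#' the missing entries with the reconstruction. Iterates until the largest
#' change in a refilled entry drops below \code{tol} or \code{maxIter} sweeps.
#' The sum of squared reconstruction error over observed cells is
#' non-increasing across sweeps; observed entries are never altered.
#'
#' @param x a \code{\linkS4class{StandardizedMET}}, \code{\linkS4class{METArray}}
#'   or plain three-way array with \code{NA} for missing entries.
#' @param dims core dimensions \code{c(P, Q, R)} (default \code{c(2, 2, 2)}).
#' @param tol convergence tolerance on the refilled entries (default 1e-6).
#' @param maxIter sweep cap (default 500).
#' @return list with \code{completed} (array), \code{A}, \code{B}, \code{C},
#'   \code{core}, \code{converged}, \code{nIter}, \code{obsError} (per-sweep
#'   observed-entry sum of squared error).
#' @examples
#' a <- array(rnorm(60), c(5, 4, 3)); a[c(1, 25)] <- NA
#' fit <- tucker3EM(a, dims = c(2, 2, 2))
#' fit$converged
#' @export
tucker3EM <- function(x, dims = c(2L, 2L, 2L), tol = 1e-6, maxIter = 500L) {
    a <- if (is(x, "METArray")) x@values else x
    d <- dim(a)
    stopifnot(length(d) == 3L, all(dims <= d), all(dims >= 1L))
    miss <- is.na(a)
    filled <- a
    filled[miss] <- 0
    A <- .leftSV(.unfold(filled, 1L), dims[1L])
    B <- .leftSV(.unfold(filled, 2L), dims[2L])
    C <- .leftSV(.unfold(filled, 3L), dims[3L])
    obsError <- numeric(0L)
    converged <- FALSE
    iter <- 0L
    repeat {
        iter <- iter + 1L
        ## one ALS pass (HOOI style): each factor from the array projected
        ## onto the other two current factors
        A <- .leftSV(.unfold(filled, 1L) %*% kronecker(C, B), dims[1L])
        B <- .leftSV(.unfold(filled, 2L) %*% kronecker(C, A), dims[2L])
        C <- .leftSV(.unfold(filled, 3L) %*% kronecker(B, A), dims[3L])
        core <- array(t(A) %*% .unfold(filled, 1L) %*% kronecker(C, B), dims)
        recon <- tucker3Reconstruct(A, B, C, core)
        obsError <- c(obsError, sum((a[!miss] - recon[!miss])^2))
        delta <- if (any(miss)) max(abs(filled[miss] - recon[miss])) else 0
        filled[miss] <- recon[miss]
        if (delta < tol) { converged <- TRUE; break }
        if (iter >= maxIter) {
            warning("Tucker3 EM did not converge in ", maxIter, " sweeps")
            break
        }
    }
    dimnames(filled) <- dimnames(a)
    list(completed = filled, A = A, B = B, C = C, core = core,
         converged = converged, nIter = iter, obsError = obsError)
}
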