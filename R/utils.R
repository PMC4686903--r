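## Internal helpers shared across modules.

## Deterministically derive n child seeds from one master seed, keeping all
## values inside the 32-bit integer range. Used so that repetitions and
## imputations get independent, order-independent RNG streams.
childSeeds <- function(seed, n) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
        get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(seed)
    s <- sample.int(.Machine$integer.max - 1L, n)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    s
}

## Least-squares coefficients via the Moore-Penrose pseudoinverse, used where
## design matrices can be rank deficient (e.g. more columns than observed
## rows). MASS::ginv handles the SVD bookkeeping.
pinvSolve <- function(X, y) {
    qrX <- qr(X)
    if (qrX$rank == ncol(X)) {
        qr.coef(qrX, y)
    } else {
        drop(MASS::ginv(X) %*% y)
    }
}

## Linear (j, k) column index into an I x (JK) wide matrix (j fastest).
jkIndex <- function(j, k, J) (k - 1L) * J + j
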