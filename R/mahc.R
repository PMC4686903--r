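## Multiple agglomerative hierarchical clustering (MAHC) imputation.
##
## Environments are clustered on the J x (I * K') wide matrix with Ward's
## incremental-sum-of-squares linkage on squared Euclidean distances; each
## missing genotype-attribute value is estimated from the environment (or
## environment group) its environment first merges with. Repeating over H
## random attribute subsets (always paired with the all-attribute tree) gives
## the multiple-imputation spread.

#' Missing-aware squared Euclidean dissimilarity between environments
#'
#' Distances are computed on the \eqn{J \times IK'} wide matrix restricted to
#' the selected attributes: for each environment pair, the squared Euclidean
#' distance over jointly observed genotype-attribute coordinates, rescaled by
#' (total coordinates / jointly observed coordinates) so that sparsity does
#' not shrink distances.
#'
#' @param std a \code{\linkS4class{StandardizedMET}} (possibly with missing
#'   entries).
#' @param attrs integer vector of attribute indices to use (default all).
#' @return symmetric \code{J x J} matrix with zero diagonal.
#' @examples
#' s <- standardizeMET(METArray(array(rnorm(36), c(6, 3, 2))))
#' environmentDistance(s)
#' @export
environmentDistance <- function(std, attrs = seq_len(dim(std@values)[3L])) {
    if (!length(attrs)) stop("'attrs' must be nonempty")
    v <- std@values[, , attrs, drop = FALSE]
    d <- dim(v)
    ## rows = environments, cols = (genotype, attribute) coordinates
    W <- matrix(aperm(v, c(2L, 1L, 3L)), d[2L], d[1L] * d[3L])
    O <- !is.na(W)
    Z <- W; Z[!O] <- 0
    Omode <- O * 1
    shared <- Omode %*% t(Omode)
    Q <- Z^2
    D <- Q %*% t(Omode) + Omode %*% t(Q) - 2 * tcrossprod(Z)
    if (any(shared[upper.tri(shared)] == 0)) {
        bad <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)[1L, ]
        stop(sprintf("environments %d and %d share no observed coordinate",
                     bad[1L], bad[2L]))
    }
    m <- ncol(W)
    D <- D * (m / shared)
    D[D < 0] <- 0            # numerical guard
    diag(D) <- 0
    dimnames(D) <- list(dimnames(std@values)[[2L]], dimnames(std@values)[[2L]])
    (D + t(D)) / 2
}

#' Ward (incremental sum of squares) agglomerative clustering
#'
#' A Lance-Williams implementation of Ward linkage on a precomputed
#' dissimilarity (squared Euclidean scale). Ties in the minimum are broken by
#' the lowest cluster-index pair, making the merge sequence fully
#' deterministic.
#'
#' @param dist symmetric \code{J x J} dissimilarity matrix with zero diagonal.
#' @param labels optional leaf labels (defaults to the matrix dimnames or
#'   \code{E1..EJ}).
#' @return a \code{\linkS4class{MergeTree}}.
#' @examples
#' D <- matrix(c(0, 1, 16, 1, 0, 16, 16, 16, 0), 3, 3)
#' wardCluster(D)@merge[1, ]  # the two close leaves merge first
#' @export
wardCluster <- function(dist, labels = NULL) {
    D <- as.matrix(dist)
    J <- nrow(D)
    if (J < 2L) stop("need at least two environments to cluster")
    if (is.null(labels))
        labels <- if (!is.null(rownames(D))) rownames(D) else paste0("E", seq_len(J))
    size <- rep(1L, J)
    id <- -seq_len(J)          # hclust convention: negative = leaf
    active <- rep(TRUE, J)
    merge <- matrix(0L, J - 1L, 2L)
    height <- numeric(J - 1L)
    work <- D
    diag(work) <- Inf
    work[!upper.tri(work) & !lower.tri(work)] <- Inf
    for (step in seq_len(J - 1L)) {
        act <- which(active)
        sub <- work[act, act, drop = FALSE]
        sub[lower.tri(sub, diag = TRUE)] <- Inf
        best <- which(sub == min(sub), arr.ind = TRUE)
        ## lowest-index pair first (row-major lexicographic on (a, b))
        best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
        a <- act[best[1L]]; b <- act[best[2L]]
        h <- work[a, b]
        pair <- sort(c(id[a], id[b]))
        ## hclust orders: leaves (negative) before clusters, both ascending
        merge[step, ] <- if (pair[1L] < 0L && pair[2L] < 0L) rev(pair) else pair
        height[step] <- h
        ## Lance-Williams Ward update into slot a
        for (l in act) {
            if (l == a || l == b) next
            na <- size[a]; nb <- size[b]; nl <- size[l]
            work[a, l] <- work[l, a] <-
                ((na + nl) * work[a, l] + (nb + nl) * work[b, l] - nl * h) /
                (na + nb + nl)
        }
        size[a] <- size[a] + size[b]
        active[b] <- FALSE
        id[a] <- step
    }
    new("MergeTree", merge = merge, height = height, labels = labels)
}

#' @describeIn wardCluster coerce to \code{\link[stats]{hclust}} for plotting
#'   and cutting.
#' @param x a \code{\linkS4class{MergeTree}}.
#' @param ... ignored.
#' @export
as.hclust.MergeTree <- function(x, ...) {
    n <- length(x@labels)
    ord <- integer(0L)
    expand <- function(node) {
        if (node < 0L) return(-node)
        c(expand(x@merge[node, 1L]), expand(x@merge[node, 2L]))
    }
    ord <- expand(n - 1L)
    structure(list(merge = x@merge, height = x@height, order = ord,
                   labels = x@labels, method = "ward",
                   call = match.call(), dist.method = "squared euclidean"),
              class = "hclust")
}

setMethod("show", "MergeTree", function(object) {
    cat(sprintf("MergeTree over %d environments (%d merges, heights %.3g..%.3g)\n",
                length(object@labels), nrow(object@merge),
                min(object@height), max(object@height)))
})

## For each leaf j: the ordered list of sibling member sets met while walking
## from the leaf to the root (the set the leaf's cluster merges with at each
## step on its path).
.siblingChains <- function(tree) {
    J <- length(tree@labels)
    members <- vector("list", J - 1L)
    chains <- rep(list(list()), J)
    cluster <- as.list(seq_len(J))     # current cluster membership by leaf
    for (step in seq_len(J - 1L)) {
        left <- tree@merge[step, 1L]
        right <- tree@merge[step, 2L]
        lm <- if (left < 0L) -left else members[[left]]
        rm <- if (right < 0L) -right else members[[right]]
        members[[step]] <- c(lm, rm)
        for (leaf in lm) chains[[leaf]] <- c(chains[[leaf]], list(rm))
        for (leaf in rm) chains[[leaf]] <- c(chains[[leaf]], list(lm))
    }
    chains
}

#' Donor estimate for one missing value from an environment hierarchy
#'
#' Walks up the tree from the environment of the missing value; at each merge
#' the estimate is the unweighted mean of the observed values of the same
#' genotype and attribute over the sibling group's environments. The first
#' merge providing at least one observed donor wins; \code{NA} is returned
#' only when no other environment observes that genotype-attribute pair.
#'
#' @param tree a \code{\linkS4class{MergeTree}} over the environments.
#' @param std the \code{\linkS4class{StandardizedMET}} the values are read
#'   from.
#' @param target integer triple \code{c(i, j, k)} of the missing entry.
#' @return scalar estimate, or \code{NA} if no donor exists.
#' @export
donorEstimate <- function(tree, std, target) {
    chain <- .siblingChains(tree)[[target[2L]]]
    for (sib in chain) {
        vals <- std@values[target[1L], sib, target[3L]]
        vals <- vals[!is.na(vals)]
        if (length(vals)) return(mean(vals))
    }
    NA_real_
}

## Vectorized donor estimation for all targets (rows of `cells`) under one
## tree. Returns a numeric vector aligned with the rows of `cells`.
## If `attrs` is given, only targets whose attribute is in `attrs` receive an
## estimate (the subset-tree rule); others get NA.
.treeEstimates <- function(tree, std, cells, attrs = NULL) {
    v <- std@values
    d <- dim(v)
    chains <- .siblingChains(tree)
    ## (i, k) rows x environment columns view for fast sibling-group means
    W <- matrix(aperm(v, c(1L, 3L, 2L)), d[1L] * d[3L], d[2L])
    O <- !is.na(W)
    Z <- W; Z[!O] <- 0
    out <- rep(NA_real_, nrow(cells))
    keep <- if (is.null(attrs)) seq_len(nrow(cells)) else
        which(cells[, 3L] %in% attrs)
    if (!length(keep)) return(out)
    byEnv <- split(keep, cells[keep, 2L])
    for (jname in names(byEnv)) {
        j <- as.integer(jname)
        rows <- byEnv[[jname]]
        ik <- (cells[rows, 3L] - 1L) * d[1L] + cells[rows, 1L]
        remaining <- seq_along(rows)
        for (sib in chains[[j]]) {
            if (!length(remaining)) break
            sibZ <- Z[ik[remaining], sib, drop = FALSE]
            sibO <- O[ik[remaining], sib, drop = FALSE]
            cnt <- rowSums(sibO)
            est <- rowSums(sibZ) / cnt
            got <- which(cnt > 0L)
            if (length(got)) {
                out[rows[remaining[got]]] <- est[got]
                remaining <- remaining[-got]
            }
        }
    }
    out
}

#' MAHC multiple imputation
#'
#' For each imputation \eqn{h}: draw \eqn{K_h} uniformly from
#' \eqn{\{1, \ldots, K-1\}} and sample that many attributes without
#' replacement; build the all-attribute environment tree and the subset tree
#' (Ward linkage on the missing-aware squared Euclidean distance); estimate
#' every missing value from each tree by the first-merge donor rule (the
#' subset tree only serves targets whose attribute was drawn); average the two
#' estimates when both exist. The final completed array averages the \eqn{H}
#' per-imputation estimates. With \eqn{K = 1} only the all-attribute tree is
#' used.
#'
#' @param std a \code{\linkS4class{StandardizedMET}} with missing entries.
#' @param H number of imputations (default 100).
#' @param seed master seed; each imputation gets an independent derived
#'   stream, so results are order-independent and bit-reproducible.
#' @param cells optional precomputed \code{M x 3} index of the missing
#'   entries (defaults to all \code{NA} entries of \code{std}).
#' @return an \code{\linkS4class{ImputationResult}}.
#' @examples
#' raw <- simulateMET(metPresetConfig("dataset3", seed = 1))
#' std <- standardizeMET(raw)
#' pat <- generateMissingPattern(raw, 0.05, seed = 2)
#' res <- mahcImpute(applyPattern(std, pat), H = 5, seed = 3)
#' res
#' @export
mahcImpute <- function(std, H = 100L, seed = 1L, cells = NULL) {
    stopifnot(is(std, "StandardizedMET"), H >= 1L)
    if (is.null(cells)) cells <- which(is.na(std@values), arr.ind = TRUE)
    colnames(cells) <- c("i", "j", "k")
    K <- dim(std@values)[3L]
    seeds <- childSeeds(seed, H)
    est <- matrix(NA_real_, H, nrow(cells))
    treeFull <- wardCluster(environmentDistance(std))
    full <- .treeEstimates(treeFull, std, cells)
    for (h in seq_len(H)) {
        if (K >= 2L) {
            set.seed(seeds[h])
            Kh <- sample.int(K - 1L, 1L)
            attrs <- sort(sample.int(K, Kh))
            ## a subset leaving some environment with no observed coordinate
            ## (e.g. exactly the attribute of a wholly missing column) cannot
            ## be clustered; that imputation uses the all-attribute tree alone
            distSub <- tryCatch(environmentDistance(std, attrs),
                                error = function(e) NULL)
            if (is.null(distSub)) {
                est[h, ] <- full
            } else {
                treeSub <- wardCluster(distSub)
                sub <- .treeEstimates(treeSub, std, cells, attrs = attrs)
                est[h, ] <- ifelse(is.na(sub), full, (full + sub) / 2)
            }
        } else {
            est[h, ] <- full
        }
    }
    bad <- which(colSums(!is.na(est)) == 0L)
    if (length(bad))
        stop("cell(s) inestimable in all imputations: ",
             paste(apply(cells[bad, , drop = FALSE], 1L, paste, collapse = ","),
                   collapse = "; "))
    .finishResult(std, est, cells, "mahc", H, seed)
}

## Assemble an ImputationResult: final array = per-cell mean over imputations.
.finishResult <- function(std, est, cells, method, H, seed) {
    completed <- std@values
    if (nrow(cells))
        completed[cells] <- colMeans(est, na.rm = TRUE)
    new("ImputationResult", estimates = est,
        cells = cells, completed = completed,
        method = method, H = as.integer(H), seed = as.integer(seed))
}

setMethod("show", "ImputationResult", function(object) {
    cat(sprintf("ImputationResult (%s): H = %d imputations of %d missing entries\n",
                object@method, object@H, nrow(object@cells)))
})

#' Completed standardized array of an imputation result
#'
#' @param res an \code{\linkS4class{ImputationResult}}.
#' @param std the \code{\linkS4class{StandardizedMET}} the imputation was run
#'   on (supplies the standardization statistics).
#' @return a \code{\linkS4class{StandardizedMET}} with no missing entries.
#' @export
completedArray <- function(res, std) {
    out <- std
    out@values <- res@completed
    out
}
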