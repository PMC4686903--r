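#' @import methods
#' @importFrom stats rnorm rgamma qt qnorm sd var cor quantile setNames as.dist
NULL

#' METArray: a three-way three-mode multi-environment trial array
#'
#' Container for an \eqn{I \times J \times K} numeric array of measurements on
#' \eqn{I} genotypes grown in \eqn{J} environments and scored for \eqn{K}
#' attributes. Missing entries are carried as \code{NA}; the observed/missing
#' mask is derived from the values and available through
#' \code{\link{missingMask}}.
#'
#' @slot values numeric array of dimension \code{c(I, J, K)} with
#'   \code{dimnames} holding the genotype, environment and attribute labels.
#'   Observed entries are finite; missing entries are \code{NA}.
#'
#' @seealso \code{\link{METArray}} (constructor), \code{\link{standardizeMET}},
#'   \code{\link{simulateMET}}
#' @export
setClass("METArray", representation(values = "array"))

setValidity("METArray", function(object) {
    v <- object@values
    d <- dim(v)
    if (length(d) != 3L)
        return("'values' must be a three-way array (genotypes x environments x attributes)")
    if (d[1L] < 2L || d[2L] < 2L || d[3L] < 1L)
        return("need I >= 2 genotypes, J >= 2 environments, K >= 1 attributes")
    if (!is.numeric(v))
        return("'values' must be numeric")
    if (any(is.infinite(v)))
        return("observed entries must be finite (use NA for missing)")
    dn <- dimnames(v)
    if (is.null(dn) || any(vapply(dn, is.null, logical(1L))))
        return("'values' must carry dimnames on all three axes")
    for (ax in 1:3)
        if (anyDuplicated(dn[[ax]]))
            return(sprintf("labels on axis %d are not unique", ax))
    TRUE
})

#' StandardizedMET: column-standardized MET array
#'
#' A \code{\linkS4class{METArray}} on the column-standardized scale, i.e. each
#' environment-attribute column \eqn{x_{jk}} has been centred and scaled over
#' genotypes so that (for fully observed columns) \eqn{\sum_i \tilde x_{ijk} =
#' 0} and the sample standard deviation (denominator \eqn{I-1}) is 1. The
#' per-column location and scale are retained for the back-transform. Columns
#' with no observed entries (wholly missing columns) have \code{NA}
#' location/scale.
#'
#' @slot values standardized numeric array, as in \code{\linkS4class{METArray}}.
#' @slot colMean \code{J x K} matrix of per-column observed-entry means.
#' @slot colSd \code{J x K} matrix of per-column observed-entry standard
#'   deviations (denominator \eqn{n_{obs} - 1}), strictly positive where
#'   defined.
#'
#' @seealso \code{\link{standardizeMET}}, \code{\link{backTransform}}
#' @export
setClass("StandardizedMET", contains = "METArray",
         representation(colMean = "matrix", colSd = "matrix"))

setValidity("StandardizedMET", function(object) {
    d <- dim(object@values)
    if (!all(dim(object@colMean) == d[2:3]))
        return("'colMean' must be J x K")
    if (!all(dim(object@colSd) == d[2:3]))
        return("'colSd' must be J x K")
    if (any(object@colSd <= 0, na.rm = TRUE))
        return("'colSd' must be strictly positive where defined")
    TRUE
})

#' MissingPattern: designated missing cells and columns
#'
#' Describes which entries of a MET array are treated as missing: a set of
#' individual cells \eqn{(i, j, k)} plus zero or more wholly missing columns
#' \eqn{(j, k)} (an attribute unmeasured for every genotype in one
#' environment). Cells and the expansion of the columns are disjoint.
#'
#' @slot cells integer matrix with columns \code{i, j, k}; one row per missing
#'   cell (excluding cells inside the designated columns).
#' @slot columns integer matrix with columns \code{j, k}; one row per wholly
#'   missing environment-attribute column.
#' @slot percent nominal fraction of missing values in \eqn{(0, 1)}.
#' @slot seed integer seed the pattern was drawn with.
#' @slot dim the \code{c(I, J, K)} dimension of the array the pattern refers to.
#'
#' @seealso \code{\link{generateMissingPattern}}, \code{\link{applyPattern}}
#' @export
setClass("MissingPattern",
         representation(cells = "matrix", columns = "matrix",
                        percent = "numeric", seed = "integer", dim = "integer"))

setValidity("MissingPattern", function(object) {
    if (ncol(object@cells) != 3L) return("'cells' must have 3 columns (i, j, k)")
    if (ncol(object@columns) != 2L) return("'columns' must have 2 columns (j, k)")
    d <- object@dim
    if (length(d) != 3L) return("'dim' must be length 3")
    if (nrow(object@cells)) {
        if (any(object@cells < 1L) ||
            any(object@cells[, 1L] > d[1L]) ||
            any(object@cells[, 2L] > d[2L]) ||
            any(object@cells[, 3L] > d[3L]))
            return("cell indices out of range")
        key <- paste(object@cells[, 2L], object@cells[, 3L])
        colkey <- paste(object@columns[, 1L], object@columns[, 2L])
        if (any(key %in% colkey))
            return("cells and the expansion of columns must be disjoint")
    }
    if (object@percent <= 0 || object@percent >= 1)
        return("'percent' must lie in (0, 1)")
    TRUE
})

#' WideView: two-way wide rearrangement of a standardized MET array
#'
#' The standardized three-way array rearranged as a two-way matrix, either
#' \eqn{I \times JK} (environments nested within attributes; column
#' \eqn{(k-1)J + j}) or \eqn{J \times IK} (genotypes nested within attributes;
#' column \eqn{(k-1)I + i}). The mapping back to \eqn{(i, j, k)} is a
#' bijection, available through \code{\link{fromWide}}.
#'
#' @slot matrix the two-way numeric matrix; missing entries remain \code{NA}.
#' @slot orientation \code{"genotypes_by_env_attr"} (\eqn{I \times JK}) or
#'   \code{"env_by_geno_attr"} (\eqn{J \times IK}).
#' @slot dim3 the original \code{c(I, J, K)}.
#' @slot labels list of the three axis label vectors.
#' @export
setClass("WideView",
         representation(matrix = "matrix", orientation = "character",
                        dim3 = "integer", labels = "list"))

#' MergeTree: an agglomerative hierarchy over environments
#'
#' Result of Ward (incremental sum of squares) clustering of the \eqn{J}
#' environments. Encodes the \eqn{J - 1} merges in \code{\link[stats]{hclust}}
#' convention: negative entries refer to leaves, positive entries to earlier
#' merges. Ward linkage admits no inversions, so heights are nondecreasing.
#'
#' @slot merge integer \code{(J-1) x 2} matrix of merges.
#' @slot height numeric vector of merge heights (the Ward criterion at each
#'   merge), nonnegative and nondecreasing.
#' @slot labels leaf (environment) labels.
#' @seealso \code{\link{wardCluster}}, \code{\link{donorEstimate}}
#' @export
setClass("MergeTree",
         representation(merge = "matrix", height = "numeric", labels = "character"))

setValidity("MergeTree", function(object) {
    n <- length(object@labels)
    if (nrow(object@merge) != n - 1L)
        return("a hierarchy over J leaves must contain exactly J - 1 merges")
    if (length(object@height) != n - 1L)
        return("'height' must have one entry per merge")
    if (any(object@height < -1e-8))
        return("heights must be nonnegative")
    if (is.unsorted(object@height + 1e-8 * cummax(abs(object@height)) * 0)) {
        if (any(diff(object@height) < -1e-8 * max(abs(object@height), 1)))
            return("heights must be nondecreasing (Ward admits no inversions)")
    }
    TRUE
})

#' ImputationResult: H per-imputation estimates plus the averaged completion
#'
#' Output of the multiple-imputation engines. Holds the \eqn{H} per-imputation
#' estimates of every missing entry (standardized scale), the index of those
#' entries, and the final "estimated data array" obtained by averaging the
#' \eqn{H} imputations.
#'
#' @slot estimates numeric \code{H x M} matrix; row \eqn{h} holds imputation
#'   \eqn{h}'s estimates for the \eqn{M} missing entries. \code{NA} where an
#'   imputation could not estimate an entry (possible for MAHC in degenerate
#'   configurations).
#' @slot cells integer \code{M x 3} matrix of the missing entries' indices
#'   \code{(i, j, k)}, in a fixed order.
#' @slot completed numeric array: the input standardized values with every
#'   missing entry replaced by the average of its \eqn{H} estimates.
#' @slot method character label of the imputation method.
#' @slot H number of imputations.
#' @slot seed master seed used.
#' @seealso \code{\link{mahcImpute}}, \code{\link{normImpute}},
#'   \code{\link{nrmImpute}}, \code{\link{pmmImpute}}
#' @export
setClass("ImputationResult",
         representation(estimates = "matrix", cells = "matrix",
                        completed = "array", method = "character",
                        H = "integer", seed = "integer"))

setValidity("ImputationResult", function(object) {
    if (ncol(object@cells) != 3L) return("'cells' must have 3 columns")
    if (ncol(object@estimates) != nrow(object@cells))
        return("'estimates' must have one column per missing entry")
    if (nrow(object@estimates) != object@H)
        return("'estimates' must have H rows")
    TRUE
})
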