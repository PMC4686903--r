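## The full evaluation protocol: designate missing values in a complete
## array, impute with each method, pool 100 imputations into 5 sets of 20 for
## Rubin's-rules coverage, and score completed arrays by NRMSE.

#' Impute a standardized MET array with a named method
#'
#' Thin dispatcher over \code{\link{mahcImpute}}, \code{\link{normImpute}},
#' \code{\link{nrmImpute}} and \code{\link{pmmImpute}} using the method labels
#' of the comparison protocol.
#'
#' @param std a \code{\linkS4class{StandardizedMET}} with missing entries.
#' @param method one of \code{"mahc"}, \code{"norm-ba"}, \code{"norm-nba"},
#'   \code{"nrm-ba"}, \code{"nrm-nba"}, \code{"pmm-ba"}, \code{"pmm-nba"}.
#' @param H number of imputations.
#' @param seed master seed.
#' @param control list of method options: \code{nrmOption}, \code{pmmOption},
#'   \code{columnRule}, \code{C}, \code{nSamples}, \code{burn}, \code{tau2}.
#' @return an \code{\linkS4class{ImputationResult}}.
#' @export
imputeMissing <- function(std, method, H = 100L, seed = 1L, control = list()) {
    ctl <- modifyList(list(nrmOption = 3L, pmmOption = 4L, columnRule = "avg",
                           C = 3L, nSamples = 5500L, burn = 500L, tau2 = 1),
                      control)
    switch(method,
        "mahc" = mahcImpute(std, H = H, seed = seed),
        "norm-ba" = normImpute(std, H = H, bayes = TRUE,
                               nSamples = ctl$nSamples, burn = ctl$burn,
                               seed = seed),
        "norm-nba" = normImpute(std, H = H, bayes = FALSE, seed = seed),
        "nrm-ba" = nrmImpute(std, H = H, option = ctl$nrmOption, bayes = TRUE,
                             columnRule = ctl$columnRule,
                             nSamples = ctl$nSamples, burn = ctl$burn,
                             tau2 = ctl$tau2, seed = seed),
        "nrm-nba" = nrmImpute(std, H = H, option = ctl$nrmOption,
                              bayes = FALSE, columnRule = ctl$columnRule,
                              seed = seed),
        "pmm-ba" = pmmImpute(std, H = H, C = ctl$C, option = ctl$pmmOption,
                             bayes = TRUE, nSamples = ctl$nSamples,
                             burn = ctl$burn, tau2 = ctl$tau2, seed = seed),
        "pmm-nba" = pmmImpute(std, H = H, C = ctl$C, option = ctl$pmmOption,
                              bayes = FALSE, seed = seed),
        stop("unknown method '", method, "'; valid methods: mahc, norm-ba, ",
             "norm-nba, nrm-ba, nrm-nba, pmm-ba, pmm-nba"))
}

## Coverage of one result restricted to a subset of its missing entries.
.scopeCoverage <- function(res, truthArray, scopeRows, poolSize, poolSeed) {
    pooled <- poolImputations(res@estimates, H = poolSize, seed = poolSeed)
    truth <- truthArray[res@cells[scopeRows, , drop = FALSE]]
    ## U_h: variance of all missing-value estimates within pooled imputation h
    withinVars <- apply(pooled, 1L, var)
    suppressWarnings(
        coverageCI(truth, pooled[, scopeRows, drop = FALSE], withinVars))
}

#' Run the missing-cells coverage protocol
#'
#' Per repetition and percentage: draw a missing pattern (the stated percent
#' of all values, including one designated wholly missing column), impute
#' with each method, pool the \code{nImputations} raw imputations into
#' \code{poolSize} averaged sets, and compute the 95\% coverage over the
#' missing \emph{cells} (the designated column's entries are excluded from
#' the coverage, which is why the cell percentage is slightly below the
#' nominal percent). Patterns are shared across methods and nested across
#' percentages within a repetition (common random numbers), and every
#' repetition gets an independent derived seed.
#'
#' @param raw a fully observed \code{\linkS4class{METArray}}.
#' @param methods method labels (see \code{\link{imputeMissing}}).
#' @param percents percentages of missing values (default \code{c(5, 10, 15,
#'   20, 25)}).
#' @param reps repetitions (default 10).
#' @param nImputations raw imputations per run (default 100).
#' @param poolSize pooled sets for Rubin's rules (default 5).
#' @param seed master seed.
#' @param control method options (see \code{\link{imputeMissing}}).
#' @return data.frame with columns \code{method, percent, repetition,
#'   coverage, nMissingCells}.
#' @export
runCellsProtocol <- function(raw, methods = "mahc",
                             percents = c(5, 10, 15, 20, 25), reps = 10L,
                             nImputations = 100L, poolSize = 5L, seed = 1L,
                             control = list()) {
    std <- standardizeMET(raw)
    truth <- std@values
    repSeeds <- childSeeds(seed, reps)
    out <- list()
    for (r in seq_len(reps)) {
        s <- childSeeds(repSeeds[r], 3L + length(methods))
        maxPat <- generateMissingPattern(raw, max(percents) / 100,
                                         nColumns = 1L, seed = s[1L])
        for (pct in sort(percents, decreasing = TRUE)) {
            pat <- .shrinkPattern(maxPat, pct / 100, seed = s[2L])
            stdm <- applyPattern(std, pat)
            cells <- patternCells(pat, expand = TRUE)
            nCells <- nrow(pat@cells)
            scopeRows <- seq_len(nCells)     # individual cells come first
            for (m in seq_along(methods)) {
                res <- imputeMissing(stdm, methods[m], H = nImputations,
                                     seed = s[3L + m], control = control)
                cov <- .scopeCoverage(res, truth, scopeRows, poolSize,
                                      poolSeed = s[3L])
                out[[length(out) + 1L]] <- data.frame(
                    method = methods[m], percent = pct, repetition = r,
                    coverage = cov$coverage, nMissingCells = nCells)
            }
        }
    }
    do.call(rbind, out)
}

## Sub-sample a pattern drawn at its maximum percent down to a lower percent,
## keeping the designated column(s) and a uniform subset of the cells.
.shrinkPattern <- function(pattern, percent, seed) {
    total <- round(percent * prod(pattern@dim))
    nCol <- nrow(pattern@columns) * pattern@dim[1L]
    nCells <- total - nCol
    if (nCells < 0L)
        stop("percent ", 100 * percent, "% is too small to contain the ",
             "designated missing column(s) on this array")
    stopifnot(nCells <= nrow(pattern@cells))
    if (nCells == nrow(pattern@cells)) {
        keep <- seq_len(nCells)
    } else {
        set.seed(seed + nCells)
        keep <- sort(sample.int(nrow(pattern@cells), nCells))
    }
    new("MissingPattern", cells = pattern@cells[keep, , drop = FALSE],
        columns = pattern@columns, percent = percent,
        seed = pattern@seed, dim = pattern@dim)
}

#' Run the missing-column coverage protocol
#'
#' For each attribute, each environment of \code{envs} (all \eqn{J} when
#' \eqn{J \le 10}, else 10 drawn without replacement) is designated in turn as
#' the wholly missing column; the \code{nImputations} imputations are pooled
#' and the coverage computed over the column's \eqn{I} values. The
#' environments play the role of repetitions.
#'
#' @inheritParams runCellsProtocol
#' @param attrs attribute indices to evaluate (default all).
#' @return data.frame with columns \code{method, attribute, environment,
#'   coverage}.
#' @export
runColumnProtocol <- function(raw, methods = "mahc", attrs = NULL,
                              nImputations = 100L, poolSize = 5L, seed = 1L,
                              control = list()) {
    std <- standardizeMET(raw)
    truth <- std@values
    d <- dim(raw@values)
    J <- d[2L]
    if (is.null(attrs)) attrs <- seq_len(d[3L])
    set.seed(seed)
    envs <- if (J <= 10L) seq_len(J) else sort(sample.int(J, 10L))
    seeds <- childSeeds(seed, length(attrs) * length(envs) * length(methods) + 1L)
    out <- list()
    idx <- 0L
    for (k in attrs) {
        for (j in envs) {
            pat <- columnPattern(raw, j, k)
            stdm <- applyPattern(std, pat)
            for (m in seq_along(methods)) {
                idx <- idx + 1L
                res <- imputeMissing(stdm, methods[m], H = nImputations,
                                     seed = seeds[idx], control = control)
                cov <- .scopeCoverage(res, truth,
                                      seq_len(nrow(res@cells)), poolSize,
                                      poolSeed = seeds[length(seeds)])
                out[[length(out) + 1L]] <- data.frame(
                    method = methods[m], attribute = k, environment = j,
                    coverage = cov$coverage)
            }
        }
    }
    do.call(rbind, out)
}

#' Run the overall-missing NRMSE protocol
#'
#' Per repetition and percentage: draw a pattern (cells plus one designated
#' column), form each method's final estimated data array by averaging all
#' raw imputations (the EM/Tucker3 baseline is a single imputation), and
#' score it by \code{\link{nrmse}} against the original array.
#'
#' @inheritParams runCellsProtocol
#' @param methods method labels; \code{"em"} adds the Tucker3-EM baseline.
#' @param emDims Tucker3 core dimensions for the EM baseline.
#' @return data.frame with columns \code{method, percent, repetition, nrmse}.
#' @export
runNrmseProtocol <- function(raw, methods = c("mahc", "em"),
                             percents = c(5, 10, 15, 20, 25), reps = 10L,
                             nImputations = 100L, seed = 1L,
                             emDims = c(2L, 2L, 2L), control = list()) {
    std <- standardizeMET(raw)
    repSeeds <- childSeeds(seed, reps)
    out <- list()
    for (r in seq_len(reps)) {
        s <- childSeeds(repSeeds[r], 2L + length(methods))
        maxPat <- generateMissingPattern(raw, max(percents) / 100,
                                         nColumns = 1L, seed = s[1L])
        for (pct in sort(percents, decreasing = TRUE)) {
            pat <- .shrinkPattern(maxPat, pct / 100, seed = s[2L])
            stdm <- applyPattern(std, pat)
            for (m in seq_along(methods)) {
                completed <- if (methods[m] == "em") {
                    tucker3EM(stdm, dims = emDims)$completed
                } else {
                    imputeMissing(stdm, methods[m], H = nImputations,
                                  seed = s[2L + m], control = control)@completed
                }
                out[[length(out) + 1L]] <- data.frame(
                    method = methods[m], percent = pct, repetition = r,
                    nrmse = nrmse(std, completed))
            }
        }
    }
    do.call(rbind, out)
}

#' Summarize protocol output as means and standard errors
#'
#' @param df output of one of the protocol runners.
#' @param value name of the value column (\code{"coverage"} or
#'   \code{"nrmse"}).
#' @param by grouping columns (default \code{method} and whichever of
#'   \code{percent}/\code{attribute} is present).
#' @return data.frame of group means and standard errors of the mean.
#' @export
summarizeProtocol <- function(df, value = c("coverage", "nrmse"), by = NULL) {
    value <- match.arg(value)
    if (is.null(by))
        by <- intersect(c("method", "percent", "attribute"), names(df))
    agg <- aggregate(df[[value]], df[by], function(x)
        c(mean = mean(x), se = sd(x) / sqrt(length(x))))
    out <- cbind(agg[by], agg$x)
    names(out)[(ncol(out) - 1L):ncol(out)] <- c("mean", "se")
    out
}
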