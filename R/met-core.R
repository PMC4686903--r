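#' Construct a METArray
#'
#' @param values numeric three-way array (\code{I x J x K}) or a vector that
#'   can be shaped to \code{dim}. Missing entries are \code{NA}.
#' @param genotypeIds,environmentIds,attributeIds optional label vectors; if
#'   omitted, defaults \code{G1..GI}, \code{E1..EJ}, \code{A1..AK} are used (or
#'   existing dimnames are kept).
#' @param dim optional \code{c(I, J, K)} when \code{values} is a plain vector.
#' @return a \code{\linkS4class{METArray}}.
#' @examples
#' x <- METArray(array(rnorm(24), c(4, 3, 2)))
#' dim(x)
#' @export
METArray <- function(values, genotypeIds = NULL, environmentIds = NULL,
                     attributeIds = NULL, dim = NULL) {
    if (!is.null(dim)) dim(values) <- dim
    d <- base::dim(values)
    stopifnot("values must be a three-way array" = length(d) == 3L)
    dn <- dimnames(values)
    if (is.null(dn)) dn <- vector("list", 3L)
    if (!is.null(genotypeIds))    dn[[1L]] <- genotypeIds
    if (!is.null(environmentIds)) dn[[2L]] <- environmentIds
    if (!is.null(attributeIds))   dn[[3L]] <- attributeIds
    defaults <- list(paste0("G", seq_len(d[1L])), paste0("E", seq_len(d[2L])),
                     paste0("A", seq_len(d[3L])))
    for (ax in 1:3) if (is.null(dn[[ax]])) dn[[ax]] <- defaults[[ax]]
    dimnames(values) <- dn
    new("METArray", values = values)
}

#' Accessors for MET containers
#'
#' \code{metValues} returns the raw three-way array; \code{missingMask} the
#' logical array that is \code{TRUE} where an entry is observed;
#' \code{genotypeIds}, \code{environmentIds} and \code{attributeIds} the axis
#' labels; \code{colMean}/\code{colSd} the per-column standardization
#' statistics of a \code{\linkS4class{StandardizedMET}}.
#'
#' @param x a \code{\linkS4class{METArray}} (or subclass).
#' @return see description.
#' @aliases missingMask genotypeIds environmentIds attributeIds colMean colSd
#' @export
metValues <- function(x) x@values

#' @rdname metValues
#' @export
missingMask <- function(x) !is.na(x@values)

#' @rdname metValues
#' @export
genotypeIds <- function(x) dimnames(x@values)[[1L]]

#' @rdname metValues
#' @export
environmentIds <- function(x) dimnames(x@values)[[2L]]

#' @rdname metValues
#' @export
attributeIds <- function(x) dimnames(x@values)[[3L]]

#' @rdname metValues
#' @export
colMean <- function(x) x@colMean

#' @rdname metValues
#' @export
colSd <- function(x) x@colSd

#' @export
setMethod("dim", "METArray", function(x) dim(x@values))

setMethod("show", "METArray", function(object) {
    d <- dim(object@values)
    nmiss <- sum(is.na(object@values))
    cat(sprintf("%s: %d genotypes x %d environments x %d attributes\n",
                class(object), d[1L], d[2L], d[3L]))
    cat(sprintf("  missing entries: %d of %d (%.1f%%)\n",
                nmiss, prod(d), 100 * nmiss / prod(d)))
})

## ---------------------------------------------------------------------------
## Column standardization
## ---------------------------------------------------------------------------

#' Column-standardize a MET array
#'
#' Centres and scales every environment-attribute column \eqn{x_{jk}} over the
#' genotypes, removing environment main effects while preserving the
#' within-environment correlations among attributes. Statistics are computed
#' over observed entries only (denominator \eqn{n_{obs} - 1} for the scale).
#' Wholly missing columns are permitted and flagged with \code{NA}
#' location/scale; a column with exactly one observed value or zero variance
#' is an error.
#'
#' @param x a \code{\linkS4class{METArray}}.
#' @return a \code{\linkS4class{StandardizedMET}}.
#' @examples
#' x <- METArray(array(rnorm(24, 10, 2), c(4, 3, 2)))
#' s <- standardizeMET(x)
#' round(colSums(metValues(s)[, 1, ]), 10)  # environment effects removed
#' @export
standardizeMET <- function(x) {
    stopifnot(is(x, "METArray"))
    v <- x@values
    d <- dim(v)
    m <- matrix(v, d[1L], d[2L] * d[3L])        # columns are (j, k), j fastest
    nobs <- colSums(!is.na(m))
    bad <- which(nobs == 1L)
    if (length(bad))
        stop("column(s) with a single observed value: ",
             .colLabel(bad, d, dimnames(v)))
    mu <- colMeans(m, na.rm = TRUE)
    sdv <- apply(m, 2L, sd, na.rm = TRUE)
    mu[nobs == 0L] <- NA_real_
    sdv[nobs == 0L] <- NA_real_
    zero <- which(nobs >= 2L & sdv == 0)
    if (length(zero))
        stop("column(s) with zero variance: ", .colLabel(zero, d, dimnames(v)))
    z <- sweep(sweep(m, 2L, mu, "-"), 2L, sdv, "/")
    dim(z) <- d
    dimnames(z) <- dimnames(v)
    new("StandardizedMET", values = z,
        colMean = matrix(mu, d[2L], d[3L],
                         dimnames = dimnames(v)[2:3]),
        colSd = matrix(sdv, d[2L], d[3L],
                       dimnames = dimnames(v)[2:3]))
}

.colLabel <- function(idx, d, dn) {
    j <- (idx - 1L) %% d[2L] + 1L
    k <- (idx - 1L) %/% d[2L] + 1L
    paste(sprintf("(%s, %s)", dn[[2L]][j], dn[[3L]][k]), collapse = ", ")
}

#' Back-transform a standardized MET array to the raw scale
#'
#' Inverts \code{\link{standardizeMET}}: \eqn{x = \tilde x \cdot s_{jk} +
#' \bar x_{.jk}}. Entries in wholly missing columns (undefined location/scale)
#' stay \code{NA}.
#'
#' @param std a \code{\linkS4class{StandardizedMET}}.
#' @param values optional replacement array on the standardized scale (e.g. a
#'   completed array); defaults to the stored values.
#' @return a \code{\linkS4class{METArray}} on the raw scale.
#' @export
backTransform <- function(std, values = NULL) {
    stopifnot(is(std, "StandardizedMET"))
    v <- if (is.null(values)) std@values else values
    d <- dim(std@values)
    m <- matrix(v, d[1L], d[2L] * d[3L])
    m <- sweep(sweep(m, 2L, as.vector(std@colSd), "*"), 2L,
               as.vector(std@colMean), "+")
    dim(m) <- d
    dimnames(m) <- dimnames(std@values)
    new("METArray", values = m)
}

## ---------------------------------------------------------------------------
## Wide views
## ---------------------------------------------------------------------------

#' Rearrange a standardized MET array as a two-way wide matrix
#'
#' \code{"genotypes_by_env_attr"} gives the \eqn{I \times JK} matrix whose
#' columns are environments nested within attributes (column \eqn{(k-1)J +
#' j}); \code{"env_by_geno_attr"} gives the \eqn{J \times IK} matrix with
#' genotypes nested within attributes (column \eqn{(k-1)I + i}). A wholly
#' missing \eqn{(j, k)} column shows up as an all-missing column only in the
#' first orientation; in the second, its entries are spread over rows, which
#' is what makes environment-mode clustering possible for missing columns.
#'
#' @param std a \code{\linkS4class{StandardizedMET}} (any
#'   \code{\linkS4class{METArray}} is accepted).
#' @param orientation one of \code{"genotypes_by_env_attr"},
#'   \code{"env_by_geno_attr"}.
#' @return a \code{\linkS4class{WideView}}.
#' @seealso \code{\link{fromWide}}, \code{\link{wideIndex}}
#' @export
toWide <- function(std, orientation = c("genotypes_by_env_attr",
                                        "env_by_geno_attr")) {
    orientation <- match.arg(orientation)
    v <- std@values
    d <- dim(v)
    dn <- dimnames(v)
    if (orientation == "genotypes_by_env_attr") {
        m <- matrix(v, d[1L], d[2L] * d[3L])
        dimnames(m) <- list(dn[[1L]],
                            paste(rep(dn[[3L]], each = d[2L]), dn[[2L]], sep = "."))
    } else {
        m <- matrix(aperm(v, c(2L, 1L, 3L)), d[2L], d[1L] * d[3L])
        dimnames(m) <- list(dn[[2L]],
                            paste(rep(dn[[3L]], each = d[1L]), dn[[1L]], sep = "."))
    }
    new("WideView", matrix = m, orientation = orientation,
        dim3 = as.integer(d), labels = dn)
}

#' Map wide-matrix coordinates back to (i, j, k)
#'
#' @param wide a \code{\linkS4class{WideView}}.
#' @param row,col coordinates in the wide matrix (vectorized).
#' @return integer matrix with columns \code{i, j, k}.
#' @export
wideIndex <- function(wide, row, col) {
    d <- wide@dim3
    if (wide@orientation == "genotypes_by_env_attr") {
        cbind(i = row,
              j = (col - 1L) %% d[2L] + 1L,
              k = (col - 1L) %/% d[2L] + 1L)
    } else {
        cbind(i = (col - 1L) %% d[1L] + 1L,
              j = row,
              k = (col - 1L) %/% d[1L] + 1L)
    }
}

#' Reconstruct the three-way array from a wide view
#'
#' @param wide a \code{\linkS4class{WideView}}.
#' @return numeric three-way array with the original dimnames.
#' @export
fromWide <- function(wide) {
    d <- wide@dim3
    if (wide@orientation == "genotypes_by_env_attr") {
        a <- array(wide@matrix, d)
    } else {
        a <- aperm(array(wide@matrix, c(d[2L], d[1L], d[3L])), c(2L, 1L, 3L))
    }
    dimnames(a) <- wide@labels
    a
}

## ---------------------------------------------------------------------------
## Missing-pattern generation
## ---------------------------------------------------------------------------

#' Draw a random missing pattern for an observed MET array
#'
#' Selects \code{nColumns} distinct environment-attribute columns uniformly to
#' be wholly missing, then draws the remaining missing cells uniformly without
#' replacement from the cells outside those columns, so that the total count
#' equals \code{round(percent * I * J * K)}. Patterns that would leave any
#' genotype-attribute row \eqn{x'_{ik}} with no observed environment are
#' rejected and redrawn (up to 1000 times): missing rows are outside the
#' supported designs.
#'
#' @param x a fully observed \code{\linkS4class{METArray}}.
#' @param percent fraction of missing values in \eqn{(0, 1)}.
#' @param nColumns number of wholly missing columns (default 1).
#' @param seed integer seed; the pattern is reproducible given the seed.
#' @return a \code{\linkS4class{MissingPattern}}.
#' @examples
#' x <- METArray(array(rnorm(58 * 8 * 6), c(58, 8, 6)))
#' p <- generateMissingPattern(x, 0.05, nColumns = 1, seed = 1)
#' nrow(patternCells(p, expand = TRUE))  # round(0.05 * 2784) = 139
#' @export
generateMissingPattern <- function(x, percent, nColumns = 1L, seed) {
    stopifnot(is(x, "METArray"))
    if (percent <= 0 || percent >= 1)
        stop("'percent' must lie in (0, 1)")
    if (anyNA(x@values))
        stop("'x' must be fully observed to designate missing values")
    d <- dim(x@values)
    I <- d[1L]; J <- d[2L]; K <- d[3L]
    total <- round(percent * I * J * K)
    nColumns <- as.integer(nColumns)
    if (total < I * nColumns)
        stop("percent too small for ", nColumns, " wholly missing column(s)")
    set.seed(seed)
    for (attempt in seq_len(1000L)) {
        colIdx <- sample.int(J * K, nColumns)
        cols <- cbind(j = (colIdx - 1L) %% J + 1L, k = (colIdx - 1L) %/% J + 1L)
        nCells <- total - I * nColumns
        inCol <- rep(FALSE, I * J * K)
        for (r in seq_len(nColumns)) {
            jk <- (cols[r, 2L] - 1L) * J + cols[r, 1L]
            inCol[(jk - 1L) * I + seq_len(I)] <- TRUE
        }
        pool <- which(!inCol)
        cellIdx <- if (nCells > 0L) sample(pool, nCells) else integer(0L)
        cells <- cbind(i = (cellIdx - 1L) %% I + 1L,
                       j = ((cellIdx - 1L) %/% I) %% J + 1L,
                       k = (cellIdx - 1L) %/% (I * J) + 1L)
        if (!.emptiesRow(cells, cols, d)) {
            pat <- new("MissingPattern", cells = cells, columns = cols,
                       percent = percent, seed = as.integer(seed),
                       dim = as.integer(d))
            return(pat)
        }
    }
    stop("could not draw a pattern without a fully missing genotype row ",
         "in 1000 attempts; lower 'percent'")
}

## TRUE if the pattern leaves some (i, k) row with all J environments missing
.emptiesRow <- function(cells, cols, d) {
    miss <- matrix(0L, d[1L] * d[3L], 1L)
    cnt <- integer(d[1L] * d[3L])
    if (nrow(cells)) {
        ik <- (cells[, 3L] - 1L) * d[1L] + cells[, 1L]
        tab <- tabulate(ik, nbins = d[1L] * d[3L])
        cnt <- cnt + tab
    }
    if (nrow(cols)) {
        for (r in seq_len(nrow(cols))) {
            k <- cols[r, 2L]
            cnt[(k - 1L) * d[1L] + seq_len(d[1L])] <-
                cnt[(k - 1L) * d[1L] + seq_len(d[1L])] + 1L
        }
    }
    any(cnt >= d[2L])
}

#' Designate a single wholly missing column
#'
#' Convenience constructor for the missing-column-only protocol: environment
#' \code{j}, attribute \code{k} missing for every genotype, no further cells.
#'
#' @param x a \code{\linkS4class{METArray}}.
#' @param j,k environment and attribute indices.
#' @return a \code{\linkS4class{MissingPattern}}.
#' @export
columnPattern <- function(x, j, k) {
    d <- dim(x@values)
    new("MissingPattern",
        cells = matrix(integer(0L), 0L, 3L,
                       dimnames = list(NULL, c("i", "j", "k"))),
        columns = cbind(j = as.integer(j), k = as.integer(k)),
        percent = d[1L] / prod(d), seed = NA_integer_, dim = as.integer(d))
}

#' All missing entries of a pattern
#'
#' @param pattern a \code{\linkS4class{MissingPattern}}.
#' @param expand if \code{TRUE} (default) the wholly missing columns are
#'   expanded to their \eqn{I} cells and appended after the individual cells;
#'   otherwise only the individual cells are returned.
#' @return integer matrix with columns \code{i, j, k}. The first
#'   \code{nrow(patternCells(p, expand = FALSE))} rows are the individual
#'   cells, the remainder the column cells, in column order.
#' @export
patternCells <- function(pattern, expand = TRUE) {
    cells <- pattern@cells
    if (!expand || nrow(pattern@columns) == 0L)
        return(cells)
    I <- pattern@dim[1L]
    extra <- do.call(rbind, lapply(seq_len(nrow(pattern@columns)), function(r)
        cbind(i = seq_len(I), j = pattern@columns[r, 1L],
              k = pattern@columns[r, 2L])))
    rbind(cells, extra)
}

#' Apply a missing pattern to a MET array
#'
#' Masks the pattern's cells and columns with \code{NA}. Works on raw or
#' standardized arrays; class and standardization statistics are preserved.
#'
#' @param x a \code{\linkS4class{METArray}} or
#'   \code{\linkS4class{StandardizedMET}}.
#' @param pattern a \code{\linkS4class{MissingPattern}} drawn for an array of
#'   the same dimension.
#' @return an object of the same class as \code{x} with entries masked.
#' @export
applyPattern <- function(x, pattern) {
    stopifnot(all(dim(x@values) == pattern@dim))
    v <- x@values
    idx <- patternCells(pattern, expand = TRUE)
    if (nrow(idx)) v[idx] <- NA_real_
    out <- x
    out@values <- v
    out
}

setMethod("show", "MissingPattern", function(object) {
    cat(sprintf("MissingPattern: %d cells + %d column(s) on a %s array (%.1f%% nominal, seed %d)\n",
                nrow(object@cells), nrow(object@columns),
                paste(object@dim, collapse = "x"),
                100 * object@percent, object@seed))
})

## ---------------------------------------------------------------------------
## File I/O
## ---------------------------------------------------------------------------

#' Read / write MET arrays as long-format CSV
#'
#' The long format has header \code{genotype,environment,attribute,value},
#' one row per cell; a missing cell has an empty value field. Axis ordering
#' follows first appearance in the file.
#'
#' @param path file path.
#' @param x a \code{\linkS4class{METArray}}.
#' @return \code{readMETLong} returns a \code{\linkS4class{METArray}};
#'   \code{writeMETLong} returns \code{path} invisibly.
#' @export
readMETLong <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "character",
                                         "numeric"))
    need <- c("genotype", "environment", "attribute", "value")
    if (!all(need %in% names(df)))
        stop("long CSV must have header genotype,environment,attribute,value")
    g <- unique(df$genotype); e <- unique(df$environment); a <- unique(df$attribute)
    v <- array(NA_real_, c(length(g), length(e), length(a)),
               dimnames = list(g, e, a))
    v[cbind(match(df$genotype, g), match(df$environment, e),
            match(df$attribute, a))] <- df$value
    new("METArray", values = v)
}

#' @rdname readMETLong
#' @export
writeMETLong <- function(x, path) {
    v <- x@values
    d <- dim(v)
    dn <- dimnames(v)
    df <- data.frame(
        genotype = rep(dn[[1L]], times = d[2L] * d[3L]),
        environment = rep(rep(dn[[2L]], each = d[1L]), times = d[3L]),
        attribute = rep(dn[[3L]], each = d[1L] * d[2L]),
        value = as.vector(v))
    utils::write.csv(df, path, row.names = FALSE, na = "")
    invisible(path)
}

#' Read / write MET arrays as per-attribute frontal slices
#'
#' Each attribute is stored as a CSV matrix of genotypes (rows) by
#' environments (columns) with row and column labels.
#'
#' @param paths named character vector of file paths; names are the attribute
#'   labels (unnamed paths get \code{A1..AK}).
#' @param x a \code{\linkS4class{METArray}}.
#' @param dir directory to write one \code{<attribute>.csv} per attribute into.
#' @return \code{readFrontalSlices} returns a \code{\linkS4class{METArray}};
#'   \code{writeFrontalSlices} returns the written paths invisibly.
#' @export
readFrontalSlices <- function(paths) {
    if (is.null(names(paths)) || any(names(paths) == ""))
        names(paths) <- paste0("A", seq_along(paths))
    slices <- lapply(paths, function(p)
        as.matrix(utils::read.csv(p, row.names = 1L, check.names = FALSE)))
    d1 <- dim(slices[[1L]])
    if (!all(vapply(slices, function(s) all(dim(s) == d1), logical(1L))))
        stop("all frontal slices must share genotype and environment sets")
    v <- array(NA_real_, c(d1, length(slices)),
               dimnames = c(dimnames(slices[[1L]]), list(names(paths))))
    for (k in seq_along(slices)) v[, , k] <- slices[[k]]
    new("METArray", values = v)
}

#' @rdname readFrontalSlices
#' @export
writeFrontalSlices <- function(x, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    v <- x@values
    paths <- character(0L)
    for (k in seq_len(dim(v)[3L])) {
        p <- file.path(dir, paste0(dimnames(v)[[3L]][k], ".csv"))
        utils::write.csv(v[, , k], p, na = "")
        paths <- c(paths, p)
    }
    invisible(paths)
}

#' Read / write missing patterns as JSON
#'
#' Cells and columns are stored zero-based (keys \code{cells}, \code{columns},
#' \code{seed}, \code{percent}, \code{dim}).
#'
#' @param pattern a \code{\linkS4class{MissingPattern}}.
#' @param path file path.
#' @return \code{readPattern} returns a \code{\linkS4class{MissingPattern}}.
#' @export
writePattern <- function(pattern, path) {
    obj <- list(cells = unname(pattern@cells - 1L),
                columns = unname(pattern@columns - 1L),
                seed = pattern@seed, percent = pattern@percent,
                dim = pattern@dim)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writePattern
#' @export
readPattern <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    asMat <- function(m, nc) {
        if (length(m) == 0L) matrix(integer(0L), 0L, nc) else
            matrix(as.integer(m), ncol = nc) + 1L
    }
    new("MissingPattern", cells = asMat(obj$cells, 3L),
        columns = asMat(obj$columns, 2L),
        percent = obj$percent, seed = as.integer(obj$seed),
        dim = as.integer(obj$dim))
}
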