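## Variance-components simulator for fixture MET arrays. Values follow the
## mixed-model structure x_ijk = g_ik + e_jk + (ge)_ijk + eps_ijk with
## per-attribute variance components and cross-attribute correlation confined
## to the genotype effects (the only effects with non-zero off-diagonal
## covariance).

#' Simulation configuration for a MET array
#'
#' @param I,J,K numbers of genotypes, environments, attributes.
#' @param varG,varE,varGE,varEps per-attribute variance components (scalars
#'   recycled, or length-\code{K} vectors), all \eqn{\ge 0}.
#' @param attrCorr \code{K x K} genotype cross-attribute correlation matrix
#'   (symmetric positive semidefinite, unit diagonal); default exchangeable
#'   with off-diagonal \code{rho}.
#' @param rho off-diagonal of the default exchangeable \code{attrCorr}.
#' @param seed integer seed.
#' @return a validated list of class \code{"SimConfig"}.
#' @seealso \code{\link{simulateMET}}, \code{\link{metPresetConfig}}
#' @export
simConfig <- function(I, J, K, varG = 0.3, varE = 0.2, varGE = 0.2,
                      varEps = 0.3, attrCorr = NULL, rho = 0.5, seed = 1L) {
    varG <- rep_len(varG, K); varE <- rep_len(varE, K)
    varGE <- rep_len(varGE, K); varEps <- rep_len(varEps, K)
    if (any(c(varG, varE, varGE, varEps) < 0))
        stop("variance components must be nonnegative")
    if (is.null(attrCorr)) {
        attrCorr <- matrix(rho, K, K)
        diag(attrCorr) <- 1
    }
    stopifnot(all(dim(attrCorr) == K))
    if (max(abs(attrCorr - t(attrCorr))) > 1e-8 ||
        max(abs(diag(attrCorr) - 1)) > 1e-8)
        stop("'attrCorr' must be symmetric with unit diagonal")
    ev <- eigen(attrCorr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
        stop("'attrCorr' must be positive semidefinite")
    structure(list(I = as.integer(I), J = as.integer(J), K = as.integer(K),
                   varG = varG, varE = varE, varGE = varGE, varEps = varEps,
                   attrCorr = attrCorr, seed = as.integer(seed)),
              class = "SimConfig")
}

#' Simulate a fully observed MET array
#'
#' Draws \eqn{x_{ijk} = g_{ik} + e_{jk} + (ge)_{ijk} + \epsilon_{ijk}}: the
#' genotype effects \eqn{g_{i\cdot}} jointly multivariate normal across
#' attributes with covariance \eqn{D^{1/2}\,C\,D^{1/2}} (\eqn{D =
#' \mathrm{diag}(\sigma^2_{G,k})}, \eqn{C} the attribute correlation), and
#' environment, interaction and residual effects independent zero-mean
#' normals with their per-attribute variances.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return a fully observed \code{\linkS4class{METArray}}.
#' @examples
#' x <- simulateMET(simConfig(20, 5, 3, seed = 7))
#' dim(x)
#' @export
simulateMET <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed)
    I <- cfg$I; J <- cfg$J; K <- cfg$K
    Dh <- diag(sqrt(cfg$varG), K)
    Sg <- Dh %*% cfg$attrCorr %*% Dh
    ## genotype effects: I draws from N(0, Sg) across attributes
    ev <- eigen(Sg, symmetric = TRUE)
    rootSg <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), K) %*% t(ev$vectors)
    g <- matrix(rnorm(I * K), I, K) %*% rootSg                      # I x K
    e <- matrix(rnorm(J * K), J, K) * rep(sqrt(cfg$varE), each = J) # J x K
    ge <- array(rnorm(I * J * K), c(I, J, K)) *
        rep(sqrt(cfg$varGE), each = I * J)
    eps <- array(rnorm(I * J * K), c(I, J, K)) *
        rep(sqrt(cfg$varEps), each = I * J)
    x <- ge + eps
    for (k in seq_len(K))
        x[, , k] <- x[, , k] + outer(g[, k], e[, k], "+")
    METArray(x)
}

## Preset sizes: two synthetic stand-ins matching the dimensions of the
## published real datasets (58x8x6 soybean-like, 50x31x4 wheat-like; purely
## simulated, not the real data) and the four simulated-trial sizes.
.presets <- list(
    dataset1_synthetic = c(58L, 8L, 6L),
    dataset2_synthetic = c(50L, 31L, 4L),
    dataset3 = c(60L, 10L, 6L),
    dataset4 = c(80L, 15L, 6L),
    dataset5 = c(100L, 20L, 5L),
    dataset6 = c(120L, 60L, 4L))

#' Named preset simulation configurations
#'
#' Fixture configurations with the component split (0.3, 0.2, 0.2, 0.3) over
#' (G, E, GE, residual), unit total variance per attribute, and genotype
#' cross-attribute correlation 0.5. \code{dataset3}..\code{dataset6} mirror
#' the simulated-trial sizes (60x10x6, 80x15x6, 100x20x5, 120x60x4);
#' \code{dataset1_synthetic} (58x8x6) and \code{dataset2_synthetic} (50x31x4)
#' are synthetic stand-ins at the dimensions of the real soybean and wheat
#' trials and carry no real data.
#'
#' @param name one of \code{names(metPresets())}.
#' @param seed integer seed.
#' @return a \code{\link{simConfig}}.
#' @export
metPresetConfig <- function(name, seed = 1L) {
    if (!name %in% names(.presets))
        stop("unknown preset '", name, "'; available: ",
             paste(names(.presets), collapse = ", "))
    d <- .presets[[name]]
    simConfig(d[1L], d[2L], d[3L], seed = seed)
}

#' @rdname metPresetConfig
#' @export
metPresets <- function() .presets
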