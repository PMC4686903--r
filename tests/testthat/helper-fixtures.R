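## Shared fixtures, built in code.

## A small simulated MET array under the default variance-component split.
makeArray <- function(I = 20L, J = 6L, K = 3L, seed = 1L, ...) {
    simulateMET(simConfig(I, J, K, seed = seed, ...))
}

## A standardized array with a pattern applied; returns pieces needed by most
## imputer tests.
makeMasked <- function(I = 20L, J = 6L, K = 3L, percent = 0.1,
                       seedData = 1L, seedPattern = 2L, nColumns = 1L) {
    raw <- makeArray(I, J, K, seed = seedData)
    std <- standardizeMET(raw)
    pat <- generateMissingPattern(raw, percent, nColumns = nColumns,
                                  seed = seedPattern)
    list(raw = raw, std = std, pattern = pat,
         masked = applyPattern(std, pat))
}

## Wrap a plain numeric array as a StandardizedMET with identity
## standardization statistics (handy for hand-built toys).
stdFromValues <- function(v) {
    d <- dim(v)
    if (is.null(dimnames(v)))
        dimnames(v) <- list(paste0("G", seq_len(d[1])),
                            paste0("E", seq_len(d[2])),
                            paste0("A", seq_len(d[3])))
    new("StandardizedMET", values = v,
        colMean = matrix(0, d[2], d[3]), colSd = matrix(1, d[2], d[3]))
}

## Cluster memberships after each merge step, canonicalized for comparison
## across implementations (list of sorted member vectors, sorted by first
## element, one entry per step).
mergePartitions <- function(merge) {
    n <- nrow(merge) + 1L
    members <- vector("list", nrow(merge))
    out <- vector("list", nrow(merge))
    for (s in seq_len(nrow(merge))) {
        grab <- function(node) if (node < 0L) -node else members[[node]]
        members[[s]] <- sort(c(grab(merge[s, 1L]), grab(merge[s, 2L])))
        live <- members[seq_len(s)]
        absorbed <- logical(s)
        for (t in seq_len(s))
            absorbed[t] <- any(vapply(seq_len(s)[-t], function(u)
                all(members[[t]] %in% members[[u]]), logical(1L)))
        clusters <- members[seq_len(s)][!absorbed]
        singles <- setdiff(seq_len(n), unlist(clusters))
        part <- c(clusters, as.list(singles))
        part <- part[order(vapply(part, min, numeric(1L)))]
        out[[s]] <- part
    }
    out
}
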