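#' Project source-level connectivity onto atlas nodes
#'
#' Converts an IC x IC band-connectivity array into node x node
#' connectivity by dipole-density weighting: the value for node pair
#' (target B <- source A) is the weighted mean of all IC-pair values,
#' each IC pair (t <- s, s != t) weighted by
#' `w_s(A) * w_t(B)` (the probability that the source IC belongs to node
#' A and the target IC to node B). Self-pairs (same IC as source and
#' target) are always excluded, so a single IC spanning two nodes cannot
#' manufacture node-to-node flow. Node pairs receiving zero total weight
#' are missing (`NA`), not zero.
#'
#' @param icConn a source-level [BandConnectivity].
#' @param densities weight matrix from [dipoleDensity()], one row per
#'   source channel.
#' @param atlas an [Atlas] (defines the node set and ordering).
#' @return A node-level [BandConnectivity].
#' @export
projectConnectivity <- function(icConn, densities, atlas) {
    stopifnot(is(icConn, "BandConnectivity"), is(atlas, "Atlas"))
    nIc <- dim(icConn@values)[1]
    if (nrow(densities) != nIc)
        stop("need one density row per source channel (", nIc, "), got ",
             nrow(densities))
    if (!identical(colnames(densities), nodeIds(atlas)))
        stop("density columns do not match the atlas node set")
    W <- as.matrix(densities)
    cs <- colSums(W)
    D <- outer(cs, cs) - crossprod(W)          # pairwise weight totals, s != t
    nB <- length(icConn@bands)
    out <- array(NA_real_, dim = c(nNodes(atlas), nNodes(atlas), nB),
                 dimnames = list(NULL, NULL, names(icConn@bands)))
    for (b in seq_len(nB)) {
        lam <- icConn@values[, , b]
        lam[is.na(lam)] <- 0                   # masked diagonal
        diag(lam) <- 0
        ## num[i, j] = sum_t sum_s w_t(i) lam[t, s] w_s(j)
        num <- t(W) %*% lam %*% W
        val <- num / D
        val[D <= .Machine$double.eps] <- NA_real_
        out[, , b] <- val
    }
    new("BandConnectivity", bands = icConn@bands, values = out,
        nodeNames = nodeIds(atlas), level = "node")
}

#' Node-retention rule from dipole coverage
#'
#' A participant contributes to a node if at least one of their dipoles
#' has that node as its maximal-weight node. A node is retained when the
#' fraction of contributing participants reaches `threshold` (default
#' 0.65). The retained-mass fraction is the proportion of the total
#' dipole-density mass (summed weights over all dipoles of all
#' participants) falling in retained nodes.
#'
#' @param densityList list over participants of [dipoleDensity()] weight
#'   matrices (their dipoles x nodes).
#' @param atlas an [Atlas].
#' @param threshold retention threshold on participant coverage (default
#'   0.65).
#' @return data.frame with columns `node_id`, `name`, `coverage`,
#'   `retained`, plus attributes `mass_fraction` (scalar) and
#'   `threshold`. Participants with no dipoles are excluded from the
#'   denominator with a warning.
#' @export
retainNodes <- function(densityList, atlas, threshold = 0.65) {
    stopifnot(is(atlas, "Atlas"), threshold >= 0, threshold <= 1,
              length(densityList) >= 1)
    ok <- vapply(densityList, function(w) NROW(w) > 0 && any(w > 0), logical(1))
    if (any(!ok))
        warning(sum(!ok), " participant(s) with no in-atlas dipoles excluded ",
                "from coverage denominators")
    densityList <- densityList[ok]
    if (!length(densityList)) stop("no participants with dipoles")
    nN <- nNodes(atlas)
    hit <- vapply(densityList, function(w) {
        if (!identical(colnames(w), nodeIds(atlas)))
            stop("density columns do not match the atlas node set")
        rows <- which(rowSums(w) > 0)
        tabulate(vapply(rows, function(r) which.max(w[r, ]), 1L), nN) > 0
    }, logical(nN))
    coverage <- rowMeans(hit)
    retained <- coverage >= threshold
    massTotal <- Reduce(`+`, lapply(densityList, colSums))
    out <- data.frame(node_id = nodeIds(atlas), name = atlas@nodes$name,
                      coverage = coverage, retained = retained)
    attr(out, "mass_fraction") <- sum(massTotal[retained]) / sum(massTotal)
    attr(out, "threshold") <- threshold
    rownames(out) <- NULL
    out
}

#' Directed connection count per band for a node set
#'
#' With `n` retained nodes there are `n * (n - 1) / 2` node pairs per
#' band, each carrying two directed values; 47 nodes give 1081.
#'
#' @param nNodes number of retained nodes.
#' @return integer pair count.
#' @export
connectionCount <- function(nNodes) as.integer(nNodes * (nNodes - 1) / 2)
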