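## Pooled-variance two-sample t statistics for every row of M.
## g1: logical vector selecting group 1 columns.
rowTStats <- function(M, g1) {
    n1 <- sum(g1); n2 <- sum(!g1)
    m1 <- rowMeans(M[, g1, drop = FALSE]); m2 <- rowMeans(M[, !g1, drop = FALSE])
    v1 <- rowSums((M[, g1, drop = FALSE] - m1)^2) / (n1 - 1)
    v2 <- rowSums((M[, !g1, drop = FALSE] - m2)^2) / (n2 - 1)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Per-edge group-difference statistics
#'
#' Pooled two-sample t statistics (and their squares, the edgewise F) on
#' the log-transformed band connectivity of every directed edge, group 1
#' minus group 2. Edges with zero within-group variance get a missing
#' statistic with a warning; edges missing for any participant (zero
#' projection weight) are likewise left missing.
#'
#' @param cohort a [ConnectivityCohort] whose `colData` has a two-level
#'   `group` column (or supply `group` directly).
#' @param group optional vector of group labels overriding `colData`.
#' @param logTransform apply the natural log before testing (default
#'   TRUE; rPDC is positive and right-skewed).
#' @return data.frame with columns `band`, `source`, `target`, `t`,
#'   `statistic` (t squared), `p` (two-sided, uncorrected).
#' @export
edgeStatistics <- function(cohort, group = NULL, logTransform = TRUE) {
    stopifnot(is(cohort, "ConnectivityCohort"))
    if (is.null(group)) group <- colData(cohort)$group
    group <- as.factor(group)
    if (nlevels(group) != 2L) stop("exactly two groups required")
    if (min(table(group)) < 2L) stop("need at least 2 participants per group")
    M <- assay(cohort, "rpdc")
    if (logTransform) M <- log(M)
    g1 <- group == levels(group)[1]
    tt <- rowTStats(M, g1)
    bad <- !is.na(rowSums(M)) & !is.finite(tt)
    if (any(bad)) {
        warning(sum(bad), " edge(s) with zero within-group variance; statistic set to missing")
        tt[bad] <- NA_real_
    }
    tt[is.na(rowSums(M))] <- NA_real_
    df <- ncol(M) - 2L
    rd <- as.data.frame(rowData(cohort))
    data.frame(band = rd$band, source = rd$source, target = rd$target,
               t = tt, statistic = tt^2,
               p = 2 * pt(abs(tt), df, lower.tail = FALSE))
}

## Connected components of supra-threshold edges. Two directed edges are
## adjacent iff they belong to the same band and t-sign component and
## share at least one node. Returns a list of integer vectors of row
## indices into `edges`.
edgeClusters <- function(edges) {
    if (!nrow(edges)) return(list())
    key <- paste(edges$band, sign(edges$t))
    out <- list()
    for (k in unique(key)) {
        rows <- which(key == k)
        sub <- edges[rows, , drop = FALSE]
        ## chain edges touching a common node; components via igraph
        links <- NULL
        for (nd in unique(c(sub$source, sub$target))) {
            touch <- which(sub$source == nd | sub$target == nd)
            if (length(touch) > 1)
                links <- rbind(links, cbind(touch[-length(touch)], touch[-1]))
        }
        g <- igraph::make_empty_graph(n = nrow(sub), directed = FALSE)
        if (!is.null(links)) g <- igraph::add_edges(g, t(links))
        comp <- igraph::components(g)$membership
        out <- c(out, lapply(split(seq_along(comp), comp), function(i) rows[i]))
    }
    out
}

## Null cluster-mass statistic for one permutation's t vector.
nullMassFor <- function(tt, edgeInfo, tcrit, nullStat) {
    supra <- which(is.finite(tt) & abs(tt) >= tcrit)
    if (!length(supra)) return(0)
    ed <- edgeInfo[supra, , drop = FALSE]
    ed$t <- tt[supra]
    masses <- vapply(edgeClusters(ed), function(i) sum(ed$t[i]^2), numeric(1))
    if (nullStat == "max_cluster") max(masses)
    else if (length(masses) >= 2) sort(masses, decreasing = TRUE)[2] else 0
}

#' Cluster-mass permutation test of group differences
#'
#' Forms clusters of adjacent supra-threshold edges (uncorrected
#' two-sided p below `pForm`; positive and negative group differences
#' clustered separately, giving two-tailed behaviour) and compares each
#' observed cluster's summed F statistic against a null distribution of
#' cluster masses obtained by reshuffling group labels. The corrected
#' p-value of a cluster with mass m is `(1 + #{null >= m}) / (nPerm + 1)`,
#' so it can never fall below `1 / (nPerm + 1)`.
#'
#' @param cohort a [ConnectivityCohort].
#' @param group optional group labels overriding `colData(cohort)$group`.
#' @param nPerm number of label shuffles (default 2000).
#' @param pForm cluster-forming uncorrected two-sided p threshold
#'   (default 1e-4).
#' @param nullStat `"max_cluster"` (default; conservative) or
#'   `"second_largest_cluster"` (discards the single largest null
#'   cluster in each shuffle).
#' @param seed integer seed for the shuffles.
#' @param logTransform passed to the statistic computation.
#' @return A [ClusterResult]. With no supra-threshold edge the result is
#'   empty, not an error.
#' @export
permuteClusters <- function(cohort, group = NULL, nPerm = 2000L,
                            pForm = 1e-4,
                            nullStat = c("max_cluster", "second_largest_cluster"),
                            seed = 1L, logTransform = TRUE) {
    stopifnot(is(cohort, "ConnectivityCohort"), nPerm >= 100)
    nullStat <- match.arg(nullStat)
    if (is.null(group)) group <- colData(cohort)$group
    group <- as.factor(group)
    stats <- edgeStatistics(cohort, group, logTransform = logTransform)
    M <- assay(cohort, "rpdc")
    if (logTransform) M <- log(M)
    keep <- !is.na(stats$t)                    # missing edges never cluster
    Mk <- M[keep, , drop = FALSE]
    edgeInfo <- stats[keep, c("band", "source", "target"), drop = FALSE]
    nS <- ncol(M)
    df <- nS - 2L
    tcrit <- stats::qt(1 - pForm / 2, df)

    obsSupra <- which(abs(stats$t[keep]) >= tcrit)
    obsEdges <- stats[keep, ][obsSupra, , drop = FALSE]
    obsClusters <- edgeClusters(obsEdges)

    g1 <- group == levels(group)[1]
    n1 <- sum(g1); n2 <- sum(!g1)
    set.seed(seed)
    nullMass <- numeric(nPerm)
    M2 <- Mk^2
    rowTot <- rowSums(Mk); rowTot2 <- rowSums(M2)
    chunk <- max(1L, min(nPerm, floor(2e7 / max(1, nrow(Mk)))))
    done <- 0L
    while (done < nPerm) {
        k <- min(chunk, nPerm - done)
        G <- vapply(seq_len(k), function(i) as.numeric(sample(g1)), numeric(nS))
        S1 <- Mk %*% G; Q1 <- M2 %*% G
        m1 <- S1 / n1
        m2 <- (rowTot - S1) / n2
        v1 <- (Q1 - S1^2 / n1) / (n1 - 1)
        v2 <- ((rowTot2 - Q1) - (rowTot - S1)^2 / n2) / (n2 - 1)
        sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
        tperm <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
        for (i in seq_len(k))
            nullMass[done + i] <- nullMassFor(tperm[, i], edgeInfo, tcrit, nullStat)
        done <- done + k
    }

    if (length(obsClusters)) {
        mass <- vapply(obsClusters, function(i) sum(obsEdges$t[i]^2), numeric(1))
        pcorr <- vapply(mass, function(m) (1 + sum(nullMass >= m)) / (nPerm + 1),
                        numeric(1))
        ord <- order(mass, decreasing = TRUE)
        clusters <- data.frame(cluster = seq_along(ord),
                               band = vapply(obsClusters[ord], function(i)
                                   obsEdges$band[i[1]], character(1)),
                               sign = vapply(obsClusters[ord], function(i)
                                   if (obsEdges$t[i[1]] > 0) "group1>group2"
                                   else "group1<group2", character(1)),
                               n_edges = lengths(obsClusters[ord]),
                               mass = mass[ord], p_corrected = pcorr[ord])
        edges <- do.call(rbind, lapply(seq_along(ord), function(ci) {
            i <- obsClusters[[ord[ci]]]
            cbind(cluster = ci, obsEdges[i, , drop = FALSE])
        }))
        rownames(edges) <- NULL
    } else {
        clusters <- data.frame(cluster = integer(0), band = character(0),
                               sign = character(0), n_edges = integer(0),
                               mass = numeric(0), p_corrected = numeric(0))
        edges <- data.frame(cluster = integer(0), band = character(0),
                            source = character(0), target = character(0),
                            t = numeric(0), statistic = numeric(0),
                            p = numeric(0))
    }
    new("ClusterResult", clusters = clusters, edges = edges,
        edgeStats = stats, nullMass = nullMass, nPerm = as.integer(nPerm),
        pForm = pForm, nullStat = nullStat, seed = as.integer(seed))
}

#' Export significant cluster edges as a GraphML graph
#'
#' Writes the member edges of clusters with corrected p below `alpha` as
#' a directed graph (edge attributes: band, t, cluster, corrected p).
#'
#' @param result a [ClusterResult].
#' @param path output GraphML file.
#' @param alpha significance level (default 0.05).
#' @return the igraph object, invisibly.
#' @export
exportClusterGraph <- function(result, path, alpha = 0.05) {
    stopifnot(is(result, "ClusterResult"))
    keep <- result@clusters$cluster[result@clusters$p_corrected < alpha]
    ed <- result@edges[result@edges$cluster %in% keep, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
        data.frame(from = ed$source, to = ed$target, band = ed$band,
                   t = ed$t, cluster = ed$cluster),
        directed = TRUE)
    igraph::write_graph(g, path, format = "graphml")
    invisible(g)
}
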