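#' @include rpdcnet-package.R
NULL

#' Canonical EEG frequency bands
#'
#' The five canonical bands used throughout the package, as half-open
#' frequency intervals in Hz: delta \[1, 4), theta \[4, 8), alpha \[8, 14),
#' beta \[14, 30) and gamma \[30, 40\] (the last band is right-closed).
#'
#' @return Named list of length-2 numeric vectors `c(lower, upper)` in Hz.
#' @export
#' @examples
#' eegBands()
eegBands <- function() {
    list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 14),
         beta = c(14, 30), gamma = c(30, 40))
}

## Centre frequency used for band-tuned AR(2) oscillators.
bandCentres <- function(bands = eegBands()) {
    vapply(bands, function(b) mean(b), numeric(1))
}

#' Fitted multivariate autoregressive model
#'
#' Container for a least-squares MVAR(p) fit. Slot `coefficients` is an
#' `n x n x p` array with `a[i, j, r]` the influence of channel `j` on
#' channel `i` at lag `r`; `noiseCov` is the residual covariance;
#' `regressorCov` the sample covariance of the stacked lagged predictors
#' (lag-major stacking: channel 1..n at lag 1, then lag 2, ...);
#' `nSamples` the number of regression equations actually used.
#'
#' @slot coefficients array, `n x n x p`.
#' @slot noiseCov symmetric positive-semidefinite `n x n` matrix.
#' @slot regressorCov symmetric positive-definite `(n p) x (n p)` matrix.
#' @slot nSamples integer, effective sample size.
#' @slot sampleRate numeric, Hz.
#' @slot channelNames character.
#' @export
setClass("MVARModel",
    representation(coefficients = "array", noiseCov = "matrix",
                   regressorCov = "matrix", nSamples = "integer",
                   sampleRate = "numeric", channelNames = "character"))

setValidity("MVARModel", function(object) {
    d <- dim(object@coefficients)
    msg <- character(0)
    if (length(d) != 3L || d[1] != d[2])
        msg <- c(msg, "coefficients must be an n x n x p array")
    n <- d[1]; p <- d[3]
    if (!isTRUE(all.equal(object@noiseCov, t(object@noiseCov), tolerance = 1e-8)))
        msg <- c(msg, "noiseCov must be symmetric")
    else if (min(eigen(object@noiseCov, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
        msg <- c(msg, "noiseCov must have nonnegative eigenvalues")
    if (!all(dim(object@regressorCov) == n * p))
        msg <- c(msg, "regressorCov must be (n p) x (n p)")
    if (object@nSamples < 1L) msg <- c(msg, "nSamples must be positive")
    if (length(msg)) msg else TRUE
})

#' @describeIn MVARModel model order p
#' @param object an `MVARModel`
#' @export
modelOrder <- function(object) dim(object@coefficients)[3]

#' @describeIn MVARModel coefficient array
#' @export
mvarCoef <- function(object) object@coefficients

#' @describeIn MVARModel residual (innovation) covariance
#' @export
noiseCov <- function(object) object@noiseCov

#' @describeIn MVARModel spectral radius of the companion matrix;
#'   values below 1 indicate a stationary model
#' @export
companionRadius <- function(object) {
    if (is(object, "MVARModel")) object <- object@coefficients
    A <- companionMatrix(object)
    max(Mod(eigen(A, only.values = TRUE)$values))
}

companionMatrix <- function(coefs) {
    n <- dim(coefs)[1]; p <- dim(coefs)[3]
    A <- matrix(0, n * p, n * p)
    for (r in seq_len(p)) A[seq_len(n), (r - 1L) * n + seq_len(n)] <- coefs[, , r]
    if (p > 1) A[n + seq_len(n * (p - 1L)), seq_len(n * (p - 1L))] <-
        diag(n * (p - 1L))
    A
}

setMethod("show", "MVARModel", function(object) {
    d <- dim(object@coefficients)
    cat(sprintf("MVARModel: %d channels, order %d, %d samples @ %g Hz\n",
                d[1], d[3], object@nSamples, object@sampleRate))
    cat(sprintf("  companion spectral radius: %.3f\n", companionRadius(object)))
})

#' Frequency-resolved directed connectivity (rPDC)
#'
#' `values[i, j, f]` holds the renormalized partial directed coherence for
#' the influence of channel `j` on channel `i` at frequency `freqs[f]`.
#' Diagonal entries are undefined and stored as `NA`. `nSamples * values`
#' is asymptotically chi-squared with 2 degrees of freedom when the true
#' influence is absent.
#'
#' @slot freqs numeric frequency grid, Hz.
#' @slot values `n x n x nfreq` array, nonnegative off the diagonal.
#' @slot nSamples integer.
#' @slot sampleRate numeric, Hz.
#' @slot channelNames character.
#' @export
setClass("SpectralConnectivity",
    representation(freqs = "numeric", values = "array", nSamples = "integer",
                   sampleRate = "numeric", channelNames = "character"))

setValidity("SpectralConnectivity", function(object) {
    d <- dim(object@values)
    msg <- character(0)
    if (length(d) != 3L || d[1] != d[2]) msg <- c(msg, "values must be n x n x nfreq")
    if (d[3] != length(object@freqs)) msg <- c(msg, "third dimension must match freqs")
    off <- object@values
    for (k in seq_len(d[3])) diag(off[, , k]) <- 0
    if (any(off < -1e-12, na.rm = TRUE)) msg <- c(msg, "rPDC values must be nonnegative")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SpectralConnectivity", function(object) {
    cat(sprintf("SpectralConnectivity: %d channels, %d frequencies (%.1f-%.1f Hz)\n",
                dim(object@values)[1], length(object@freqs),
                min(object@freqs), max(object@freqs)))
})

#' Band-averaged directed connectivity
#'
#' `values[i, j, b]` is the arithmetic mean of the rPDC for influence
#' `j -> i` over grid frequencies falling in band `b`. `level` records
#' whether rows/columns index source channels (independent components) or
#' atlas nodes.
#'
#' @slot bands named list of `c(lower, upper)` Hz intervals.
#' @slot values `n x n x nbands` array.
#' @slot nodeNames character row/column labels.
#' @slot level `"source"` or `"node"`.
#' @export
setClass("BandConnectivity",
    representation(bands = "list", values = "array", nodeNames = "character",
                   level = "character"))

setValidity("BandConnectivity", function(object) {
    d <- dim(object@values)
    msg <- character(0)
    if (length(d) != 3L || d[1] != d[2]) msg <- c(msg, "values must be n x n x nbands")
    if (d[3] != length(object@bands)) msg <- c(msg, "third dimension must match bands")
    if (!object@level %in% c("source", "node")) msg <- c(msg, "level must be 'source' or 'node'")
    if (length(msg)) msg else TRUE
})

#' @describeIn BandConnectivity band names
#' @param object a `BandConnectivity`
#' @export
bandNames <- function(object) names(object@bands)

#' @describeIn BandConnectivity extract one band's directed matrix
#' @param band band name, e.g. `"alpha"`
#' @export
bandMatrix <- function(object, band) {
    stopifnot(band %in% names(object@bands))
    m <- object@values[, , match(band, names(object@bands))]
    dimnames(m) <- list(target = object@nodeNames, source = object@nodeNames)
    m
}

setMethod("show", "BandConnectivity", function(object) {
    cat(sprintf("BandConnectivity (%s level): %d nodes x %d bands (%s)\n",
                object@level, dim(object@values)[1], length(object@bands),
                paste(names(object@bands), collapse = ", ")))
})

#' Spherical-node anatomical atlas
#'
#' Nodes are spheres in MNI millimetre space; each node's spatial support
#' is discretised into a deterministic grid of points used by the Gaussian
#' dipole-density projection.
#'
#' @slot nodes data.frame with columns `node_id`, `name`, `x`, `y`, `z`,
#'   `radius_mm`.
#' @slot supports named list of `k x 3` matrices of support-point
#'   coordinates (mm), one per node.
#' @export
setClass("Atlas", representation(nodes = "data.frame", supports = "list"))

setValidity("Atlas", function(object) {
    msg <- character(0)
    need <- c("node_id", "name", "x", "y", "z", "radius_mm")
    if (!all(need %in% names(object@nodes)))
        msg <- c(msg, paste("nodes must have columns", paste(need, collapse = ", ")))
    else {
        if (anyDuplicated(object@nodes$node_id)) msg <- c(msg, "node_ids must be unique")
        if (length(object@supports) != nrow(object@nodes))
            msg <- c(msg, "one support per node required")
        if (any(vapply(object@supports, nrow, 1L) == 0L))
            msg <- c(msg, "node supports must be non-empty")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn Atlas number of nodes
#' @param object an `Atlas`
#' @export
nNodes <- function(object) nrow(object@nodes)

#' @describeIn Atlas node identifier vector
#' @export
nodeIds <- function(object) object@nodes$node_id

setMethod("show", "Atlas", function(object) {
    cat(sprintf("Atlas: %d spherical nodes, %d support points\n",
                nNodes(object), sum(vapply(object@supports, nrow, 1L))))
})

#' Cohort of band connectivity as a SummarizedExperiment
#'
#' Rows index directed node pairs within a band (rowData columns `band`,
#' `source`, `target`); columns index participants (colData carries group
#' labels and covariates). Assay `"rpdc"` holds the band-averaged rPDC.
#'
#' @export
setClass("ConnectivityCohort", contains = "SummarizedExperiment")

setValidity("ConnectivityCohort", function(object) {
    rd <- rowData(object)
    msg <- character(0)
    if (!all(c("band", "source", "target") %in% names(rd)))
        msg <- c(msg, "rowData must have band, source, target")
    if (!"rpdc" %in% assayNames(object)) msg <- c(msg, "assay 'rpdc' required")
    if (length(msg)) msg else TRUE
})

#' Cluster-mass permutation test result
#'
#' @slot clusters data.frame, one row per observed cluster: band, sign,
#'   number of edges, cluster mass (summed F), corrected p.
#' @slot edges data.frame of cluster member edges.
#' @slot edgeStats per-edge statistic table (as from [edgeStatistics()]).
#' @slot nullMass numeric vector of per-permutation null cluster masses.
#' @slot nPerm integer number of label shuffles.
#' @slot pForm cluster-forming (uncorrected, two-sided) p threshold.
#' @slot nullStat `"max_cluster"` or `"second_largest_cluster"`.
#' @slot seed integer seed used for the shuffles.
#' @export
setClass("ClusterResult",
    representation(clusters = "data.frame", edges = "data.frame",
                   edgeStats = "data.frame", nullMass = "numeric",
                   nPerm = "integer", pForm = "numeric", nullStat = "character",
                   seed = "integer"))

setValidity("ClusterResult", function(object) {
    msg <- character(0)
    if (nrow(object@clusters) &&
        any(object@clusters$p_corrected < 1 / (object@nPerm + 1) - 1e-12))
        msg <- c(msg, "corrected p cannot fall below 1/(n_perm+1)")
    if (!object@nullStat %in% c("max_cluster", "second_largest_cluster"))
        msg <- c(msg, "unknown null statistic")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ClusterResult", function(object) {
    cat(sprintf("ClusterResult: %d cluster(s), %d permutations (%s null)\n",
                nrow(object@clusters), object@nPerm, object@nullStat))
    if (nrow(object@clusters)) print(object@clusters)
})

#' @describeIn ClusterResult observed clusters with corrected p-values
#' @param object a `ClusterResult`
#' @export
clusterTable <- function(object) object@clusters

#' @describeIn ClusterResult member edges of each observed cluster
#' @export
clusterEdges <- function(object) object@edges

#' Fitted association model
#'
#' Coefficient table of one outcome regression (negative-binomial with
#' robust standard errors, or linear), in the layout term / b / SE / z / p.
#'
#' @slot family `"negbin_robust"` or `"linear"`.
#' @slot coefficients data.frame with columns `term`, `b`, `se`, `z`, `p`
#'   (robust SEs).
#' @slot classicalSe named numeric, model-based SEs.
#' @slot outcome character, outcome name.
#' @slot n integer, number of observations.
#' @slot fit the underlying fitted model object.
#' @export
setClass("AssociationFit",
    representation(family = "character", coefficients = "data.frame",
                   classicalSe = "numeric", outcome = "character",
                   n = "integer", fit = "ANY"))

setValidity("AssociationFit", function(object) {
    msg <- character(0)
    if (!object@family %in% c("negbin_robust", "linear"))
        msg <- c(msg, "family must be negbin_robust or linear")
    cf <- object@coefficients
    if (!all(c("term", "b", "se", "z", "p") %in% names(cf)))
        msg <- c(msg, "coefficient table must have term, b, se, z, p")
    else {
        if (any(cf$se <= 0)) msg <- c(msg, "standard errors must be positive")
        if (any(cf$p <= 0 | cf$p > 1)) msg <- c(msg, "p-values must lie in (0, 1]")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "AssociationFit", function(object) {
    cat(sprintf("AssociationFit (%s): %s, n = %d\n",
                object@family, object@outcome, object@n))
    print(object@coefficients, digits = 3)
})

#' @describeIn AssociationFit coefficient table (term, b, se, z, p)
#' @param object an `AssociationFit`
#' @export
coefTable <- function(object) object@coefficients
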