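#' Specification for a synthetic MVAR cohort
#'
#' Describes a two-group cohort of source-level recordings generated from
#' band-tuned AR(2) oscillators with planted directed couplings. Each
#' source is a damped oscillator with pole angle `2 * pi * fc / sampleRate`
#' (`fc` the centre of its assigned band) and pole modulus 0.95, giving a
#' clear spectral peak inside the band. A coupling adds band-tuned
#' cross-coefficients from its source channel to its target channel: a
#' damped cosine kernel at the band centre spanning roughly one
#' oscillation period (`round(sampleRate / fc)` lags, capped at 48),
#' normalised to unit peak transfer gain so `strength` is the peak gain.
#' A multi-lag kernel is needed because the renormalized partial directed
#' coherence of a single-lag coupling is exactly flat in frequency (with
#' p lags the 2 x p Fourier weight matrix is square for p <= 2), so only
#' couplings with several lags of memory can be band-specific.
#' `groupDelta` is added to the strength for group 2 only, so the two
#' groups differ exactly at the flagged couplings.
#'
#' @param nPerGroup participants per group.
#' @param nSources number of source channels (>= 2).
#' @param sampleRate sampling rate, Hz (default 500).
#' @param duration recording length, seconds (default 180, a 3-minute
#'   eyes-closed resting recording).
#' @param couplings list of couplings, each a list with elements `source`,
#'   `target` (1-based channel indices), `band` (one of
#'   `names(eegBands())`), `strength` in `[0, 1)` (peak transfer gain),
#'   optional `groupDelta` (default 0) and optional `lags` overriding the
#'   kernel length.
#' @param noiseSd innovation standard deviation, signal units.
#' @param dipoleJitterSd isotropic sd (mm) of dipole scatter around the
#'   assigned atlas node centre (default 6).
#' @param seed integer seed; generation is a pure function of the spec.
#'
#' @details The generated model (for both groups) must be stationary:
#' the spectral radius of its companion matrix must be below 1. A
#' non-stationary coefficient set is rejected with a diagnostic naming the
#' offending coupling(s).
#'
#' @return An object of class `SimSpec` (a validated list).
#' @export
#' @examples
#' simSpec(nPerGroup = 5, nSources = 3,
#'         couplings = list(list(source = 1, target = 2, band = "alpha",
#'                               strength = 0.3, groupDelta = 0.2)),
#'         duration = 10, seed = 1)
simSpec <- function(nPerGroup, nSources, sampleRate = 500, duration = 180,
                    couplings = list(), noiseSd = 1, dipoleJitterSd = 6,
                    seed = 1L) {
    stopifnot(nPerGroup >= 1, nSources >= 2, duration > 0, noiseSd > 0)
    if (sampleRate <= 2 * max(unlist(eegBands())))
        stop("sampleRate must exceed twice the highest band edge (80 Hz)")
    for (cp in couplings) {
        if (!all(c("source", "target", "band", "strength") %in% names(cp)))
            stop("each coupling needs source, target, band, strength")
        if (!cp$band %in% names(eegBands()))
            stop("unknown band: ", cp$band)
        if (cp$source == cp$target)
            stop("coupling source and target must differ")
        if (max(cp$source, cp$target) > nSources)
            stop("coupling channel index exceeds nSources")
        if (cp$strength < 0 || cp$strength >= 1)
            stop("coupling strength must lie in [0, 1)")
    }
    spec <- structure(list(nPerGroup = as.integer(nPerGroup),
                           nSources = as.integer(nSources),
                           sampleRate = sampleRate, duration = duration,
                           couplings = couplings, noiseSd = noiseSd,
                           dipoleJitterSd = dipoleJitterSd,
                           seed = as.integer(seed)),
                      class = "SimSpec")
    for (g in 1:2) checkStationary(mvarCoefficientsFor(spec, g), spec)
    spec
}

## Band assignment per source: couplings pin their source and target
## channels to the coupling band; remaining channels cycle through the
## five bands so the cohort spans the spectrum.
sourceBandAssignment <- function(spec) {
    bands <- rep(names(eegBands()), length.out = spec$nSources)
    for (cp in spec$couplings) {
        bands[cp$source] <- cp$band
        bands[cp$target] <- cp$band
    }
    bands
}

## Damped cosine coupling kernel at the band centre, spanning about one
## oscillation period and normalised to unit peak transfer gain over the
## 0.5-45 Hz range.
couplingKernel <- function(band, sampleRate, lags = NULL) {
    fc <- bandCentres()[[band]]
    if (is.null(lags)) lags <- max(2L, min(48L, round(sampleRate / fc)))
    r <- seq_len(lags)
    damp <- 0.3^(1 / lags)
    k <- cos(2 * pi * fc / sampleRate * r) * damp^r
    om <- seq(0.5, 45, by = 0.25) * 2 * pi / sampleRate
    gain <- vapply(om, function(w) Mod(sum(k * exp(-1i * w * r))), numeric(1))
    k / max(gain)
}

## Generating coefficient array (n x n x p) for one group.
mvarCoefficientsFor <- function(spec, group) {
    n <- spec$nSources
    kernels <- lapply(spec$couplings, function(cp)
        couplingKernel(cp$band, spec$sampleRate, cp$lags))
    p <- max(2L, if (length(kernels)) max(lengths(kernels)) else 0L)
    A <- array(0, dim = c(n, n, p))
    centres <- bandCentres()[sourceBandAssignment(spec)]
    rho <- 0.95
    theta <- 2 * pi * centres / spec$sampleRate
    for (k in seq_len(n)) {
        A[k, k, 1] <- 2 * rho * cos(theta[k])
        A[k, k, 2] <- -rho^2
    }
    for (i in seq_along(spec$couplings)) {
        cp <- spec$couplings[[i]]
        s <- cp$strength + if (group == 2L && !is.null(cp$groupDelta)) cp$groupDelta else 0
        kk <- kernels[[i]]
        A[cp$target, cp$source, seq_along(kk)] <-
            A[cp$target, cp$source, seq_along(kk)] + s * kk
    }
    A
}

checkStationary <- function(coefs, spec) {
    if (companionRadius(coefs) < 1) return(invisible(TRUE))
    bad <- character(0)
    for (i in seq_along(spec$couplings)) {
        reduced <- spec
        reduced$couplings <- spec$couplings[-i]
        for (g in 1:2) {
            if (companionRadius(mvarCoefficientsFor(reduced, g)) < 1) {
                cp <- spec$couplings[[i]]
                bad <- c(bad, sprintf("%d->%d (%s, strength %.3g)",
                                      cp$source, cp$target, cp$band, cp$strength))
                break
            }
        }
    }
    stop("generated MVAR model is non-stationary (companion spectral radius >= 1); ",
         if (length(bad)) paste("offending coupling(s):", paste(unique(bad), collapse = "; "))
         else "no single coupling restores stationarity when removed")
}

## Simulate one VAR realisation of N samples (after burn-in) from a
## coefficient array, using the current RNG stream.
simulateVar <- function(coefs, nSamples, noiseSd, burn = 500L) {
    n <- dim(coefs)[1]
    innov <- matrix(rnorm(n * (nSamples + burn), sd = noiseSd), nrow = n)
    x <- var_recursion(coefs, innov)
    t(x[, burn + seq_len(nSamples), drop = FALSE])
}

#' Simulate a two-group cohort of source recordings
#'
#' Generates per-participant multichannel time series from the group's
#' MVAR model described by `spec`, plus (when an atlas is supplied) one
#' dipole coordinate per source channel, scattered isotropically around
#' the channel's assigned atlas node centre.
#'
#' @param spec a [simSpec()] object.
#' @param atlas optional [Atlas]; when supplied, source channels are
#'   assigned to nodes (round-robin by default, or via `nodeAssignment`)
#'   and dipole coordinates are drawn around the node centres.
#' @param nodeAssignment optional integer vector of length
#'   `spec$nSources` giving the atlas node row index of each source.
#'
#' @return list with elements
#'   \describe{
#'     \item{recordings}{list of per-participant lists with `series`
#'       (samples x sources matrix) and, with an atlas, `dipoles`
#'       (data.frame source_id, x_mm, y_mm, z_mm).}
#'     \item{group}{integer vector of group labels (1/2).}
#'     \item{truth}{list with the generating coefficient array per group,
#'       the per-source band assignment and node assignment.}
#'   }
#'   Output is a pure function of `spec` (same spec, same seed, identical
#'   output).
#' @export
simulateMvarCohort <- function(spec, atlas = NULL, nodeAssignment = NULL) {
    stopifnot(inherits(spec, "SimSpec"))
    coefs <- list(mvarCoefficientsFor(spec, 1L), mvarCoefficientsFor(spec, 2L))
    nTotal <- 2L * spec$nPerGroup
    group <- rep(1:2, each = spec$nPerGroup)
    N <- round(spec$duration * spec$sampleRate)
    if (!is.null(atlas)) {
        if (is.null(nodeAssignment))
            nodeAssignment <- rep(seq_len(nNodes(atlas)), length.out = spec$nSources)
        stopifnot(length(nodeAssignment) == spec$nSources,
                  all(nodeAssignment >= 1), all(nodeAssignment <= nNodes(atlas)))
    }
    set.seed(spec$seed)
    recordings <- vector("list", nTotal)
    for (k in seq_len(nTotal)) {
        series <- simulateVar(coefs[[group[k]]], N, spec$noiseSd)
        colnames(series) <- paste0("src", seq_len(spec$nSources))
        rec <- list(series = series)
        if (!is.null(atlas)) {
            ctr <- as.matrix(atlas@nodes[nodeAssignment, c("x", "y", "z")])
            xyz <- ctr + matrix(rnorm(3L * spec$nSources, sd = spec$dipoleJitterSd),
                                ncol = 3)
            rec$dipoles <- data.frame(source_id = colnames(series),
                                      x_mm = xyz[, 1], y_mm = xyz[, 2],
                                      z_mm = xyz[, 3])
        }
        recordings[[k]] <- rec
    }
    list(recordings = recordings, group = group,
         truth = list(coefficients = coefs,
                      sourceBands = sourceBandAssignment(spec),
                      nodeAssignment = nodeAssignment))
}
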