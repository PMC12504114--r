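#' Family-wise error calibration of the cluster permutation test
#'
#' Monte-Carlo estimate of the family-wise false-positive rate of
#' [permuteClusters()] under a global null: for each replicate, both
#' groups are drawn from the same generating MVAR model, each
#' participant's recording is fitted, rPDC is band-averaged, and the
#' cluster-mass permutation test is run; the replicate counts as a
#' false positive when any cluster attains a corrected p below `alpha`.
#'
#' @param nReplicates number of replicate null datasets.
#' @param nPerGroup participants per group (default 20).
#' @param nSources channels/nodes (default 10).
#' @param nPerm label shuffles per replicate (default 200).
#' @param duration recording length per participant in seconds (default
#'   20; the permutation test is exact at any length, so a short
#'   recording only reduces estimator precision, not validity).
#' @param alpha corrected significance level (default 0.05).
#' @param pForm cluster-forming threshold (default 1e-4).
#' @param nullStat null cluster statistic (default `"max_cluster"`).
#' @param order MVAR order used for fitting (default 4; the permutation
#'   null only needs group exchangeability, which holds at any order).
#' @param sampleRate generator sampling rate in Hz (default 100, which
#'   keeps the generating kernels short and the fits fast).
#' @param seed integer master seed; replicate seeds are derived from it.
#' @return data.frame with one row per replicate: `n_clusters`, `min_p`
#'   (corrected; NA when no cluster formed) and `any_significant`.
#'   `mean(out$any_significant)` estimates the FWER.
#' @export
estimateFwer <- function(nReplicates, nPerGroup = 20, nSources = 10,
                         nPerm = 200, duration = 20, alpha = 0.05,
                         pForm = 1e-4, nullStat = "max_cluster", order = 4,
                         sampleRate = 100, seed = 1L) {
    couplings <- list(
        list(source = 1, target = 2, band = "alpha", strength = 0.3),
        list(source = 3, target = 4, band = "theta", strength = 0.25))
    couplings <- Filter(function(cp) max(cp$source, cp$target) <= nSources,
                        couplings)
    out <- data.frame(n_clusters = integer(nReplicates),
                      min_p = rep(NA_real_, nReplicates),
                      any_significant = logical(nReplicates))
    for (r in seq_len(nReplicates)) {
        repSeed <- (seed * 10007L + r) %% 2147483647L
        spec <- simSpec(nPerGroup = nPerGroup, nSources = nSources,
                        sampleRate = sampleRate, duration = duration,
                        couplings = couplings, seed = repSeed)
        cohort <- simulateMvarCohort(spec)
        bandConn <- lapply(cohort$recordings, function(rec)
            bandAverage(computeRpdc(fitMvar(rec$series, order = order,
                                            sampleRate = spec$sampleRate))))
        cc <- connectivityCohort(bandConn,
                                 data.frame(group = factor(cohort$group)))
        res <- permuteClusters(cc, nPerm = nPerm, pForm = pForm,
                               nullStat = nullStat,
                               seed = (repSeed + 1L) %% 2147483647L)
        tab <- clusterTable(res)
        out$n_clusters[r] <- nrow(tab)
        if (nrow(tab)) out$min_p[r] <- min(tab$p_corrected)
        out$any_significant[r] <- nrow(tab) > 0 && min(tab$p_corrected) < alpha
    }
    out
}
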