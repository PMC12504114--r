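#' Renormalized partial directed coherence from a fitted MVAR model
#'
#' For each ordered channel pair (target `i` <- source `j`, `i != j`) and
#' frequency `w`, the Fourier transform of the cross-coefficients
#' `Abar_ij(w) = sum_r a[i, j, r] exp(-2 pi i w r / fs)` is stacked into
#' the 2-vector `X = (Re Abar, Im Abar)`. Its 2 x 2 covariance `V` is
#' obtained by propagating the asymptotic coefficient-estimator covariance
#' `Sigma[i, i] * (R^-1 restricted to source j's lag block) / N` through
#' the cosine/sine Fourier weights. The statistic
#' `lambda_ij(w) = X' V^-1 X / N` is the renormalized partial directed
#' coherence: `N * lambda` is asymptotically chi-squared with 2 degrees of
#' freedom when the true influence `j -> i` is absent, making values
#' comparable across pairs and frequencies.
#'
#' @param model an [MVARModel] of order >= 2 (one lag leaves the
#'   real/imaginary covariance rank-deficient).
#' @param freqs frequency grid in Hz, strictly inside `(0, fs / 2)`;
#'   default 1-40 Hz in 0.5-Hz steps.
#' @return A [SpectralConnectivity]; diagonal entries are `NA`.
#' @export
#' @examples
#' spec <- simSpec(nPerGroup = 1, nSources = 2, duration = 8, seed = 3,
#'                 couplings = list(list(source = 1, target = 2,
#'                                       band = "alpha", strength = 0.3)))
#' rec <- simulateMvarCohort(spec)$recordings[[1]]
#' sc <- computeRpdc(fitMvar(rec$series, order = 2))
computeRpdc <- function(model, freqs = seq(1, 40, by = 0.5)) {
    stopifnot(is(model, "MVARModel"))
    validObject(model)
    n <- dim(model@coefficients)[1]; p <- dim(model@coefficients)[3]
    fs <- model@sampleRate; N <- model@nSamples
    if (p < 2)
        stop("rPDC needs model order >= 2: with one lag the (Re, Im) covariance ",
             "is singular; refit with a higher order")
    if (any(freqs <= 0) || any(freqs >= fs / 2))
        stop("frequencies must lie strictly inside (0, sampleRate/2)")
    Rinv <- solve(model@regressorCov)
    nf <- length(freqs)
    phase <- outer(2 * pi * freqs / fs, seq_len(p))   # nf x p
    Fc <- cos(phase); Fs <- sin(phase)
    lam <- array(NA_real_, dim = c(n, n, nf))
    for (j in seq_len(n)) {
        idx <- (seq_len(p) - 1L) * n + j              # lag block of source j
        Cj <- Rinv[idx, idx, drop = FALSE]
        FcC <- Fc %*% Cj; FsC <- Fs %*% Cj
        v11 <- rowSums(FcC * Fc)                      # per-frequency quadratic forms
        v22 <- rowSums(FsC * Fs)
        v12 <- -rowSums(FcC * Fs)
        Aj <- matrix(model@coefficients[, j, ], nrow = n)  # n x p
        X1 <- Fc %*% t(Aj); X2 <- -Fs %*% t(Aj)       # nf x n, Re/Im of Abar
        for (i in seq_len(n)) {
            if (i == j) next
            x1 <- X1[, i]
            x2 <- X2[, i]
            s <- model@noiseCov[i, i] / N
            det <- v11 * v22 - v12^2
            ## singular when Re and Im components are perfectly correlated
            if (any(det <= 1e-12 * v11 * v22))
                stop("singular (Re, Im) covariance for pair ", j, " -> ", i,
                     "; use a longer recording or a lower model order")
            q <- (x1^2 * v22 - 2 * x1 * x2 * v12 + x2^2 * v11) / (det * s)
            lam[i, j, ] <- q / N
        }
    }
    new("SpectralConnectivity", freqs = freqs, values = lam,
        nSamples = as.integer(N), sampleRate = fs,
        channelNames = model@channelNames)
}

#' Average spectral connectivity into canonical bands
#'
#' Each band value is the arithmetic mean of the rPDC over grid
#' frequencies inside the band. Band intervals are left-closed and
#' right-open, except the highest band which is right-closed (gamma
#' includes 40 Hz).
#'
#' @param conn a [SpectralConnectivity].
#' @param bands named list of `c(lower, upper)` intervals (default
#'   [eegBands()]).
#' @return A [BandConnectivity] at the source level.
#' @export
bandAverage <- function(conn, bands = eegBands()) {
    stopifnot(is(conn, "SpectralConnectivity"))
    n <- dim(conn@values)[1]
    out <- array(NA_real_, dim = c(n, n, length(bands)),
                 dimnames = list(NULL, NULL, names(bands)))
    last <- which.max(vapply(bands, `[`, numeric(1), 2))
    for (b in seq_along(bands)) {
        lo <- bands[[b]][1]; hi <- bands[[b]][2]
        sel <- conn@freqs >= lo & (if (b == last) conn@freqs <= hi
                                   else conn@freqs < hi)
        if (!any(sel))
            stop(sprintf("band %s [%g, %g) contains no grid frequency (grid step too coarse)",
                         names(bands)[b], lo, hi))
        sub <- conn@values[, , sel, drop = FALSE]
        out[, , b] <- rowMeans(array(sub, dim = c(n * n, sum(sel))))
    }
    new("BandConnectivity", bands = bands, values = out,
        nodeNames = conn@channelNames, level = "source")
}

#' Tidy data frame of band connectivity
#'
#' @param conn a [BandConnectivity].
#' @param participant optional participant label column.
#' @return data.frame with columns participant (optional), target,
#'   source, band, value; self-connections omitted.
#' @export
bandConnectivityTable <- function(conn, participant = NULL) {
    stopifnot(is(conn, "BandConnectivity"))
    n <- dim(conn@values)[1]
    idx <- which(row(diag(n)) != col(diag(n)), arr.ind = TRUE)
    rows <- do.call(rbind, lapply(seq_along(conn@bands), function(b)
        data.frame(target = conn@nodeNames[idx[, 1]],
                   source = conn@nodeNames[idx[, 2]],
                   band = names(conn@bands)[b],
                   value = conn@values[, , b][idx])))
    if (!is.null(participant)) rows <- cbind(participant = participant, rows)
    rows
}
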