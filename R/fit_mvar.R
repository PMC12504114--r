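## Build the lagged regression problem for an MVAR(p) fit.
## Regressors are stacked lag-major: channels 1..n at lag 1, then lag 2...
laggedDesign <- function(x, p) {
    N <- nrow(x); n <- ncol(x)
    Y <- x[(p + 1):N, , drop = FALSE]
    X <- matrix(0, N - p, n * p)
    for (r in seq_len(p))
        X[, (r - 1L) * n + seq_len(n)] <- x[(p + 1 - r):(N - r), , drop = FALSE]
    list(Y = Y, X = X)
}

#' Fit a multivariate autoregressive model by least squares
#'
#' Fits `x_t = sum_r A_r x_{t-r} + e_t` to a continuous multichannel
#' recording after per-channel mean removal. With `order = "auto"` the
#' order minimising the Bayesian information criterion over 1..`maxOrder`
#' is selected. The residual covariance and the sample covariance of the
#' stacked lagged predictors are retained because the rPDC renormalization
#' needs the asymptotic coefficient-estimator covariance
#' `(Sigma x R^-1) / N`.
#'
#' @param x numeric matrix, samples x channels (or a list with element
#'   `series`, as produced by [simulateMvarCohort()]).
#' @param order integer model order, or `"auto"` for BIC selection.
#' @param sampleRate sampling rate in Hz (default 500).
#' @param maxOrder upper bound for automatic order selection (default 20).
#' @return An [MVARModel].
#' @export
#' @examples
#' spec <- simSpec(nPerGroup = 1, nSources = 2, duration = 4, seed = 2,
#'                 couplings = list(list(source = 1, target = 2,
#'                                       band = "alpha", strength = 0.3)))
#' rec <- simulateMvarCohort(spec)$recordings[[1]]
#' fitMvar(rec$series, order = 2)
fitMvar <- function(x, order = "auto", sampleRate = 500, maxOrder = 20L) {
    if (is.list(x) && !is.null(x$series)) x <- x$series
    x <- as.matrix(x)
    if (!all(is.finite(x))) stop("series contains non-finite values")
    n <- ncol(x); N <- nrow(x)
    x <- sweep(x, 2, colMeans(x))
    if (identical(order, "auto")) {
        orders <- seq_len(min(maxOrder, floor((N - 10) / (n + 1) / n)))
        if (!length(orders)) stop("series too short for any model order")
        bic <- vapply(orders, function(p) {
            d <- laggedDesign(x, p)
            qr_ <- qr(d$X)
            res <- d$Y - d$X %*% qr.coef(qr_, d$Y)
            Neff <- nrow(d$Y)
            S <- crossprod(res) / Neff
            Neff * determinant(S, logarithm = TRUE)$modulus + n^2 * p * log(Neff)
        }, numeric(1))
        order <- orders[which.min(bic)]
    }
    p <- as.integer(order)
    minN <- (p * n + 10) * n
    if (N < minN)
        stop(sprintf("series too short: %d samples, need at least %d for order %d with %d channels",
                     N, minN, p, n))
    d <- laggedDesign(x, p)
    qr_ <- qr(d$X)
    if (qr_$rank < ncol(d$X)) {
        bad <- unique(((qr_$pivot[(qr_$rank + 1):ncol(d$X)] - 1L) %% n) + 1L)
        stop("rank-deficient regressor matrix; collinear channel(s): ",
             paste(bad, collapse = ", "))
    }
    B <- qr.coef(qr_, d$Y)                       # (n p) x n, column i = target i
    res <- d$Y - d$X %*% B
    Neff <- nrow(d$Y)
    Sigma <- crossprod(res) / (Neff - n * p)
    R <- crossprod(d$X) / Neff
    A <- array(0, dim = c(n, n, p))
    for (r in seq_len(p))
        A[, , r] <- t(B[(r - 1L) * n + seq_len(n), , drop = FALSE])
    chn <- colnames(x)
    if (is.null(chn)) chn <- paste0("ch", seq_len(n))
    new("MVARModel", coefficients = A, noiseCov = Sigma, regressorCov = R,
        nSamples = as.integer(Neff), sampleRate = sampleRate,
        channelNames = chn)
}

#' Asymptotic standard errors of MVAR coefficients
#'
#' `se[i, j, r]` for coefficient `a[i, j, r]`, from the Kronecker-form
#' estimator covariance `(Sigma x R^-1) / N`.
#'
#' @param model an [MVARModel].
#' @return array matching the coefficient array in shape.
#' @export
mvarCoefSe <- function(model) {
    n <- dim(model@coefficients)[1]; p <- dim(model@coefficients)[3]
    Rinv <- solve(model@regressorCov)
    se <- array(0, dim = c(n, n, p))
    v <- diag(Rinv) / model@nSamples
    for (r in seq_len(p)) for (j in seq_len(n))
        se[, j, r] <- sqrt(diag(model@noiseCov) * v[(r - 1L) * n + j])
    se
}
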