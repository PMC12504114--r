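## Independent oracles used across the suite. These re-derive expected
## quantities from first principles, never through the code paths they
## check.

## Stationary covariance of a VAR(p) process by solving the discrete
## Lyapunov equation of its companion form: vec(P) = (I - A (x) A)^-1
## vec(Q). Returns function(h) giving the lag-h cross-covariance matrix
## Cov(x_t, x_{t-h}) of the n channels.
lyapunovAutocov <- function(coefs, noiseSd = 1) {
    n <- dim(coefs)[1]; p <- dim(coefs)[3]
    A <- matrix(0, n * p, n * p)
    for (r in seq_len(p)) A[seq_len(n), (r - 1) * n + seq_len(n)] <- coefs[, , r]
    if (p > 1) A[n + seq_len(n * (p - 1)), seq_len(n * (p - 1))] <- diag(n * (p - 1))
    Q <- matrix(0, n * p, n * p)
    Q[seq_len(n), seq_len(n)] <- diag(noiseSd^2, n)
    m <- n * p
    P <- matrix(solve(diag(m * m) - kronecker(A, A), as.vector(Q)), m, m)
    function(h) {
        G <- P
        if (h > 0) for (k in seq_len(h)) G <- A %*% G
        G[seq_len(n), seq_len(n)]
    }
}

## Brute-force rPDC from known model quantities: complex summation for
## Abar and explicit 2x2 matrix algebra, one frequency at a time.
bruteRpdc <- function(coefs, Sigma, R, N, fs, freqs, i, j) {
    p <- dim(coefs)[3]; n <- dim(coefs)[1]
    Rinv <- solve(R)
    idx <- (seq_len(p) - 1) * n + j
    Cj <- Rinv[idx, idx, drop = FALSE]
    vapply(freqs, function(f) {
        z <- sum(coefs[i, j, ] * exp(-2i * pi * f * seq_len(p) / fs))
        X <- c(Re(z), Im(z))
        J <- rbind(cos(2 * pi * f * seq_len(p) / fs),
                   -sin(2 * pi * f * seq_len(p) / fs))
        V <- J %*% (Sigma[i, i] * Cj / N) %*% t(J)
        drop(t(X) %*% solve(V) %*% X) / N
    }, numeric(1))
}

## Two-sample pooled t from the textbook formula.
pooledT <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

## Build a ConnectivityCohort directly from random positive band values
## (no MVAR machinery), for tests of the statistics layer alone.
randomCohort <- function(nNodes, nPerGroup, seed = 1, shift = NULL) {
    set.seed(seed)
    nodes <- paste0("n", seq_len(nNodes))
    mk <- function(grp) {
        v <- array(exp(rnorm(nNodes * nNodes * 5)), c(nNodes, nNodes, 5))
        if (!is.null(shift) && grp == 2) v <- v * exp(shift)
        for (b in 1:5) diag(v[, , b]) <- NA
        new("BandConnectivity", bands = eegBands(), values = v,
            nodeNames = nodes, level = "node")
    }
    conns <- c(lapply(seq_len(nPerGroup), function(k) mk(1)),
               lapply(seq_len(nPerGroup), function(k) mk(2)))
    connectivityCohort(conns, data.frame(group = factor(rep(1:2, each = nPerGroup))))
}

## Simulate one uncoupled bivariate oscillator recording and return
## N * lambda at the requested frequency (null rPDC draw).
nullRpdcDraw <- function(seed, duration = 100, fs = 100, freq = 10) {
    spec <- simSpec(nPerGroup = 1, nSources = 2, sampleRate = fs,
                    duration = duration, seed = seed)
    rec <- simulateMvarCohort(spec)$recordings[[1]]
    m <- fitMvar(rec$series, order = 2, sampleRate = fs)
    sc <- computeRpdc(m, freqs = freq)
    sc@values[2, 1, 1] * m@nSamples
}

## Inverse of the cohort row layout: rebuild an n x n x 5 band array
## from one participant's stacked edge vector.
cohortRowsToArray <- function(v, n) {
    idx <- which(row(diag(n)) != col(diag(n)), arr.ind = TRUE)
    m <- nrow(idx)
    A <- array(NA_real_, c(n, n, 5))
    for (b in 1:5) {
        slice <- A[, , b]
        slice[idx] <- v[(b - 1) * m + seq_len(m)]
        A[, , b] <- slice
    }
    A
}
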