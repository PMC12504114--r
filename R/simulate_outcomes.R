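#' Specification for synthetic clinical outcomes
#'
#' Clinical scores are drawn from a negative-binomial model on the excess
#' above the scale floor of 17 (the instrument's total ranges from 17 to
#' 113): `score = 17 + NB(mu, dispersion)` with
#' `log mu = intercept + betaConnectivity * edge + covariates %*% betaCovariates`.
#' `dispersion` is the negative-binomial size parameter (Poisson limit as
#' it grows large).
#'
#' @param intercept intercept on the log-mean scale (default 2.5, mean
#'   excess ~12 points above the floor).
#' @param betaConnectivity generative coefficient on the connectivity edge.
#' @param betaCovariates numeric vector of covariate coefficients (may be
#'   empty).
#' @param dispersion positive negative-binomial size.
#' @param seed integer seed.
#' @return An object of class `OutcomeSimSpec`.
#' @export
outcomeSimSpec <- function(intercept = 2.5, betaConnectivity = 0,
                           betaCovariates = numeric(0), dispersion = 5,
                           seed = 1L) {
    stopifnot(dispersion > 0, is.numeric(betaCovariates))
    structure(list(intercept = intercept,
                   betaConnectivity = betaConnectivity,
                   betaCovariates = betaCovariates,
                   dispersion = dispersion, seed = as.integer(seed)),
              class = "OutcomeSimSpec")
}

#' Simulate clinical scores from connectivity
#'
#' @param edge numeric vector, one connectivity edge value per participant
#'   (typically log-rPDC of the selected edge).
#' @param covariates optional numeric matrix/data.frame (participants x
#'   covariates) matching `spec$betaCovariates` in column count.
#' @param spec an [outcomeSimSpec()].
#' @return data.frame with `participant`, `score` (>= 17), the linear
#'   predictor `eta`, `edge` and any covariate columns. Deterministic
#'   given the spec's seed.
#' @export
simulateOutcomes <- function(edge, covariates = NULL, spec = outcomeSimSpec()) {
    stopifnot(inherits(spec, "OutcomeSimSpec"))
    n <- length(edge)
    eta <- spec$intercept + spec$betaConnectivity * edge
    if (length(spec$betaCovariates)) {
        if (is.null(covariates))
            stop("betaCovariates given but no covariates supplied")
        covariates <- as.matrix(covariates)
        if (ncol(covariates) != length(spec$betaCovariates))
            stop(sprintf("covariate dimension mismatch: %d columns vs %d coefficients",
                         ncol(covariates), length(spec$betaCovariates)))
        if (nrow(covariates) != n)
            stop("covariates must have one row per participant")
        eta <- eta + drop(covariates %*% spec$betaCovariates)
    } else if (!is.null(covariates) && NCOL(covariates) > 0) {
        stop(sprintf("covariate dimension mismatch: %d columns vs 0 coefficients",
                     NCOL(covariates)))
    }
    set.seed(spec$seed)
    score <- 17 + rnbinom(n, size = spec$dispersion, mu = exp(eta))
    out <- data.frame(participant = seq_len(n), score = score,
                      eta = eta, edge = edge)
    if (!is.null(covariates)) out <- cbind(out, as.data.frame(covariates))
    out
}
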