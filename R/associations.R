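robustCoefTable <- function(fit, vcovFun) {
    ct <- lmtest::coeftest(fit, vcov. = vcovFun(fit))
    data.frame(term = rownames(ct), b = ct[, 1], se = ct[, 2],
               z = ct[, 3], p = pmax(ct[, 4], .Machine$double.xmin),
               row.names = NULL)
}

#' Negative-binomial model of follow-up symptom scores
#'
#' Regresses the follow-up clinical score (negative binomial, log link,
#' on the excess above the scale floor of 17) on a baseline connectivity
#' edge while adjusting for baseline score, age, sex and site. Standard
#' errors are sandwich (robust); model-based SEs are retained alongside.
#'
#' @param data data.frame containing the outcome and predictors
#'   (complete cases on the model variables are used).
#' @param outcome name of the follow-up score column (default
#'   `"score"`); values must be at least 17, the scale floor.
#' @param edge name of the connectivity predictor column (default
#'   `"edge"`, typically log-rPDC of the selected edge).
#' @param covariates character vector of adjustment columns (default
#'   `c("baseline", "age", "sex", "site")`, used when present in `data`).
#' @return An [AssociationFit] with family `"negbin_robust"`.
#' @export
fitSymptomModel <- function(data, outcome = "score", edge = "edge",
                            covariates = c("baseline", "age", "sex", "site")) {
    covariates <- intersect(covariates, names(data))
    vars <- c(outcome, edge, covariates)
    stopifnot(all(vars %in% names(data)))
    data <- data[complete.cases(data[vars]), vars, drop = FALSE]
    y <- data[[outcome]]
    if (any(y < 17)) stop("scores below the scale floor of 17")
    if (length(unique(y)) == 1L) stop("all outcome values identical; nothing to fit")
    data$.y <- y - 17
    form <- as.formula(paste(".y ~", paste(c(edge, covariates), collapse = " + ")))
    fit <- tryCatch(
        suppressWarnings(MASS::glm.nb(form, data = data, maxit = 50)),
        error = function(e) stop("negative-binomial fit failed to converge: ",
                                 conditionMessage(e)))
    ct <- robustCoefTable(fit, function(f) sandwich::vcovHC(f, type = "HC0"))
    classical <- setNames(sqrt(diag(stats::vcov(fit))), names(coef(fit)))
    new("AssociationFit", family = "negbin_robust", coefficients = ct,
        classicalSe = classical, outcome = outcome, n = nrow(data), fit = fit)
}

#' Linear model of person-level negative sentiment
#'
#' Regresses mean daily negative-sentiment proportion on a baseline
#' connectivity edge, adjusting for positive sentiment, age, sex, site
#' and phone type. Reports robust (HC3) standard errors, keeping the
#' classical ones alongside. Baseline depression is deliberately not a
#' covariate of this model.
#'
#' @param data data.frame of included participants.
#' @param outcome outcome column (default `"mean_prop_negative"`).
#' @param edge connectivity predictor column (default `"edge"`).
#' @param covariates adjustment columns (default
#'   `c("mean_prop_positive", "age", "sex", "site", "phone")`, used when
#'   present).
#' @return An [AssociationFit] with family `"linear"`.
#' @export
fitSentimentModel <- function(data, outcome = "mean_prop_negative",
                              edge = "edge",
                              covariates = c("mean_prop_positive", "age",
                                             "sex", "site", "phone")) {
    covariates <- intersect(covariates, names(data))
    vars <- c(outcome, edge, covariates)
    stopifnot(all(vars %in% names(data)))
    data <- data[complete.cases(data[vars]), vars, drop = FALSE]
    form <- as.formula(paste(outcome, "~",
                             paste(c(edge, covariates), collapse = " + ")))
    fit <- lm(form, data = data)
    if (any(is.na(coef(fit)))) {
        aliased <- names(coef(fit))[is.na(coef(fit))]
        stop("collinear design; aliased term(s): ", paste(aliased, collapse = ", "))
    }
    ct <- robustCoefTable(fit, function(f) sandwich::vcovHC(f, type = "HC3"))
    classical <- setNames(sqrt(diag(stats::vcov(fit))), names(coef(fit)))
    new("AssociationFit", family = "linear", coefficients = ct,
        classicalSe = classical, outcome = outcome, n = nrow(data), fit = fit)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant).
#' @return list with `r`, `p`, `n`.
#' @export
pearsonR <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) stop("need at least 3 complete observations")
    if (sd(x) == 0 || sd(y) == 0) stop("zero variance in input")
    ct <- cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Standardized effect size of a model term
#'
#' Converts a fitted term's test statistic to a Cohen's d via
#' `d = 2 t / sqrt(df)` with `df = n - k` residual degrees of freedom
#' (for the negative-binomial family the robust z plays the role of t).
#' The conversion is invariant to rescaling of the predictor.
#'
#' @param fit an [AssociationFit].
#' @param term term name as it appears in [coefTable()].
#' @return Cohen's d (signed).
#' @export
standardizedEffect <- function(fit, term) {
    stopifnot(is(fit, "AssociationFit"))
    ct <- fit@coefficients
    row <- match(term, ct$term)
    if (is.na(row)) stop("term not in fit: ", term)
    df <- fit@n - nrow(ct)
    2 * ct$z[row] / sqrt(df)
}

#' Benjamini-Hochberg report across bands
#'
#' Supplementary FDR adjustment of per-band p-values for one outcome.
#'
#' @param fits named list of [AssociationFit] (names = bands).
#' @param term the term whose p-values to adjust (default `"edge"`).
#' @return data.frame band, b, p, p_fdr.
#' @export
fdrAcrossBands <- function(fits, term = "edge") {
    rows <- do.call(rbind, lapply(names(fits), function(b) {
        ct <- coefTable(fits[[b]])
        k <- match(term, ct$term)
        data.frame(band = b, b = ct$b[k], p = ct$p[k])
    }))
    rows$p_fdr <- stats::p.adjust(rows$p, method = "BH")
    rows
}
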