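## One synthetic symptom dataset in the layout the fitter expects.
symptomData <- function(n, beta, seed, dispersion = 5) {
    set.seed(seed)
    edge <- rnorm(n, -2, 0.8)
    baseline <- rnorm(n, 30, 8)
    age <- rnorm(n, 16, 1.5)
    sex <- rbinom(n, 1, 0.6)
    site <- rbinom(n, 1, 0.5)
    sp <- outcomeSimSpec(betaConnectivity = beta,
                         betaCovariates = c(0.02, 0, 0.1, 0),
                         dispersion = dispersion, seed = seed + 5000)
    d <- simulateOutcomes(edge, cbind(baseline, age, sex, site), sp)
    d
}

test_that("outcome simulation honours the null-effect limit and determinism", {
    sp <- outcomeSimSpec(betaConnectivity = 0, dispersion = 500, seed = 71)
    d <- simulateOutcomes(rnorm(20000), spec = sp)
    expect_lt(abs(mean(d$score - 17) - exp(2.5)) / exp(2.5), 0.05)
    expect_identical(simulateOutcomes(rnorm(5), spec = sp)$score,
                     simulateOutcomes(rnorm(5), spec = sp)$score)
    expect_error(simulateOutcomes(rnorm(5), cbind(1:5),
                                  outcomeSimSpec(betaCovariates = c(1, 2))),
                 "dimension mismatch")
})

test_that("the symptom model recovers the generative coefficient", {
    cover <- 0
    for (s in 1:40) {
        d <- symptomData(300, -0.25, seed = 700 + s)
        f <- fitSymptomModel(d)
        ct <- coefTable(f)
        k <- match("edge", ct$term)
        ci <- ct$b[k] + c(-1.96, 1.96) * ct$se[k]
        cover <- cover + (ci[1] <= -0.25 && -0.25 <= ci[2])
    }
    expect_gte(cover, 34)
})

test_that("a Poisson-limit intercept-only fit matches the Poisson coefficients", {
    set.seed(72)
    d <- data.frame(score = 17 + rpois(500, 12), edge = rnorm(500))
    f <- fitSymptomModel(d, covariates = character(0))
    pois <- glm((score - 17) ~ edge, data = d, family = poisson())
    expect_equal(coefTable(f)$b, unname(coef(pois)), tolerance = 0.01)
    expect_gt(summary(f@fit)$theta, 50)   # dispersion pushed to the limit
})

test_that("symptom-model preconditions are enforced", {
    d <- symptomData(100, 0, seed = 73)
    d$score[1] <- 10
    expect_error(fitSymptomModel(d), "scale floor")
    d2 <- symptomData(50, 0, seed = 74)
    d2$score <- 20
    expect_error(fitSymptomModel(d2), "identical")
})

test_that("the sentiment model recovers its slope and flags collinearity", {
    cover <- 0
    for (s in 1:20) {
        set.seed(800 + s)
        n <- 200
        d <- data.frame(edge = rnorm(n, -2, 0.8),
                        mean_prop_positive = runif(n, 0.1, 0.5),
                        age = rnorm(n, 16, 1.5), sex = rbinom(n, 1, 0.6),
                        site = rbinom(n, 1, 0.5), phone = rbinom(n, 1, 0.15))
        d$mean_prop_negative <- 0.2 - 0.02 * d$edge + 0.05 * d$mean_prop_positive +
            rnorm(n, 0, 0.05)
        f <- fitSentimentModel(d)
        ct <- coefTable(f)
        k <- match("edge", ct$term)
        ci <- ct$b[k] + c(-1.96, 1.96) * ct$se[k]
        cover <- cover + (ci[1] <= -0.02 && -0.02 <= ci[2])
    }
    expect_gte(cover, 17)
    d$dup <- d$age
    expect_error(fitSentimentModel(d, covariates = c("age", "dup")),
                 "aliased")
})

test_that("the linear fit matches the normal-equation oracle to 1e-12", {
    d <- data.frame(edge = c(1, 2, 3, 4, 5),
                    mean_prop_negative = c(0.3, 0.25, 0.28, 0.2, 0.15))
    f <- fitSentimentModel(d, covariates = character(0))
    X <- cbind(1, d$edge)
    beta <- solve(t(X) %*% X, t(X) %*% d$mean_prop_negative)
    expect_equal(coefTable(f)$b, drop(beta), tolerance = 1e-12)
})

test_that("coefficients are invariant to covariate ordering", {
    d <- symptomData(150, -0.2, seed = 75)
    f1 <- fitSymptomModel(d, covariates = c("baseline", "age", "sex", "site"))
    f2 <- fitSymptomModel(d, covariates = c("site", "sex", "age", "baseline"))
    k1 <- coefTable(f1); k2 <- coefTable(f2)
    expect_equal(k1$b[k1$term == "edge"], k2$b[k2$term == "edge"],
                 tolerance = 1e-10)
})

test_that("pearsonR matches its definition and rejects degenerate input", {
    x <- c(1, 2, 4, 7)
    expect_equal(pearsonR(x, x)$r, 1)
    expect_equal(pearsonR(x, -x)$r, -1)
    y <- c(2, 1, 5, 9)
    want <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pearsonR(x, y)$r, want, tolerance = 1e-12)
    expect_error(pearsonR(c(1, 1, 1), y[1:3]), "zero variance")
    expect_error(pearsonR(1:2, 2:3), "at least 3")
})

test_that("standardized effects follow the t-to-d conversion", {
    d <- symptomData(200, -0.3, seed = 76)
    f <- fitSymptomModel(d)
    ct <- coefTable(f)
    k <- match("edge", ct$term)
    df <- f@n - nrow(ct)
    expect_equal(standardizedEffect(f, "edge"), 2 * ct$z[k] / sqrt(df))
    ## rescaling the predictor halves b but leaves d unchanged
    d2 <- d; d2$edge <- d2$edge * 2
    f2 <- fitSymptomModel(d2)
    expect_equal(coefTable(f2)$b[k] * 2, ct$b[k], tolerance = 1e-6)
    expect_equal(standardizedEffect(f2, "edge"), standardizedEffect(f, "edge"),
                 tolerance = 1e-6)
    expect_error(standardizedEffect(f, "nope"), "not in fit")
})

test_that("the FDR report adjusts across bands", {
    fits <- lapply(c(alpha = 1, beta = 2), function(s)
        fitSymptomModel(symptomData(120, -0.2, seed = 900 + s)))
    rep_ <- fdrAcrossBands(fits)
    expect_equal(rep_$p_fdr, stats::p.adjust(rep_$p, "BH"))
})
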