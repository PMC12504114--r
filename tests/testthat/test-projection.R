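## Band connectivity with hand-set values for two source channels.
twoIcConn <- function(vals) {
    v <- array(NA_real_, c(2, 2, 5))
    for (b in 1:5) { v[2, 1, b] <- vals[1]; v[1, 2, b] <- vals[2] }
    new("BandConnectivity", bands = eegBands(), values = v,
        nodeNames = c("ic1", "ic2"), level = "source")
}

test_that("the 20-mm FWHM kernel has the closed-form sigma", {
    expect_equal(fwhmToSigma(20), 8.4932, tolerance = 1e-4)
})

test_that("dipole density normalizes over the atlas support", {
    one <- sphericalAtlas(data.frame(node_id = "a", name = "a",
                                     x = 0, y = 0, z = 0, radius_mm = 15))
    w <- dipoleDensity(matrix(c(0, 0, 0), 1), one)
    expect_equal(unname(w[1, 1]), 1)
    ## equidistant between two identical nodes: equal weights
    two <- sphericalAtlas(data.frame(node_id = c("a", "b"), name = c("a", "b"),
                                     x = c(-40, 40), y = 0, z = 0,
                                     radius_mm = 15))
    w2 <- dipoleDensity(matrix(c(0, 0, 0), 1), two)
    expect_equal(unname(w2[1, 1]), unname(w2[1, 2]), tolerance = 1e-12)
    expect_equal(sum(w2), 1)
    ## far dipole: zero vector plus warning
    expect_warning(w3 <- dipoleDensity(matrix(c(500, 500, 500), 1), two),
                   "5 sigma")
    expect_equal(sum(w3), 0)
})

test_that("indicator densities make projection a pure relabeling", {
    atlas <- toyAtlas()
    W <- matrix(0, 2, 10, dimnames = list(NULL, nodeIds(atlas)))
    W[1, 3] <- 1; W[2, 7] <- 1
    ic <- twoIcConn(c(4.2, 1.1))
    node <- projectConnectivity(ic, W, atlas)
    m <- bandMatrix(node, "alpha")
    expect_equal(unname(m[7, 3]), 4.2)   # ic1 -> ic2 becomes node3 -> node7
    expect_equal(unname(m[3, 7]), 1.1)
    expect_equal(sum(!is.na(m)), 2)      # all other node pairs missing
})

test_that("split densities match the brute-force enumeration oracle", {
    atlas <- sphericalAtlas(data.frame(node_id = c("A", "B"),
                                       name = c("A", "B"),
                                       x = c(-40, 40), y = 0, z = 0,
                                       radius_mm = 15))
    W <- matrix(0.5, 2, 2, dimnames = list(NULL, c("A", "B")))
    lam <- c(4.2, 1.1)                   # ic1->ic2 and ic2->ic1
    node <- projectConnectivity(twoIcConn(lam), W, atlas)
    ## brute force: every node pair receives both IC pairs with equal
    ## weight 0.25, so each equals the unweighted mean of the IC values
    want <- mean(lam)
    for (b in names(eegBands())) {
        m <- bandMatrix(node, b)
        expect_equal(unname(m[1, 2]), want, tolerance = 1e-12)
        expect_equal(unname(m[2, 1]), want, tolerance = 1e-12)
        expect_equal(unname(m[1, 1]), want, tolerance = 1e-12)  # cross-IC within node
    }
})

test_that("projection is invariant to rescaling one IC's weights", {
    atlas <- toyAtlas()
    set.seed(41)
    W <- matrix(runif(20), 2, 10, dimnames = list(NULL, nodeIds(atlas)))
    W <- W / rowSums(W)
    ic <- twoIcConn(c(2.5, 0.7))
    a <- projectConnectivity(ic, W, atlas)
    W2 <- W; W2[1, ] <- W2[1, ] * 0.5
    b <- projectConnectivity(ic, W2, atlas)
    expect_equal(a@values, b@values, tolerance = 1e-12)
})

test_that("projected values stay inside the range of contributing IC pairs", {
    atlas <- toyAtlas()
    set.seed(42)
    n <- 6
    W <- matrix(runif(n * 10), n, 10, dimnames = list(NULL, nodeIds(atlas)))
    W <- W / rowSums(W)
    v <- array(exp(rnorm(n * n * 5)), c(n, n, 5))
    for (b in 1:5) diag(v[, , b]) <- NA
    ic <- new("BandConnectivity", bands = eegBands(), values = v,
              nodeNames = paste0("ic", 1:n), level = "source")
    node <- projectConnectivity(ic, W, atlas)
    off <- v[rep(!diag(n), 5)]
    expect_gte(min(node@values, na.rm = TRUE), min(off, na.rm = TRUE))
    expect_lte(max(node@values, na.rm = TRUE), max(off, na.rm = TRUE))
})

test_that("node retention applies the coverage threshold arithmetic", {
    atlas <- toyAtlas()
    ids <- nodeIds(atlas)
    mkDens <- function(nodes) {
        W <- matrix(0, length(nodes), 10, dimnames = list(NULL, ids))
        for (k in seq_along(nodes)) W[k, nodes[k]] <- 1
        W
    }
    ## node 1 hit by 3 of 4 participants (0.75 >= 0.65 -> retained);
    ## node 2 hit by 2 of 4 (0.50 < 0.65 -> dropped)
    dens <- list(mkDens(c(1, 2)), mkDens(c(1, 2)), mkDens(1), mkDens(3))
    cov <- retainNodes(dens, atlas)
    expect_equal(cov$coverage[1], 0.75); expect_true(cov$retained[1])
    expect_equal(cov$coverage[2], 0.50); expect_false(cov$retained[2])
    ## saturation: everyone hits every node -> all retained, mass 1
    full <- lapply(1:3, function(i) mkDens(1:10))
    cov2 <- retainNodes(full, atlas)
    expect_true(all(cov2$retained))
    expect_equal(attr(cov2, "mass_fraction"), 1)
    ## monotone: a higher threshold never adds nodes
    cov65 <- retainNodes(dens, atlas, threshold = 0.65)
    cov80 <- retainNodes(dens, atlas, threshold = 0.80)
    expect_true(all(cov80$retained <= cov65$retained))
    ## empty participants are excluded with a warning
    expect_warning(cov3 <- retainNodes(c(dens, list(mkDens(integer(0)))), atlas),
                   "excluded")
    expect_equal(cov3$coverage[1], 0.75)
})
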