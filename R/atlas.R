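#' Convert Gaussian kernel FWHM to standard deviation
#'
#' `sigma = FWHM / (2 * sqrt(2 * log(2)))`; the default 20-mm kernel gives
#' sigma ~ 8.493 mm.
#'
#' @param fwhm full width at half maximum, mm.
#' @return standard deviation in mm.
#' @export
fwhmToSigma <- function(fwhm = 20) fwhm / (2 * sqrt(2 * log(2)))

#' Build an atlas of spherical nodes
#'
#' Each node's spatial support is a deterministic cubic grid of points
#' (spacing `spacing` mm) clipped to the node's sphere; the grid always
#' contains the centre.
#'
#' @param nodes data.frame with columns `node_id`, `name`, `x`, `y`, `z`,
#'   `radius_mm` (MNI millimetre coordinates).
#' @param spacing support-grid spacing in mm (default 5).
#' @return An [Atlas].
#' @export
sphericalAtlas <- function(nodes, spacing = 5) {
    stopifnot(all(c("node_id", "name", "x", "y", "z", "radius_mm") %in% names(nodes)))
    supports <- lapply(seq_len(nrow(nodes)), function(k) {
        r <- nodes$radius_mm[k]
        g <- spacing * seq(-floor(r / spacing), floor(r / spacing))
        pts <- as.matrix(expand.grid(x = g, y = g, z = g))
        pts <- pts[rowSums(pts^2) <= r^2, , drop = FALSE]
        sweep(pts, 2, c(nodes$x[k], nodes$y[k], nodes$z[k]), `+`)
    })
    names(supports) <- nodes$node_id
    new("Atlas", nodes = as.data.frame(nodes), supports = supports)
}

#' Bundled toy atlas
#'
#' Ten spherical nodes (15-mm radius) at spread-out MNI-like coordinates,
#' loosely named after regions relevant to the analysis (mid-cingulate
#' cortex, precuneus, middle temporal gyri, occipital and frontal areas).
#' Intended as a no-download test and demo surface, not an anatomical
#' reference.
#'
#' @param spacing support-grid spacing in mm (default 5).
#' @return An [Atlas] with 10 nodes.
#' @export
toyAtlas <- function(spacing = 5) {
    nodes <- data.frame(
        node_id = c("occ_l", "occ_r", "front_l", "front_r", "precuneus",
                    "mcc", "mtg_l", "mtg_r", "parietal_mid", "calcarine"),
        name = c("left occipital", "right occipital", "left frontal",
                 "right frontal", "precuneus", "mid-cingulate cortex",
                 "left middle temporal gyrus", "right middle temporal gyrus",
                 "midline parietal", "calcarine gyrus"),
        x = c(-30, 30, -40, 40, 0, 0, -55, 55, 0, 0),
        y = c(-88, -88, 35, 35, -62, -12, -35, -35, -40, -85),
        z = c(0, 0, 30, 30, 45, 40, -5, -5, 60, 10),
        radius_mm = 15)
    sphericalAtlas(nodes, spacing = spacing)
}

#' Read an atlas from a delimited node table
#'
#' Expects columns `node_id` (or `id`), `name`, `x`, `y`, `z`,
#' `radius_mm`, in MNI millimetre coordinates.
#'
#' @param path CSV/TSV path (separator inferred from extension).
#' @param spacing support-grid spacing in mm.
#' @return An [Atlas].
#' @export
readAtlasTable <- function(path, spacing = 5) {
    sep <- if (grepl("\\.tsv$", path)) "\t" else ","
    nodes <- utils::read.table(path, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE)
    if ("id" %in% names(nodes) && !"node_id" %in% names(nodes))
        names(nodes)[names(nodes) == "id"] <- "node_id"
    sphericalAtlas(nodes, spacing = spacing)
}

#' Gaussian dipole-density weights over atlas nodes
#'
#' Each dipole coordinate is convolved with an isotropic 3-D Gaussian
#' kernel (default FWHM 20 mm) to form a probabilistic dipole-density
#' field; the weight of a node is the kernel mass falling on the node's
#' support points, normalised by the kernel's total mass over the whole
#' atlas support. A dipole farther than `5 * sigma` from every support
#' point receives a zero row with a warning.
#'
#' @param xyz numeric matrix/data.frame of dipole coordinates (rows) in
#'   mm; columns x, y, z (a data.frame with `x_mm`, `y_mm`, `z_mm` is also
#'   accepted).
#' @param atlas an [Atlas].
#' @param fwhm kernel full width at half maximum in mm (default 20).
#' @return matrix of membership weights, dipoles x nodes; rows sum to 1
#'   (or 0 for out-of-range dipoles).
#' @export
dipoleDensity <- function(xyz, atlas, fwhm = 20) {
    stopifnot(is(atlas, "Atlas"))
    if (is.data.frame(xyz)) {
        cols <- if (all(c("x_mm", "y_mm", "z_mm") %in% names(xyz)))
            c("x_mm", "y_mm", "z_mm") else c("x", "y", "z")
        xyz <- as.matrix(xyz[, cols])
    }
    xyz <- matrix(as.numeric(xyz), ncol = 3)
    if (!all(is.finite(xyz))) stop("dipole coordinates must be finite")
    sigma <- fwhmToSigma(fwhm)
    allPts <- do.call(rbind, atlas@supports)
    nodeOf <- rep(seq_along(atlas@supports),
                  vapply(atlas@supports, nrow, 1L))
    W <- matrix(0, nrow(xyz), nNodes(atlas),
                dimnames = list(NULL, nodeIds(atlas)))
    far <- logical(nrow(xyz))
    for (k in seq_len(nrow(xyz))) {
        d2 <- rowSums(sweep(allPts, 2, xyz[k, ])^2)
        if (min(d2) > (5 * sigma)^2) { far[k] <- TRUE; next }
        g <- exp(-d2 / (2 * sigma^2))
        W[k, ] <- vapply(split(g, nodeOf), sum, numeric(1)) / sum(g)
    }
    if (any(far))
        warning(sum(far), " dipole(s) farther than 5 sigma from every node support; ",
                "assigned zero weight")
    W
}
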