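#' Assemble a cohort of band connectivity
#'
#' Stacks per-participant node-level [BandConnectivity] objects into a
#' [ConnectivityCohort] (a `SummarizedExperiment` whose rows are directed
#' node pairs within a band and whose columns are participants).
#'
#' @param connList list of [BandConnectivity] objects sharing node set
#'   and bands.
#' @param participants data.frame of per-participant covariates (must
#'   include a `group` column for group comparisons); one row per element
#'   of `connList`.
#' @return A [ConnectivityCohort] with assay `"rpdc"`.
#' @export
connectivityCohort <- function(connList, participants) {
    stopifnot(length(connList) >= 1,
              nrow(participants) == length(connList))
    ref <- connList[[1]]
    nodes <- ref@nodeNames
    n <- length(nodes)
    idx <- which(row(diag(n)) != col(diag(n)), arr.ind = TRUE)  # target, source
    bands <- names(ref@bands)
    rd <- do.call(rbind, lapply(bands, function(b)
        data.frame(band = b, source = nodes[idx[, 2]],
                   target = nodes[idx[, 1]])))
    M <- vapply(connList, function(cc) {
        stopifnot(identical(cc@nodeNames, nodes),
                  identical(names(cc@bands), bands))
        unlist(lapply(seq_along(bands), function(b) cc@values[, , b][idx]),
               use.names = FALSE)
    }, numeric(nrow(rd)))
    rownames(M) <- paste0(rd$band, "|", rd$source, "->", rd$target)
    if (is.null(rownames(participants)) ||
        identical(rownames(participants), as.character(seq_len(nrow(participants)))))
        rownames(participants) <- paste0("p", seq_len(nrow(participants)))
    colnames(M) <- rownames(participants)
    se <- SummarizedExperiment(assays = list(rpdc = M),
                               rowData = S4Vectors::DataFrame(rd),
                               colData = S4Vectors::DataFrame(participants))
    new("ConnectivityCohort", se)
}

#' Extract one edge's values across a cohort
#'
#' @param cohort a [ConnectivityCohort].
#' @param band band name.
#' @param source,target node ids of the directed edge `source -> target`.
#' @param log return natural-log values (default TRUE, the scale used by
#'   the association models).
#' @return numeric vector, one value per participant.
#' @export
edgeValues <- function(cohort, band, source, target, log = TRUE) {
    rd <- rowData(cohort)
    sel <- rd$band == band & rd$source == source & rd$target == target
    if (sum(sel) != 1L)
        stop("edge not found in cohort: ", band, " ", source, " -> ", target)
    v <- assay(cohort, "rpdc")[sel, ]
    if (log) base::log(v) else v
}
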