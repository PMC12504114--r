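#' Pipeline run configuration
#'
#' Collects every tunable threshold of the analysis, defaulting to the
#' reference values used throughout the package: 20-mm dipole-density
#' kernel FWHM, 0.65 node-retention threshold, 2000 permutations,
#' 1e-4 cluster-forming p, 5-s pause boundary, 60-s deduplication window,
#' 3 messages per valid day, 7 valid days, 180-day observation window.
#' The configuration is echoed verbatim into every output manifest.
#'
#' @param nPerGroup,nSources,duration synthetic demo cohort size and
#'   recording length (seconds).
#' @param sampleRate demo generator sampling rate, Hz.
#' @param couplings planted couplings for the demo generator (see
#'   [simSpec()]); the default plants one alpha-band group difference.
#' @param order MVAR order policy: `"auto"` or an integer.
#' @param freqStep frequency-grid step in Hz.
#' @param fwhmMm dipole-density kernel FWHM, mm.
#' @param retentionThreshold node-retention participant-coverage
#'   threshold.
#' @param nPerm permutation count; `pForm` cluster-forming p.
#' @param nullStat null cluster statistic.
#' @param pauseGap,dedupeWindow,minMessages,minDays,windowDays text
#'   thresholds (seconds, seconds, messages, days, days).
#' @param seed master seed; each stage derives its own stream from it.
#' @return a validated `RunConfig` list.
#' @export
runConfig <- function(nPerGroup = 12, nSources = 10, duration = 20,
                      sampleRate = 100,
                      couplings = list(list(source = 5, target = 7,
                                            band = "alpha", strength = 0.25,
                                            groupDelta = 0.3)),
                      order = 8, freqStep = 0.5, fwhmMm = 20,
                      retentionThreshold = 0.65, nPerm = 2000L, pForm = 1e-4,
                      nullStat = "max_cluster", pauseGap = 5,
                      dedupeWindow = 60, minMessages = 3, minDays = 7,
                      windowDays = 180, seed = 1L) {
    cfg <- list(nPerGroup = nPerGroup, nSources = nSources,
                duration = duration, sampleRate = sampleRate,
                couplings = couplings, order = order,
                freqStep = freqStep, fwhmMm = fwhmMm,
                retentionThreshold = retentionThreshold,
                nPerm = as.integer(nPerm), pForm = pForm,
                nullStat = nullStat, pauseGap = pauseGap,
                dedupeWindow = dedupeWindow, minMessages = minMessages,
                minDays = minDays, windowDays = windowDays,
                seed = as.integer(seed))
    if (cfg$retentionThreshold < 0 || cfg$retentionThreshold > 1)
        stop("retentionThreshold must lie in [0, 1]")
    if (cfg$fwhmMm <= 0) stop("fwhmMm must be positive")
    if (cfg$pForm <= 0 || cfg$pForm >= 1) stop("pForm must lie in (0, 1)")
    if (cfg$nPerm < 100) stop("nPerm must be at least 100")
    if (cfg$pauseGap < 0 || cfg$dedupeWindow < 0) stop("negative time threshold")
    structure(cfg, class = "RunConfig")
}

stageSeed <- function(config, stage) {
    offs <- match(stage, c("simulate", "connect", "project", "groupdiff",
                           "text", "associate"))
    (config$seed * 7919L + offs * 104729L) %% 2147483647L
}

#' Run the end-to-end demonstration pipeline on synthetic data
#'
#' Executes the requested stages in dependency order on a synthetic
#' cohort: `simulate` (MVAR recordings, dipoles, keystroke logs),
#' `connect` (MVAR fit, rPDC, band averages), `project` (dipole-density
#' projection and node retention), `groupdiff` (cluster permutation
#' test), `text` (message reconstruction and sentiment metrics) and
#' `associate` (outcome models on a selected edge). Writes tidy CSV/JSON
#' artifacts plus a manifest recording the config echo, per-stage seeds
#' and md5 hashes of every output; a rerun with the same config
#' reproduces the hashes.
#'
#' @param config a [runConfig()].
#' @param outDir output directory (created if missing).
#' @param stages subset of stages to run (default all).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config = runConfig(), outDir = tempfile("rpdcnet-run-"),
                        stages = c("simulate", "connect", "project",
                                   "groupdiff", "text", "associate")) {
    stopifnot(inherits(config, "RunConfig"))
    stages <- match.arg(stages, several.ok = TRUE)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    state <- list(config = config)
    say <- function(...) message(sprintf(...))

    if ("simulate" %in% stages) {
        atlas <- toyAtlas()
        spec <- simSpec(nPerGroup = config$nPerGroup,
                        nSources = config$nSources,
                        sampleRate = config$sampleRate,
                        duration = config$duration,
                        couplings = config$couplings,
                        seed = stageSeed(config, "simulate"))
        state$atlas <- atlas
        state$cohort <- simulateMvarCohort(spec, atlas = atlas)
        nTot <- length(state$cohort$recordings)
        dip <- do.call(rbind, lapply(seq_len(nTot), function(k)
            cbind(participant = k, state$cohort$recordings[[k]]$dipoles)))
        write.csv(dip, file.path(outDir, "dipoles.csv"), row.names = FALSE)
        kspec <- lapply(seq_len(nTot), function(k)
            keystrokeSimSpec(nDays = 30, msgsPerDay = 6,
                             pNegative = 0.15 + 0.1 * (state$cohort$group[k] == 2),
                             pPositive = 0.3, pauseGap = config$pauseGap,
                             seed = (stageSeed(config, "text") + k) %% 2147483647L))
        state$keystrokes <- lapply(kspec, simulateKeystrokes)
        say("simulate: %d participants, %d sources", nTot, config$nSources)
    }
    if ("connect" %in% stages) {
        if (is.null(state$cohort)) stop("run the 'simulate' stage first")
        freqs <- seq(1, 40, by = config$freqStep)
        state$bandConn <- lapply(state$cohort$recordings, function(rec)
            bandAverage(computeRpdc(
                fitMvar(rec$series, order = config$order,
                        sampleRate = config$sampleRate),
                freqs = freqs)))
        say("connect: fitted %d recordings", length(state$bandConn))
    }
    if ("project" %in% stages) {
        if (is.null(state$bandConn)) stop("run the 'connect' stage first")
        dens <- lapply(state$cohort$recordings, function(rec)
            dipoleDensity(rec$dipoles, state$atlas, fwhm = config$fwhmMm))
        coverage <- retainNodes(dens, state$atlas,
                                threshold = config$retentionThreshold)
        nodeConn <- Map(function(bc, w)
            projectConnectivity(bc, w, state$atlas), state$bandConn, dens)
        cc <- connectivityCohort(nodeConn,
                                 data.frame(group = factor(state$cohort$group)))
        keepNodes <- coverage$node_id[coverage$retained]
        rd <- rowData(cc)
        state$nodeCohort <- cc[rd$source %in% keepNodes &
                               rd$target %in% keepNodes, ]
        state$coverage <- coverage
        write.csv(cbind(coverage,
                        mass_fraction = attr(coverage, "mass_fraction")),
                  file.path(outDir, "node_coverage.csv"), row.names = FALSE)
        say("project: %d/%d nodes retained (mass fraction %.3f)",
            sum(coverage$retained), nrow(coverage),
            attr(coverage, "mass_fraction"))
    }
    if ("groupdiff" %in% stages) {
        if (is.null(state$nodeCohort)) stop("run the 'project' stage first")
        res <- permuteClusters(state$nodeCohort, nPerm = config$nPerm,
                               pForm = config$pForm,
                               nullStat = config$nullStat,
                               seed = stageSeed(config, "groupdiff"))
        state$clusters <- res
        jsonlite::write_json(
            list(config = unclass(config), clusters = clusterTable(res),
                 edges = clusterEdges(res)),
            file.path(outDir, "clusters.json"), auto_unbox = TRUE,
            digits = NA, na = "null")
        write.csv(res@edgeStats, file.path(outDir, "edge_stats.csv"),
                  row.names = FALSE)
        say("groupdiff: %d cluster(s) found over %d edges tested",
            nrow(clusterTable(res)), sum(!is.na(res@edgeStats$t)))
    }
    if ("text" %in% stages) {
        if (is.null(state$keystrokes)) stop("run the 'simulate' stage first")
        tp <- lapply(state$keystrokes, function(ks)
            textPipeline(ks$log, pauseGap = config$pauseGap,
                         dedupeWindow = config$dedupeWindow,
                         windowDays = config$windowDays,
                         minMessages = config$minMessages,
                         minDays = config$minDays))
        state$text <- tp
        person <- do.call(rbind, lapply(seq_along(tp), function(k)
            cbind(participant = k, tp[[k]]$person)))
        write.csv(person, file.path(outDir, "person_sentiment.csv"),
                  row.names = FALSE)
        say("text: %d participants, %d included by the 3-message/7-day rule",
            nrow(person), sum(person$included))
    }
    if ("associate" %in% stages) {
        if (is.null(state$nodeCohort) || is.null(state$text))
            stop("run the 'project' and 'text' stages first")
        rd <- rowData(state$nodeCohort)
        pick <- which(rd$band == "alpha" & rd$source == "mcc" &
                      rd$target == "precuneus")
        if (!length(pick)) pick <- which(!is.na(rowSums(assay(state$nodeCohort))))[1]
        edge <- log(assay(state$nodeCohort, "rpdc")[pick[1], ])
        scores <- simulateOutcomes(edge, covariates = NULL,
                                   spec = outcomeSimSpec(betaConnectivity = -0.25,
                                       seed = stageSeed(config, "associate")))
        person <- do.call(rbind, lapply(state$text, `[[`, "person"))
        assoc <- data.frame(edge = edge, score = scores$score,
                            mean_prop_negative = person$mean_prop_negative,
                            mean_prop_positive = person$mean_prop_positive)
        symp <- fitSymptomModel(assoc, covariates = character(0))
        sent <- fitSentimentModel(assoc[person$included, ],
                                  covariates = "mean_prop_positive")
        state$associations <- list(symptom = symp, sentiment = sent)
        write.csv(coefTable(symp), file.path(outDir, "symptom_model.csv"),
                  row.names = FALSE)
        write.csv(coefTable(sent), file.path(outDir, "sentiment_model.csv"),
                  row.names = FALSE)
        say("associate: edge %s|%s->%s", rd$band[pick[1]], rd$source[pick[1]],
            rd$target[pick[1]])
    }

    files <- list.files(outDir, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    manifest <- list(
        config = unclass(config),
        stages = stages,
        stage_seeds = setNames(lapply(stages, function(s) stageSeed(config, s)),
                               stages),
        hashes = as.list(tools::md5sum(files)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    state$manifest <- manifest
    invisible(state)
}
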