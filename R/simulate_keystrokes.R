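## Token lists used by the bundled lexicon classifier and the keystroke
## generator. Deliberately disjoint so a message's ground-truth label is
## always recoverable by token counting.
lexiconTokens <- function() {
    list(positive = c("great", "love", "happy", "good", "awesome", "joy",
                      "nice", "fun", "glad", "cool"),
         negative = c("bad", "sad", "awful", "hate", "terrible", "angry",
                      "cry", "worst", "upset", "lonely"),
         neutral  = c("the", "okay", "maybe", "school", "phone", "later",
                      "time", "today", "thing", "about"))
}

#' Specification for a synthetic keystroke stream
#'
#' Describes per-participant smartphone keystroke logs with known message
#' boundaries and a known sentiment mix. Messages are typed character by
#' character (inter-key gaps well under 5 s), occasionally interrupted by
#' a mistyped character immediately corrected with a backspace, and
#' terminated by an enter key, an app switch, or a typing pause. Genuine
#' messages are separated by at least `interMessageGap` seconds so the
#' 60-s deduplication window cannot remove them; duplicate "partial
#' string" artifacts (a prefix of the next message, same app, within the
#' window) are injected with probability `pPartial` and flagged in the
#' ground truth.
#'
#' @param nDays observation days (default 180, a 6-month window).
#' @param msgsPerDay mean messages per day (Poisson).
#' @param pNegative,pPositive probabilities that a message is negative /
#'   positive (remaining mass is neutral); `pNegative + pPositive <= 1`.
#' @param pauseGap seconds of silence that constitutes a message boundary
#'   (must be >= 5 so ground-truth boundaries are recoverable).
#' @param interMessageGap seconds between consecutive genuine messages
#'   (default 90).
#' @param backspaceRate per-character probability of a typo + backspace
#'   pair (default 0.05).
#' @param pPartial probability that a message is preceded by a partial
#'   duplicate artifact (default 0.1).
#' @param apps character vector of app identifiers to draw from.
#' @param seed integer seed.
#' @return An object of class `KeystrokeSimSpec`.
#' @export
keystrokeSimSpec <- function(nDays = 180, msgsPerDay = 5, pNegative = 0.2,
                             pPositive = 0.3, pauseGap = 5,
                             interMessageGap = 90, backspaceRate = 0.05,
                             pPartial = 0.1,
                             apps = c("messages", "instagram", "snapchat"),
                             seed = 1L) {
    stopifnot(nDays >= 1, msgsPerDay >= 0, pNegative >= 0, pPositive >= 0,
              backspaceRate >= 0, backspaceRate < 1, pPartial >= 0, pPartial <= 1)
    if (pNegative + pPositive > 1)
        stop("pNegative + pPositive must not exceed 1")
    if (pauseGap < 5)
        stop("pauseGap must be at least 5 s so ground-truth boundaries are recoverable")
    if (interMessageGap < pauseGap)
        stop("interMessageGap must be at least pauseGap")
    structure(list(nDays = as.integer(nDays), msgsPerDay = msgsPerDay,
                   pNegative = pNegative, pPositive = pPositive,
                   pauseGap = pauseGap, interMessageGap = interMessageGap,
                   backspaceRate = backspaceRate, pPartial = pPartial,
                   apps = apps, seed = as.integer(seed)),
              class = "KeystrokeSimSpec")
}

randomMessageText <- function(label) {
    tok <- lexiconTokens()
    main <- sample(tok[[label]], sample(2:4, 1), replace = TRUE)
    filler <- if (label == "neutral") character(0) else
        sample(tok$neutral, sample(0:1, 1), replace = TRUE)
    paste(sample(c(main, filler)), collapse = " ")
}

## Emit keystroke rows for one message text: per-character records with
## optional typo+backspace pairs. Returns data.frame(t, key) with t in
## seconds relative to the message start.
typeMessage <- function(text, backspaceRate) {
    chars <- strsplit(text, "")[[1]]
    keys <- character(0)
    for (ch in chars) {
        if (runif(1) < backspaceRate) {
            keys <- c(keys, sample(letters, 1), "BACKSPACE")
        }
        keys <- c(keys, ch)
    }
    gaps <- runif(length(keys), 0.08, 0.35)
    data.frame(t = cumsum(gaps), key = keys, stringsAsFactors = FALSE)
}

#' Simulate keystroke logs with known ground truth
#'
#' @param spec a [keystrokeSimSpec()].
#' @return list with elements
#'   \describe{
#'     \item{log}{data.frame of keypress records: `t` (POSIXct, UTC),
#'       `key` (single character, `"BACKSPACE"` or `"ENTER"`), `app`.}
#'     \item{truth}{list with `messages` (data.frame day, start, text,
#'       label, app, artifact flag -- artifacts are injected partial
#'       duplicates that deduplication should remove) and `daily`
#'       (data.frame date, n_messages, prop_negative, prop_positive over
#'       genuine messages; days without messages are absent).}
#'   }
#' @export
simulateKeystrokes <- function(spec) {
    stopifnot(inherits(spec, "KeystrokeSimSpec"))
    set.seed(spec$seed)
    origin <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")
    logs <- list(); truthRows <- list()
    for (day in seq_len(spec$nDays)) {
        nMsg <- rpois(1, spec$msgsPerDay)
        if (nMsg == 0) next
        t0 <- as.numeric(origin) + (day - 1) * 86400 + 8 * 3600
        for (m in seq_len(nMsg)) {
            u <- runif(1)
            label <- if (u < spec$pNegative) "negative"
                     else if (u < spec$pNegative + spec$pPositive) "positive"
                     else "neutral"
            text <- randomMessageText(label)
            app <- sample(spec$apps, 1)
            if (nchar(text) >= 4 && runif(1) < spec$pPartial) {
                ## partial duplicate: a prefix typed in the same app,
                ## ending (pause boundary) within the 60-s dedupe window
                prefix <- substr(text, 1, sample(2:(nchar(text) - 1), 1))
                ks <- typeMessage(prefix, 0)
                logs[[length(logs) + 1L]] <-
                    data.frame(t = t0 + ks$t, key = ks$key, app = app,
                               stringsAsFactors = FALSE)
                truthRows[[length(truthRows) + 1L]] <-
                    data.frame(day = day, start = t0, text = prefix,
                               label = label, app = app, artifact = TRUE,
                               stringsAsFactors = FALSE)
                t0 <- t0 + max(ks$t) + runif(1, spec$pauseGap + 1, 30)
            }
            ks <- typeMessage(text, spec$backspaceRate)
            useEnter <- runif(1) < 0.5
            rows <- data.frame(t = t0 + ks$t, key = ks$key, app = app,
                               stringsAsFactors = FALSE)
            if (useEnter)
                rows <- rbind(rows, data.frame(t = t0 + max(ks$t) + 0.2,
                                               key = "ENTER", app = app))
            logs[[length(logs) + 1L]] <- rows
            truthRows[[length(truthRows) + 1L]] <-
                data.frame(day = day, start = t0, text = text, label = label,
                           app = app, artifact = FALSE, stringsAsFactors = FALSE)
            t0 <- t0 + max(ks$t) + spec$interMessageGap + runif(1, 0, 30)
        }
    }
    log <- do.call(rbind, logs)
    truth <- do.call(rbind, truthRows)
    if (is.null(log)) {
        log <- data.frame(t = as.POSIXct(character(0), tz = "UTC"),
                          key = character(0), app = character(0))
        truth <- data.frame(day = integer(0), start = numeric(0),
                            text = character(0), label = character(0),
                            app = character(0), artifact = logical(0))
    }
    log$t <- as.POSIXct(log$t, origin = "1970-01-01", tz = "UTC")
    truth$start <- as.POSIXct(truth$start, origin = "1970-01-01", tz = "UTC")
    genuine <- truth[!truth$artifact, , drop = FALSE]
    daily <- if (nrow(genuine)) {
        dates <- as.Date(genuine$start, tz = "UTC")
        agg <- lapply(split(genuine, dates), function(d)
            data.frame(date = as.Date(d$start[1], tz = "UTC"),
                       n_messages = nrow(d),
                       prop_negative = mean(d$label == "negative"),
                       prop_positive = mean(d$label == "positive")))
        out <- do.call(rbind, agg); rownames(out) <- NULL; out
    } else data.frame(date = as.Date(character(0)), n_messages = integer(0),
                      prop_negative = numeric(0), prop_positive = numeric(0))
    list(log = log, truth = list(messages = truth, daily = daily))
}

#' Write a keystroke log as JSON lines
#'
#' One JSON object per keypress: `{"t": ISO-8601, "key": ..., "app": ...}`.
#'
#' @param log keystroke data.frame as from [simulateKeystrokes()].
#' @param path output file path.
#' @export
writeKeystrokeJsonl <- function(log, path) {
    recs <- vapply(seq_len(nrow(log)), function(i) {
        jsonlite::toJSON(list(t = format(log$t[i], "%Y-%m-%dT%H:%M:%OS3Z",
                                         tz = "UTC"),
                              key = log$key[i], app = log$app[i]),
                         auto_unbox = TRUE)
    }, character(1))
    writeLines(recs, path)
}

#' Read a keystroke log from JSON lines
#'
#' @param path file of one JSON object per keypress (`t`, `key`, `app`).
#' @return data.frame with POSIXct `t`, `key`, `app`.
#' @export
readKeystrokeJsonl <- function(path) {
    recs <- lapply(readLines(path), jsonlite::fromJSON)
    data.frame(t = as.POSIXct(vapply(recs, `[[`, "", "t"),
                              format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"),
               key = vapply(recs, `[[`, "", "key"),
               app = vapply(recs, `[[`, "", "app"),
               stringsAsFactors = FALSE)
}
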