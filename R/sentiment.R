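#' Clean message text for sentiment classification
#'
#' Removes URLs (scheme- or `www.`-prefixed tokens) and `@user` mentions,
#' collapses elongated words (runs of three or more identical letters
#' become a single letter, so "noooo" becomes "no"), and normalises
#' whitespace. Punctuation, capitalization, emojis and hashtags are
#' preserved. The transformation is idempotent. Note the elongation rule
#' can over-collapse legitimate double letters inside longer runs (e.g.
#' "soooon" becomes "son").
#'
#' @param text character vector.
#' @return cleaned character vector.
#' @export
#' @examples
#' cleanText("noooo")                    # "no"
#' cleanText("see http://x.co @sam!")    # "see !"
#' cleanText("#joytotheworld \U0001F600") # unchanged
cleanText <- function(text) {
    x <- gsub("(?i)\\b(?:[a-z][a-z0-9+.-]*://\\S+|www\\.\\S+)", "", text,
              perl = TRUE)
    x <- gsub("@\\w+", "", x)
    x <- gsub("([[:alpha:]])\\1{2,}", "\\1", x)
    x <- gsub("[[:space:]]+", " ", x)
    trimws(x)
}

#' Bundled lexicon sentiment classifier
#'
#' A deterministic token-count stub standing in for a transformer-based
#' sentiment model: it labels a message by the majority of matched
#' positive versus negative lexicon tokens (case-insensitive,
#' punctuation-stripped); ties, no matches and empty messages are
#' neutral.
#'
#' @return a function mapping a character vector to labels in
#'   `c("positive", "negative", "neutral")`.
#' @export
lexiconClassifier <- function() {
    tok <- lexiconTokens()
    function(text) {
        vapply(text, function(msg) {
            words <- tolower(unlist(strsplit(gsub("[^[:alnum:]#@' ]", " ", msg),
                                             "[[:space:]]+")))
            npos <- sum(words %in% tok$positive)
            nneg <- sum(words %in% tok$negative)
            if (npos > nneg) "positive" else if (nneg > npos) "negative"
            else "neutral"
        }, character(1), USE.NAMES = FALSE)
    }
}

#' Attach sentiment labels to messages
#'
#' Applies a classifier (any function from text to one label per
#' message) to cleaned message text. Exactly one label per message; a
#' classifier emitting anything outside positive/negative/neutral is an
#' error.
#'
#' @param msgs message data.frame with a `text` column.
#' @param classifier labelling function (default [lexiconClassifier()]).
#' @param clean apply [cleanText()] first (default TRUE).
#' @return `msgs` with added columns `clean_text` and `label`.
#' @export
classifyMessages <- function(msgs, classifier = lexiconClassifier(),
                             clean = TRUE) {
    txt <- if (clean) cleanText(msgs$text) else msgs$text
    lab <- classifier(txt)
    if (length(lab) != nrow(msgs))
        stop("classifier must return one label per message")
    bad <- setdiff(unique(lab), c("positive", "negative", "neutral"))
    if (length(bad))
        stop("classifier returned out-of-vocabulary label(s): ",
             paste(bad, collapse = ", "))
    msgs$clean_text <- txt
    msgs$label <- lab
    msgs
}

#' Daily and person-level sentiment metrics
#'
#' Computes, per calendar day (date of the message start timestamp), the
#' proportions of negative and positive messages relative to that day's
#' total, then averages the proportions (unweighted) over valid days to
#' give person-level metrics. A valid day has at least `minMessages`
#' messages; a participant is included when they have at least `minDays`
#' valid days within the first `windowDays` days of observation (counted
#' from their first message).
#'
#' @param records labelled message data.frame (columns `start`, `label`).
#' @param windowDays observation window in days (default 180).
#' @param minMessages messages needed for a valid day (default 3).
#' @param minDays valid days needed for inclusion (default 7).
#' @param tz timezone for day boundaries (default `"UTC"`; day boundaries
#'   fall at local midnight of this zone).
#' @return list with `daily` (data.frame date, n_messages, prop_negative,
#'   prop_positive, valid, in_window) and `person` (one-row data.frame
#'   mean_prop_negative, mean_prop_positive, n_valid_days, included).
#' @export
sentimentMetrics <- function(records, windowDays = 180, minMessages = 3,
                             minDays = 7, tz = "UTC") {
    if (!nrow(records))
        return(list(daily = data.frame(date = as.Date(character(0)),
                                       n_messages = integer(0),
                                       prop_negative = numeric(0),
                                       prop_positive = numeric(0),
                                       valid = logical(0), in_window = logical(0)),
                    person = data.frame(mean_prop_negative = NA_real_,
                                        mean_prop_positive = NA_real_,
                                        n_valid_days = 0L, included = FALSE)))
    dates <- as.Date(records$start, tz = tz)
    daily <- do.call(rbind, lapply(split(records$label, dates), function(lab)
        data.frame(n_messages = length(lab),
                   prop_negative = mean(lab == "negative"),
                   prop_positive = mean(lab == "positive"))))
    daily <- cbind(date = as.Date(rownames(daily)), daily)
    rownames(daily) <- NULL
    daily$valid <- daily$n_messages >= minMessages
    daily$in_window <- as.integer(daily$date - min(daily$date)) < windowDays
    use <- daily$valid & daily$in_window
    person <- data.frame(
        mean_prop_negative = if (any(use)) mean(daily$prop_negative[use]) else NA_real_,
        mean_prop_positive = if (any(use)) mean(daily$prop_positive[use]) else NA_real_,
        n_valid_days = sum(use),
        included = sum(use) >= minDays)
    list(daily = daily, person = person)
}

#' Full text pipeline for one participant
#'
#' Reconstruct, deduplicate, retain, clean, classify and aggregate a raw
#' keystroke log in one call: the stage order is reconstruct ->
#' deduplicate -> length filter -> clean/classify -> metrics.
#'
#' @param events keystroke data.frame (`t`, `key`, `app`).
#' @param classifier sentiment classifier (default [lexiconClassifier()]).
#' @param pauseGap,dedupeWindow,windowDays,minMessages,minDays pipeline
#'   thresholds; defaults 5 s, 60 s, 180 days, 3 messages, 7 days.
#' @return list with `messages` (labelled survivors) and the
#'   [sentimentMetrics()] output (`daily`, `person`).
#' @export
textPipeline <- function(events, classifier = lexiconClassifier(),
                         pauseGap = 5, dedupeWindow = 60, windowDays = 180,
                         minMessages = 3, minDays = 7) {
    msgs <- reconstructMessages(events, pauseGap = pauseGap)
    msgs <- dedupeMessages(msgs, window = dedupeWindow)
    msgs <- retainMessages(msgs)
    msgs <- classifyMessages(msgs, classifier)
    metrics <- sentimentMetrics(msgs, windowDays = windowDays,
                                minMessages = minMessages, minDays = minDays)
    c(list(messages = msgs), metrics)
}
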