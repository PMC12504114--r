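#' Reconstruct messages from a keystroke stream
#'
#' Replays time-stamped keypress events into messages. Characters
#' accumulate in a buffer; `"BACKSPACE"` deletes the last buffered
#' character (a no-op on an empty buffer); the buffer is emitted as a
#' message at each boundary. Boundaries are: a pause of at least
#' `pauseGap` seconds before the next keypress, a change of active app,
#' or an `"ENTER"` key (which emits without adding a character). Empty
#' buffers emit nothing. With `overlapRule = TRUE`, a secondary pass
#' mirrors logger-side segmentation: a string sharing at least 50% of its
#' longest common prefix with the preceding message in the same app is
#' treated as a revision of that message and merged into it (the later
#' text wins); a string with less than 50% overlap stays a separate
#' message.
#'
#' @param events data.frame with columns `t` (POSIXct or numeric
#'   seconds, nondecreasing), `key` (single character, `"BACKSPACE"` or
#'   `"ENTER"`), and optionally `app`.
#' @param pauseGap boundary pause in seconds (default 5).
#' @param overlapRule apply the <50% prefix-overlap secondary splitter
#'   (default FALSE).
#' @return data.frame with columns `text`, `start`, `end` (same class as
#'   `t`), `app`, `boundary_reason` (`"pause"`, `"app_switch"`,
#'   `"enter"`, `"overlap_rule"` or `"stream_end"`).
#' @export
reconstructMessages <- function(events, pauseGap = 5, overlapRule = FALSE) {
    if (!nrow(events))
        return(data.frame(text = character(0), start = numeric(0),
                          end = numeric(0), app = character(0),
                          boundary_reason = character(0)))
    tt <- as.numeric(events$t)
    if (is.unsorted(tt)) {
        bad <- which(diff(tt) < 0)[1] + 1L
        stop("timestamps not nondecreasing; first offending index: ", bad)
    }
    app <- if ("app" %in% names(events)) as.character(events$app)
           else rep(NA_character_, nrow(events))
    key <- as.character(events$key)
    msgs <- list()
    buf <- character(0); bufStart <- NA_real_; bufEnd <- NA_real_
    curApp <- app[1]
    emit <- function(reason) {
        if (length(buf))
            msgs[[length(msgs) + 1L]] <<- data.frame(
                text = paste(buf, collapse = ""), start = bufStart,
                end = bufEnd, app = curApp, boundary_reason = reason,
                stringsAsFactors = FALSE)
        buf <<- character(0); bufStart <<- NA_real_; bufEnd <<- NA_real_
    }
    for (k in seq_along(key)) {
        if (k > 1) {
            if (!identical(app[k], app[k - 1]) &&
                !(is.na(app[k]) && is.na(app[k - 1]))) {
                emit("app_switch"); curApp <- app[k]
            } else if (tt[k] - tt[k - 1] >= pauseGap) {
                emit("pause")
            }
        }
        if (key[k] == "ENTER") {
            bufEnd <- tt[k]
            emit("enter")
        } else if (key[k] == "BACKSPACE") {
            if (length(buf)) buf <- buf[-length(buf)]
            bufEnd <- tt[k]
        } else {
            if (!length(buf)) bufStart <- tt[k]
            buf <- c(buf, key[k]); bufEnd <- tt[k]
        }
    }
    emit("stream_end")
    out <- do.call(rbind, msgs)
    if (is.null(out))
        return(data.frame(text = character(0), start = numeric(0),
                          end = numeric(0), app = character(0),
                          boundary_reason = character(0)))
    if (overlapRule) out <- applyOverlapRule(out)
    if (inherits(events$t, "POSIXct")) {
        out$start <- as.POSIXct(out$start, origin = "1970-01-01",
                                tz = attr(events$t, "tzone") %||% "UTC")
        out$end <- as.POSIXct(out$end, origin = "1970-01-01",
                              tz = attr(events$t, "tzone") %||% "UTC")
    }
    rownames(out) <- NULL
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Secondary logger-style segmentation: a string with >= 50% longest-
## common-prefix overlap with the preceding same-app message is a
## revision of it and is merged (boundary_reason overlap_rule); < 50%
## overlap keeps it a separate message.
applyOverlapRule <- function(msgs) {
    if (nrow(msgs) < 2) return(msgs)
    keep <- rep(TRUE, nrow(msgs))
    prev <- 1L
    for (k in 2:nrow(msgs)) {
        a <- msgs$text[prev]; b <- msgs$text[k]
        n <- min(nchar(a), nchar(b))
        lcp <- 0
        while (lcp < n && substr(a, lcp + 1, lcp + 1) == substr(b, lcp + 1, lcp + 1))
            lcp <- lcp + 1
        sameApp <- identical(msgs$app[prev], msgs$app[k])
        if (sameApp && lcp / max(nchar(a), nchar(b)) >= 0.5) {
            msgs$text[prev] <- if (nchar(b) >= nchar(a)) b else a
            msgs$end[prev] <- msgs$end[k]
            msgs$boundary_reason[prev] <- "overlap_rule"
            keep[k] <- FALSE
        } else prev <- k
    }
    msgs[keep, , drop = FALSE]
}

#' Drop partial or redundant messages
#'
#' Removes a message when its text is entirely contained in the next
#' message's text, both were typed in the same app, and the next message
#' started within `window` seconds of this one ending. Single left-to-
#' right pass over chronologically ordered messages.
#'
#' @param msgs message data.frame as from [reconstructMessages()].
#' @param window containment window in seconds (default 60).
#' @return the filtered message data.frame.
#' @export
dedupeMessages <- function(msgs, window = 60) {
    if (nrow(msgs) < 2) return(msgs)
    drop <- logical(nrow(msgs))
    for (k in seq_len(nrow(msgs) - 1L)) {
        sameApp <- identical(msgs$app[k], msgs$app[k + 1]) ||
            (is.na(msgs$app[k]) && is.na(msgs$app[k + 1]))
        within <- as.numeric(msgs$start[k + 1]) - as.numeric(msgs$end[k]) <= window
        if (sameApp && within &&
            grepl(msgs$text[k], msgs$text[k + 1], fixed = TRUE))
            drop[k] <- TRUE
    }
    out <- msgs[!drop, , drop = FALSE]
    rownames(out) <- NULL
    out
}

isSingleEmoji <- function(x) {
    if (nchar(x) != 1L) return(FALSE)
    cp <- utf8ToInt(x)
    (cp >= 0x1F000 && cp <= 0x1FAFF) || (cp >= 0x2600 && cp <= 0x27BF)
}

#' Retain analyzable messages
#'
#' Keeps messages longer than one character, plus single-character
#' emojis.
#'
#' @param msgs message data.frame.
#' @return the filtered data.frame.
#' @export
retainMessages <- function(msgs) {
    keep <- nchar(msgs$text) > 1 | vapply(msgs$text, isSingleEmoji, logical(1))
    out <- msgs[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}
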