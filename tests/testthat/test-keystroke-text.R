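ev <- function(t, key, app = "messages")
    data.frame(t = t, key = key, app = app, stringsAsFactors = FALSE)

test_that("message boundaries follow enter, pause and app switch", {
    ## minimal enter-terminated message
    m <- reconstructMessages(ev(c(0, 0.2, 0.5), c("h", "i", "ENTER")))
    expect_equal(m$text, "hi")
    expect_equal(m$boundary_reason, "enter")
    ## backspace deletes, a >= 5 s pause splits
    m2 <- reconstructMessages(ev(c(0, .2, .4, .6, 7, 7.2),
                                 c("n", "o", "o", "BACKSPACE", "o", "k")))
    expect_equal(m2$text, c("no", "ok"))
    expect_equal(m2$boundary_reason, c("pause", "stream_end"))
    ## a 4.9 s gap does not split
    m3 <- reconstructMessages(ev(c(0, 4.9), c("a", "b")))
    expect_equal(m3$text, "ab")
    ## app switch splits even without a pause
    m4 <- reconstructMessages(
        ev(c(0, .2, .4, .6), c("h", "i", "y", "o"),
           app = c("messages", "messages", "snapchat", "snapchat")))
    expect_equal(m4$text, c("hi", "yo"))
    expect_equal(m4$boundary_reason[1], "app_switch")
    ## backspace on an empty buffer is a no-op; empty buffers emit nothing
    m5 <- reconstructMessages(ev(c(0, 1, 1.2), c("BACKSPACE", "ENTER", "x")))
    expect_equal(m5$text, "x")
    ## unsorted timestamps are rejected with the offending index
    expect_error(reconstructMessages(ev(c(1, 0.5), c("a", "b"))), "index: 2")
})

test_that("trailing backspaces remove the typed characters", {
    m <- reconstructMessages(ev(c(0, .1, .2, .3, .4, 9),
                                c("n", "o", "p", "BACKSPACE", "BACKSPACE", "k")))
    expect_equal(m$text[1], "n")
})

test_that("deduplication drops contained strings in the 60-s same-app window", {
    base <- as.POSIXct("2024-03-01 10:00:00", tz = "UTC")
    msgs <- data.frame(text = c("hell", "hello there"),
                       start = base + c(0, 12), end = base + c(2, 20),
                       app = "messages",
                       boundary_reason = c("pause", "enter"))
    expect_equal(dedupeMessages(msgs)$text, "hello there")
    ## 90 s apart: both kept
    msgs90 <- msgs; msgs90$start[2] <- base + 95; msgs90$end[2] <- base + 100
    expect_equal(nrow(dedupeMessages(msgs90)), 2L)
    ## different apps: both kept
    msgsApp <- msgs; msgsApp$app <- c("messages", "snapchat")
    expect_equal(nrow(dedupeMessages(msgsApp)), 2L)
})

test_that("retention keeps multi-character messages and single emojis", {
    msgs <- data.frame(text = c("a", "ab", "\U0001F600", "!"),
                       start = 1:4, end = 1:4, app = "m",
                       boundary_reason = "enter")
    expect_equal(retainMessages(msgs)$text, c("ab", "\U0001F600"))
})

test_that("text cleaning matches the documented rules and is idempotent", {
    expect_equal(cleanText("noooo"), "no")
    expect_equal(cleanText("see http://x.co @sam!"), "see !")
    expect_equal(cleanText("#joytotheworld \U0001F600"),
                 "#joytotheworld \U0001F600")
    expect_equal(cleanText("check www.example.com now"), "check now")
    expect_equal(cleanText("Hey!! SO fun..."), "Hey!! SO fun...")
    x <- c("noooo", "a   b", "@me you", "HTTPS://A.B cool")
    expect_equal(cleanText(cleanText(x)), cleanText(x))
})

test_that("the lexicon stub labels by token majority with neutral ties", {
    cls <- lexiconClassifier()
    expect_equal(cls("great great bad"), "positive")
    expect_equal(cls("bad great"), "neutral")
    expect_equal(cls(""), "neutral")
    expect_equal(cls("awful day at school"), "negative")
    msgs <- data.frame(text = c("love it", "hate it"), start = 1:2,
                       end = 1:2, app = "m", boundary_reason = "enter")
    out <- classifyMessages(msgs)
    expect_equal(out$label, c("positive", "negative"))
    expect_error(classifyMessages(msgs, classifier = function(x)
        rep("meh", length(x))), "out-of-vocabulary")
})

test_that("daily metrics and the inclusion rule follow the thresholds", {
    base <- as.POSIXct("2024-01-01 09:00:00", tz = "UTC")
    rec <- data.frame(
        start = c(base, base + 60, base + 120,         # day 1: neg neg pos
                  base + 86400, base + 86460),         # day 2: two messages
        label = c("negative", "negative", "positive", "negative", "neutral"))
    m <- sentimentMetrics(rec)
    expect_equal(m$daily$prop_negative, c(2 / 3, 1 / 2))
    expect_equal(m$daily$prop_positive, c(1 / 3, 0))
    expect_equal(m$daily$valid, c(TRUE, FALSE))
    ## person level averages valid days only; 1 valid day < 7 -> excluded
    expect_equal(m$person$mean_prop_negative, 2 / 3)
    expect_false(m$person$included)
    ## 6 valid days still excluded, 7 included
    mk <- function(nd) data.frame(
        start = rep(base + 86400 * (seq_len(nd) - 1), each = 3) + 1:3,
        label = "negative")
    expect_false(sentimentMetrics(mk(6))$person$included)
    expect_true(sentimentMetrics(mk(7))$person$included)
    ## metrics conservation: prop * n recovers the negative count per day
    with(m$daily, expect_equal(prop_negative * n_messages, c(2, 1)))
})

test_that("messages outside the observation window do not count", {
    base <- as.POSIXct("2024-01-01 09:00:00", tz = "UTC")
    rec <- data.frame(start = c(base + 1:3, base + 86400 * 200 + 1:3),
                      label = "negative")
    m <- sentimentMetrics(rec)
    expect_equal(m$person$n_valid_days, 1L)
    expect_equal(sum(m$daily$in_window), 1L)
})

test_that("the reconstruction pipeline inverts the keystroke generator", {
    spec <- keystrokeSimSpec(nDays = 10, msgsPerDay = 5, pNegative = 0.3,
                             pPositive = 0.3, seed = 61)
    ks <- simulateKeystrokes(spec)
    tp <- textPipeline(ks$log)
    truth <- ks$truth$messages
    genuine <- truth[!truth$artifact, ]
    expect_equal(tp$messages$text, genuine$text)
    expect_equal(tp$messages$label, genuine$label)
    daily <- ks$truth$daily
    expect_equal(tp$daily$prop_negative, daily$prop_negative)
    expect_equal(tp$daily$prop_positive, daily$prop_positive)
    expect_equal(tp$daily$n_messages, daily$n_messages)
    ## determinism of the generator
    expect_identical(simulateKeystrokes(spec)$log, ks$log)
})

test_that("keystroke logs round-trip through JSONL", {
    ks <- simulateKeystrokes(keystrokeSimSpec(nDays = 2, msgsPerDay = 3,
                                              seed = 62))
    path <- tempfile(fileext = ".jsonl")
    writeKeystrokeJsonl(ks$log, path)
    back <- readKeystrokeJsonl(path)
    expect_equal(back$key, ks$log$key)
    expect_equal(back$app, ks$log$app)
    expect_lt(max(abs(as.numeric(back$t) - as.numeric(ks$log$t))), 0.0011)
    ## reconstruction from the round-tripped log is unchanged
    expect_equal(textPipeline(back)$messages$text,
                 textPipeline(ks$log)$messages$text)
})

test_that("keystroke spec invariants are enforced", {
    expect_error(keystrokeSimSpec(pNegative = 0.7, pPositive = 0.5),
                 "must not exceed 1")
    expect_error(keystrokeSimSpec(pauseGap = 2), "at least 5")
    ## zero-message days are absent from the daily truth table
    ks <- simulateKeystrokes(keystrokeSimSpec(nDays = 40, msgsPerDay = 0.5,
                                              seed = 63))
    days <- as.Date(ks$truth$messages$start[!ks$truth$messages$artifact],
                    tz = "UTC")
    expect_setequal(as.character(ks$truth$daily$date), as.character(unique(days)))
})
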