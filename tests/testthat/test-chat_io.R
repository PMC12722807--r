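test_that("parseChat keeps participant utterances and drops everything else", {
  txt <- chatFixture(c(
    "@Begin", "@Languages:\teng",
    "@Participants:\tPAR Participant, INV Investigator",
    "*PAR:\tthe boy falls .",
    "%mor:\tdet|the n|boy v|fall .",
    "*INV:\ttell me more .",
    "*PAR:\tum I see a boy",
    "@End"))
  expect_identical(parseChat(txt), "the boy falls . um I see a boy")

  # interviewer-only file is an empty transcript
  expect_error(parseChat(chatFixture(c("@Begin", "*INV:\tgo on ."))),
               "empty transcript")
  # no main tier at all is a parse error
  expect_error(parseChat(chatFixture(c("@Begin", "@End"))), "parse error")
})

test_that("continuation lines and alternate speaker codes are handled", {
  txt <- chatFixture(c(
    "*CHI:\tthe cookie jar",
    "\tis falling down .",
    "*INV:\tmhm ."))
  expect_identical(parseChat(txt, speaker = "CHI"),
                   "the cookie jar is falling down .")
})

test_that("cleanUtterance applies each policy rule", {
  expect_identical(cleanUtterance("&uh the <the boy> [//] boy"),
                   "uh the the boy boy")
  expect_identical(cleanUtterance("the cookie (.) jar"), "the cookie . jar")
  expect_identical(cleanUtterance("a (..) b (...) c"), "a . b . c")
  expect_identical(cleanUtterance("plain words only"), "plain words only")
  expect_identical(cleanUtterance("&-um overflowing +..."),
                   "um overflowing .")
  expect_identical(cleanUtterance("he [: she] &=laughs runs"), "he runs")
  expect_warning(out <- cleanUtterance("bad [ bracket"), "unbalanced")
  expect_identical(out, "bad bracket")
  # policy switches
  strict <- cleaningPolicy(keepFillers = FALSE, pauseToPeriod = FALSE)
  expect_identical(cleanUtterance("&uh boy (.) falls", strict), "boy falls")
})

test_that("parsing is idempotent on its own cleaned output", {
  raw <- chatFixture(c("*PAR:\t&uh the <the boy> [//] boy (.) falls .",
                       "*INV:\tok ."))
  once <- parseChat(raw)
  again <- parseChat(paste0("*PAR:\t", once))
  expect_identical(again, once)
})

test_that("no interviewer token survives into the corpus text", {
  txts <- replicate(5, {
    inv <- paste("zzqx", sample(letters, 3), collapse = " ")
    chatFixture(c(paste0("*INV:\t", inv), "*PAR:\tboy on stool .",
                  paste0("*INV:\t", inv)))
  })
  for (t in txts) expect_false(grepl("zzqx", parseChat(t)))
})

test_that("loadCorpus joins files with metadata and validates labels", {
  dir <- tempfile(); dir.create(dir)
  writeLines(chatFixture(c("*PAR:\ta boy .")), file.path(dir, "t1.cha"))
  writeLines(chatFixture(c("*PAR:\ta jar .")), file.path(dir, "t2.cha"))
  md <- data.frame(transcript_id = c("t1", "t2"),
                   participant_id = c("p1", "p2"),
                   label = c("control", "impaired"))
  corp <- loadCorpus(file.path(dir, c("t1.cha", "t2.cha")), md)
  expect_s4_class(corp, "TranscriptCorpus")
  cc <- classCounts(corp)
  expect_equal(unname(cc[["control"]]), 1)
  expect_equal(unname(cc[["impaired"]]), 1)
  expect_equal(corpusRecords(corp)$text, c("a boy .", "a jar ."))

  # file missing from metadata -> error naming the id
  writeLines(chatFixture(c("*PAR:\tx .")), file.path(dir, "t3.cha"))
  expect_error(loadCorpus(file.path(dir, paste0("t", 1:3, ".cha")), md), "t3")
  # bad label -> error
  md$label[1] <- "dementia"
  expect_error(loadCorpus(file.path(dir, c("t1.cha", "t2.cha")), md),
               "control, impaired|not in")
})

test_that("a generated corpus loads with matching bookkeeping", {
  dir <- tinyCorpusDir(n = 6, participants = 4, seed = 7)
  corp <- loadCorpusDir(dir)
  rec <- corpusRecords(corp)
  expect_equal(nrow(rec), 12)
  expect_equal(length(unique(rec$participant_id)), 8)
  expect_true(all(nzchar(rec$text)))
  expect_equal(unname(classCounts(corp)), c(6L, 6L),
               ignore_attr = TRUE)
})
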