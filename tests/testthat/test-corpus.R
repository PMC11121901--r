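test_that("count_tokens counts maximal runs of non-whitespace", {
  expect_equal(count_tokens(""), 0L)
  expect_equal(count_tokens("a  b\tc\nd"), 4L)
  expect_equal(count_tokens(paste(rep("x", 128), collapse = " ")), 128L)
  expect_equal(count_tokens(NA_character_), 0L)
})

test_that("count_tokens agrees with a strsplit oracle on fuzzed strings", {
  alphabet <- c(letters[1:4], " ", "\t", "\n", "  ")
  withr::with_seed(11, {
    strings <- vapply(1:1000, function(i) {
      paste(sample(alphabet, sample.int(30, 1), replace = TRUE),
            collapse = "")
    }, character(1))
  })
  oracle <- vapply(strings, function(s) {
    length(Filter(nzchar, strsplit(s, "[ \t\n\r\f\v]+")[[1]]))
  }, integer(1), USE.NAMES = FALSE)
  expect_equal(count_tokens(strings), oracle)
})

test_that("read_citations yields records in document order with joined abstracts", {
  fx <- fixture_suite()
  raw <- read_citations(fx$cite_fix$citation_path)
  n_expected <- 3 * fx$spec$n_citations_per_class + 5  # + rejection records
  expect_equal(nrow(raw), n_expected)
  expect_equal(raw$pmid[1], fx$cite_fix$golden_labels$pmid[1])
  expect_true(all(lengths(raw$mesh_headings[1:3]) > 0))
})

test_that("multi-part abstracts concatenate with single spaces", {
  path <- tempfile(fileext = ".xml")
  writeLines(c(
    "<PubmedArticleSet><PubmedArticle><MedlineCitation>",
    "<PMID>1</PMID><Article>",
    "<Journal><JournalIssue><PubDate><Year>2020</Year></PubDate></JournalIssue></Journal>",
    "<ArticleTitle>t</ArticleTitle>",
    '<Abstract><AbstractText Label="BACKGROUND">part one</AbstractText>',
    '<AbstractText Label="METHODS">part two</AbstractText></Abstract>',
    "<PublicationTypeList><PublicationType>Journal Article</PublicationType></PublicationTypeList>",
    "</Article>",
    '<MeshHeadingList><MeshHeading><DescriptorName UI="D1">x</DescriptorName></MeshHeading></MeshHeadingList>',
    "</MedlineCitation></PubmedArticle></PubmedArticleSet>"), path)
  raw <- read_citations(path)
  expect_equal(raw$abstract, "part one part two")
  expect_equal(raw$mesh_headings[[1]], "D1")
})

test_that("malformed citation XML errors with the offending file named", {
  bad <- tempfile(fileext = ".xml")
  writeLines("<PubmedArticleSet><oops", bad)
  expect_error(read_citations(bad), "malformed citation XML")
})

make_raw_record <- function(pmid = "1", pub_types = "Journal Article",
                            year = 2020L, title = "t",
                            abstract = paste(rep("w", 129), collapse = " "),
                            headings = "D1") {
  tibble::tibble(pmid = pmid, pub_types = list(pub_types), year = year,
                 month = "Jan", day = "", title = title,
                 abstract = abstract, mesh_headings = list(headings))
}

test_that("validation accepts complete records and rejects with the first failed reason", {
  ok <- make_raw_record()
  short <- make_raw_record(pmid = "2",
                           abstract = paste(rep("w", 126), collapse = " "))
  dup <- make_raw_record(pmid = "1")
  nomesh <- make_raw_record(pmid = "3", headings = character())
  editorial <- make_raw_record(pmid = "4", pub_types = "Editorial",
                               headings = character())
  raw <- dplyr::bind_rows(ok, short, dup, nomesh, editorial)
  acc <- filter_citations(raw)
  rej <- citation_rejections(acc)
  expect_equal(acc$pmid, "1")
  expect_equal(count_tokens(acc$text), 130L)  # title + 129-token abstract
  expect_equal(rej$reason[rej$pmid == "2"], "min_tokens")
  expect_equal(rej$reason[rej$pmid == "1"], "duplicate_id")
  expect_equal(rej$reason[rej$pmid == "3"], "no_mesh")
  # first failed reason in check order, not a later one
  expect_equal(rej$reason[rej$pmid == "4"], "not_journal_article")
})

test_that("a joined text of exactly 127 tokens is rejected, 128 accepted", {
  r127 <- make_raw_record(pmid = "a",
                          abstract = paste(rep("w", 126), collapse = " "))
  r128 <- make_raw_record(pmid = "b",
                          abstract = paste(rep("w", 127), collapse = " "))
  acc <- filter_citations(dplyr::bind_rows(r127, r128))
  expect_equal(acc$pmid, "b")
  expect_equal(citation_rejections(acc)$reason, "min_tokens")
})

test_that("duplicate handling is first-accepted-wins across the whole pass", {
  raw <- dplyr::bind_rows(
    make_raw_record(pmid = "9", title = "first"),
    make_raw_record(pmid = "8"),
    make_raw_record(pmid = "9", title = "second"))
  acc <- filter_citations(raw)
  expect_equal(acc$title[acc$pmid == "9"], "first")
  # a rejected first occurrence does not block a later valid one
  raw2 <- dplyr::bind_rows(
    make_raw_record(pmid = "7", headings = character()),
    make_raw_record(pmid = "7"))
  expect_equal(nrow(filter_citations(raw2)), 1)
})

test_that("every accepted record satisfies the record invariants", {
  fx <- fixture_suite()
  acc <- filter_citations(read_citations(fx$cite_fix$citation_path))
  expect_true(all(nzchar(acc$pmid)))
  expect_false(any(duplicated(acc$pmid)))
  expect_true(all(!is.na(acc$year)))
  expect_true(all(nzchar(acc$title) & nzchar(acc$abstract)))
  expect_true(all(lengths(acc$mesh_headings) > 0))
  expect_true(all(acc$n_tokens >= 128))
  expect_equal(acc$text, paste(acc$title, acc$abstract))
})
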