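test_that("the rule cascade fires in fixed order: rare, disease tree, other", {
  fx <- fixture_suite()
  cfg <- labeling_config(fx$term_set)
  rare_ui <- setdiff(fx$term_set$mesh_id, "D035583")[1]
  nonrare_ui <- fx$mesh_fix$roles$nonrare[1]
  f03_ui <- "D900003"   # tree F03.625
  b_ui <- "D900004"     # tree B01

  # rare-set member forces RARE even among many disease headings
  expect_equal(
    as.character(assign_label(c(rare_ui, fx$mesh_fix$roles$nonrare[1:5]),
                              cfg, fx$vocab)), "RARE")
  expect_equal(as.character(assign_label(f03_ui, cfg, fx$vocab)), "NON_RARE")
  expect_equal(as.character(assign_label(nonrare_ui, cfg, fx$vocab)),
               "NON_RARE")
  expect_equal(as.character(assign_label(b_ui, cfg, fx$vocab)), "OTHER")
  expect_equal(as.character(assign_label(character(), cfg, fx$vocab)),
               "OTHER")
  # unknown UIs fail the tree test silently
  expect_equal(as.character(assign_label("D999111", cfg, fx$vocab)), "OTHER")
})

test_that("labeling_config validates its invariants", {
  expect_error(labeling_config(c("D000001")), "D035583")
  expect_error(labeling_config("D035583", disease_tree_prefixes = character()),
               "prefixes")
})

test_that("supplementary headings satisfy the rare rule but not the tree rule", {
  fx <- fixture_suite()
  cfg <- labeling_config(fx$term_set)
  # C800001 is in the rare set (direct xref from a rare leaf)
  expect_equal(as.character(assign_label("C800001", cfg, fx$vocab)), "RARE")
  # C800002 is not in the set and has no tree numbers -> OTHER by default
  expect_equal(as.character(assign_label("C800002", cfg, fx$vocab)), "OTHER")
  # with the mapping option on, C800002 maps to a Diseases-tree descriptor
  cfg_mapped <- labeling_config(fx$term_set, map_supplementary = TRUE)
  expect_equal(as.character(assign_label("C800002", cfg_mapped, fx$vocab)),
               "NON_RARE")
})

test_that("assign_label agrees with the brute-force oracle on fuzzed sets", {
  fx <- fixture_suite()
  cfg <- labeling_config(fx$term_set)
  pool <- c(fx$term_set$mesh_id, fx$vocab$descriptors$ui,
            fx$vocab$supplementary$ui, "D999111")
  withr::with_seed(23, {
    for (i in 1:500) {
      h <- random_heading_set(pool)
      expect_equal(as.character(assign_label(h, cfg, fx$vocab)),
                   oracle_label(h, cfg$rare_ids, fx$vocab))
    }
  })
})

test_that("labels are monotone under rare-set growth", {
  fx <- fixture_suite()
  cfg_small <- labeling_config(fx$term_set)
  grown <- c(fx$term_set$mesh_id, fx$mesh_fix$roles$nonrare[1])
  cfg_big <- labeling_config(grown)
  pool <- c(fx$vocab$descriptors$ui, fx$vocab$supplementary$ui)
  rank <- c(RARE = 1, NON_RARE = 2, OTHER = 3)
  withr::with_seed(29, {
    for (i in 1:200) {
      h <- random_heading_set(pool)
      l1 <- as.character(assign_label(h, cfg_small, fx$vocab))
      l2 <- as.character(assign_label(h, cfg_big, fx$vocab))
      expect_lte(rank[[l2]], rank[[l1]])
    }
  })
})

test_that("news articles are labeled by the same cascade, no token filter", {
  fx <- fixture_suite()
  cfg <- labeling_config(fx$term_set)
  news <- read_news_articles(fx$news_fix$news_path)
  expect_equal(nrow(news), 3 * fx$spec$n_news_per_class)
  labeled <- label_news_articles(news, cfg, fx$vocab)
  joined <- dplyr::inner_join(labeled, fx$news_fix$golden_labels, by = "id")
  expect_equal(as.character(joined$label.x), joined$label.y)
  # short texts survive: news has no 128-token floor
  expect_true(any(count_tokens(labeled$text) < 128))
})

test_that("news without headings labels OTHER with a notice", {
  fx <- fixture_suite()
  cfg <- labeling_config(fx$term_set)
  path <- tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"id":"n1","text":"local sports roundup","mesh_headings":[]}'), path)
  news <- read_news_articles(path)
  expect_message(out <- label_news_articles(news, cfg, fx$vocab), "OTHER")
  expect_equal(as.character(out$label), "OTHER")
})

test_that("citation labeling matches the fixture's golden labels", {
  fx <- fixture_suite()
  cfg <- labeling_config(fx$term_set)
  acc <- filter_citations(read_citations(fx$cite_fix$citation_path))
  labeled <- label_documents(acc, cfg, fx$vocab)
  joined <- dplyr::inner_join(
    dplyr::select(labeled, "pmid", "label"),
    fx$cite_fix$golden_labels, by = "pmid")
  expect_equal(nrow(joined), nrow(fx$cite_fix$golden_labels))
  expect_equal(as.character(joined$label.x), joined$label.y)
})
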