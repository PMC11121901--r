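#' Specification for the synthetic fixture suite
#'
#' The fixture generators emulate every external input of the pipeline at
#' miniature scale — a mini-MeSH with a Diseases (C) subtree, a Mental
#' Disorders (F03) subtree, a non-disease (B) subtree and the rare-diseases
#' attribute descriptor; a Mondo-style ontology whose rare leaves
#' cross-reference that mini-MeSH directly or through GARD; and citation /
#' news corpora whose per-class vocabularies are pairwise disjoint, which
#' makes the classes linearly separable by construction. Every generator is
#' byte-deterministic under `seed` and emits its intended ground truth as a
#' golden file, so pipeline tests are self-verifying.
#'
#' @param seed Master seed; all generators derive their randomness from it.
#' @param n_mesh_descriptors Exact number of descriptor records in the
#'   mini-MeSH (at least the structural minimum, which depends on
#'   `n_rare_leaves`).
#' @param n_rare_leaves Rare ontology leaves, split across direct-MeSH,
#'   via-GARD and unresolvable-GARD routes.
#' @param n_gard_links Rows in the GARD-to-MeSH mapping table.
#' @param n_citations_per_class Accepted-by-construction citations per
#'   class.
#' @param n_news_per_class News articles per class.
#' @param token_count_range Inclusive range of whitespace-token counts for
#'   generated citation texts (all above the 128-token filter).
#' @param vocab_per_class Named list of pairwise-disjoint word vectors, one
#'   per class.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L,
                         n_mesh_descriptors = 30L,
                         n_rare_leaves = 10L,
                         n_gard_links = 4L,
                         n_citations_per_class = 12L,
                         n_news_per_class = 5L,
                         token_count_range = c(132L, 168L),
                         vocab_per_class = NULL) {
  if (is.null(vocab_per_class)) {
    vocab_per_class <- list(
      RARE = sprintf("orphavar%02d", 1:40),
      NON_RARE = sprintf("clinterm%02d", 1:40),
      OTHER = sprintf("miscword%02d", 1:40)
    )
  }
  pairs <- utils::combn(names(vocab_per_class), 2, simplify = FALSE)
  for (pr in pairs) {
    if (length(intersect(vocab_per_class[[pr[1]]],
                         vocab_per_class[[pr[2]]])) > 0) {
      abort("class vocabularies must be pairwise disjoint")
    }
  }
  if (n_rare_leaves < 4) abort("n_rare_leaves must be at least 4")
  structure(list(seed = as.integer(seed),
                 n_mesh_descriptors = as.integer(n_mesh_descriptors),
                 n_rare_leaves = as.integer(n_rare_leaves),
                 n_gard_links = as.integer(n_gard_links),
                 n_citations_per_class = as.integer(n_citations_per_class),
                 n_news_per_class = as.integer(n_news_per_class),
                 token_count_range = as.integer(token_count_range),
                 vocab_per_class = vocab_per_class),
            class = "fixture_spec")
}

# split the rare leaves into extraction routes:
# ~60% direct xref, 2 unresolvable GARD, rest resolvable GARD
fixture_routes <- function(spec) {
  n <- spec$n_rare_leaves
  n_unres <- 2L
  n_direct <- max(1L, ceiling((n - n_unres) * 0.6))
  n_gard <- n - n_direct - n_unres
  list(n_direct = n_direct, n_gard = max(1L, n_gard),
       n_unresolvable = n - n_direct - max(1L, n_gard))
}

#' Generate the mini-MeSH fixture
#'
#' Writes descriptor and supplementary-concept XML in the standard NLM
#' dialects. The vocabulary contains: the rare-diseases attribute
#' descriptor `D035583`; a Diseases subtree under `C06` holding the rare
#' ontology targets (the first two of which have tree descendants, to
#' exercise expansion) and non-rare disease fillers; an `F03` Mental
#' Disorders subtree; a non-disease `B01` subtree; one descriptor without
#' tree numbers; and two supplementary concepts, the first of which serves
#' as a rare-disease target with no tree numbers.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return List with `descriptor_path`, `supplementary_path`, the
#'   `descriptors` / `supplementary` tibbles, and `roles`: the UI sets the
#'   other generators build on (`rare_direct`, `rare_gard`, `rare_supp`,
#'   `tree_children`, `nonrare`, `other`, `no_tree`).
#' @export
make_mesh_fixture <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  routes <- fixture_routes(spec)
  n_targets <- routes$n_direct + routes$n_gard + routes$n_unresolvable

  rows <- list(
    tibble(ui = "D900008", name = "Pathological Conditions",
           tn = list("C23")),
    tibble(ui = "D035583", name = "Rare Diseases", tn = list("C23.550")),
    tibble(ui = "D900001", name = "Digestive System Diseases",
           tn = list("C06")),
    tibble(ui = "D900002", name = "Mental Disorders", tn = list("F03")),
    tibble(ui = "D900003", name = "Anxiety Disorders", tn = list("F03.625")),
    tibble(ui = "D900004", name = "Bacteria", tn = list("B01")),
    tibble(ui = "D900005", name = "Proteobacteria", tn = list("B01.050")),
    tibble(ui = "D900006", name = "Enterobacteriaceae",
           tn = list("B01.050.150")),
    tibble(ui = "D900007", name = "Unrooted Concept", tn = list(character()))
  )
  # rare targets at C06.1xx; first two get descendants
  targets <- purrr::map(seq_len(n_targets), function(i) {
    tibble(ui = sprintf("D%06d", 100000L + i),
           name = sprintf("Fixture Rare Disease %d", i),
           tn = list(sprintf("C06.%03d", 100L + i)))
  })
  children <- list(
    tibble(ui = "D150001", name = "Fixture Rare Subtype 1a",
           tn = list("C06.101.100")),
    tibble(ui = "D150002", name = "Fixture Rare Subtype 1a-i",
           tn = list("C06.101.100.050")),
    tibble(ui = "D150003", name = "Fixture Rare Subtype 2a",
           tn = list("C06.102.100"))
  )
  # non-rare disease fillers at C06.9xx plus one in F03
  skeleton_n <- length(rows) + n_targets + length(children)
  n_filler <- spec$n_mesh_descriptors - skeleton_n
  if (n_filler < 3) {
    abort(sprintf("n_mesh_descriptors must be at least %d for this spec",
                  skeleton_n + 3L))
  }
  n_nonrare <- ceiling(n_filler * 2 / 3)
  fillers <- purrr::map(seq_len(n_filler), function(i) {
    if (i <= n_nonrare) {
      tibble(ui = sprintf("D%06d", 160000L + i),
             name = sprintf("Fixture Common Disease %d", i),
             tn = list(sprintf("C06.%03d", 900L + i)))
    } else {
      tibble(ui = sprintf("D%06d", 170000L + i),
             name = sprintf("Fixture Organism %d", i),
             tn = list(sprintf("B01.%03d", 900L + i)))
    }
  })

  descriptors <- dplyr::bind_rows(c(rows, targets, children, fillers)) |>
    rename(tree_numbers = "tn")

  supplementary <- tibble(
    ui = c("C800001", "C800002"),
    name = c("Kleefstra-like Fixture Syndrome", "Fixture Substance"),
    mapped_to = list("D900003", descriptors$ui[descriptors$name ==
                                                 "Fixture Common Disease 1"])
  )

  descriptor_path <- file.path(dir, "mesh_descriptors.xml")
  supplementary_path <- file.path(dir, "mesh_supplementary.xml")

  desc_xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    "<DescriptorRecordSet>",
    unlist(purrr::pmap(descriptors, function(ui, name, tree_numbers) {
      tn_block <- if (length(tree_numbers) == 0) character() else c(
        "    <TreeNumberList>",
        sprintf("      <TreeNumber>%s</TreeNumber>", tree_numbers),
        "    </TreeNumberList>")
      c("  <DescriptorRecord>",
        sprintf("    <DescriptorUI>%s</DescriptorUI>", ui),
        sprintf("    <DescriptorName><String>%s</String></DescriptorName>",
                name),
        tn_block,
        "  </DescriptorRecord>")
    })),
    "</DescriptorRecordSet>")
  writeLines(desc_xml, descriptor_path)

  supp_xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    "<SupplementalRecordSet>",
    unlist(purrr::pmap(supplementary, function(ui, name, mapped_to) {
      c("  <SupplementalRecord>",
        sprintf("    <SupplementalRecordUI>%s</SupplementalRecordUI>", ui),
        sprintf(
          "    <SupplementalRecordName><String>%s</String></SupplementalRecordName>",
          name),
        "    <HeadingMappedToList>",
        unlist(purrr::map(mapped_to, function(m) c(
          "      <HeadingMappedTo>",
          sprintf(
            "        <DescriptorReferredTo><DescriptorUI>*%s</DescriptorUI></DescriptorReferredTo>",
            m),
          "      </HeadingMappedTo>"))),
        "    </HeadingMappedToList>",
        "  </SupplementalRecord>")
    })),
    "</SupplementalRecordSet>")
  writeLines(supp_xml, supplementary_path)

  target_uis <- purrr::map_chr(targets, "ui")
  roles <- list(
    rare_direct = target_uis[seq_len(routes$n_direct)],
    rare_gard = target_uis[routes$n_direct + seq_len(routes$n_gard)],
    rare_unresolvable_slots = routes$n_unresolvable,
    rare_supp = "C800001",
    tree_children = purrr::map_chr(children, "ui"),
    nonrare = c(descriptors$ui[startsWith(descriptors$name,
                                          "Fixture Common Disease")],
                "D900002", "D900003"),
    other = c("D900004", "D900005", "D900006",
              descriptors$ui[startsWith(descriptors$name,
                                        "Fixture Organism")]),
    no_tree = "D900007"
  )
  list(descriptor_path = descriptor_path,
       supplementary_path = supplementary_path,
       descriptors = descriptors, supplementary = supplementary,
       roles = roles)
}

#' Generate the ontology + GARD fixture with golden extraction answers
#'
#' Emits an OBO-graph JSON ontology whose rare leaves reference the
#' mini-MeSH: some directly (`MESH:` xrefs, including one supplementary
#' concept), some only through `GARD:` xrefs resolvable in the emitted
#' mapping TSV, and some through GARD ids deliberately absent from it.
#' Negative controls — a rare *non-leaf* with a direct MeSH xref and a
#' non-rare leaf with a MeSH xref — are included. The intended extraction
#' answer and the fully expanded term set (computed here by a brute-force
#' pairwise tree-number scan, independent of the package's expansion code)
#' are written as golden TSVs.
#'
#' @param spec A [fixture_spec()].
#' @param mesh_fixture Result of [make_mesh_fixture()].
#' @param dir Output directory.
#' @return List with `ontology_path`, `gard_path`, `golden_terms`
#'   (extraction answer tibble), `golden_term_set` (post-expansion tibble)
#'   and the corresponding `golden_terms_path` / `golden_term_set_path`.
#' @export
make_ontology_fixture <- function(spec, mesh_fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  roles <- mesh_fixture$roles

  node_id <- function(i) sprintf("MONDO:%07d", i)
  nodes <- list(list(id = node_id(1), lbl = "disease",
                     meta = list(subsets = list())))
  edges <- list()
  golden <- list()
  nxt <- 2L

  add_node <- function(lbl, rare, xrefs, parent = node_id(1)) {
    id <- node_id(nxt)
    nxt <<- nxt + 1L
    meta <- list(
      subsets = if (rare)
        list("http://purl.obolibrary.org/obo/mondo#rare") else list(),
      xrefs = purrr::map(xrefs, function(x) list(val = x))
    )
    nodes[[length(nodes) + 1L]] <<- list(id = id, lbl = lbl, meta = meta)
    if (!is.null(parent)) {
      edges[[length(edges) + 1L]] <<- list(sub = id, pred = "is_a",
                                           obj = parent)
    }
    id
  }

  for (i in seq_along(roles$rare_direct)) {
    id <- add_node(sprintf("fixture rare disease %d (direct)", i), TRUE,
                   paste0("MESH:", roles$rare_direct[i]))
    golden[[length(golden) + 1L]] <- tibble(
      mesh_id = roles$rare_direct[i], source = "direct_xref",
      origin_node = id)
  }
  # one rare leaf references the supplementary concept directly
  id <- add_node("fixture rare syndrome (supplementary)", TRUE,
                 paste0("MESH:", roles$rare_supp))
  golden[[length(golden) + 1L]] <- tibble(
    mesh_id = roles$rare_supp, source = "direct_xref", origin_node = id)

  gard_rows <- list()
  for (i in seq_along(roles$rare_gard)) {
    gid <- sprintf("%04d", 5000L + i)
    id <- add_node(sprintf("fixture rare disease %d (gard)", i), TRUE,
                   paste0("GARD:", gid))
    gard_rows[[length(gard_rows) + 1L]] <- tibble(
      gard_id = gid, mesh_id = roles$rare_gard[i])
    golden[[length(golden) + 1L]] <- tibble(
      mesh_id = roles$rare_gard[i], source = "via_gard", origin_node = id)
  }
  # unresolvable GARD routes: leaves whose GARD ids are absent from the TSV
  for (i in seq_len(roles$rare_unresolvable_slots)) {
    add_node(sprintf("fixture rare disease %d (unresolvable)", i), TRUE,
             sprintf("GARD:%04d", 8000L + i))
  }
  # negative controls
  parent_id <- add_node("fixture rare NON-leaf", TRUE, "MESH:D900001")
  add_node("child of the rare non-leaf", FALSE, character(),
           parent = parent_id)
  add_node("fixture NON-rare leaf", FALSE,
           paste0("MESH:", roles$nonrare[1]))

  # pad the GARD table with extra links not referenced by any node
  extra <- spec$n_gard_links - length(gard_rows)
  if (extra > 0) {
    for (i in seq_len(extra)) {
      gard_rows[[length(gard_rows) + 1L]] <- tibble(
        gard_id = sprintf("%04d", 9000L + i),
        mesh_id = roles$nonrare[1 + (i %% length(roles$nonrare))])
    }
  }

  ontology_path <- file.path(dir, "ontology.json")
  doc <- list(graphs = list(list(nodes = nodes, edges = edges)))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE),
             ontology_path)

  gard_path <- file.path(dir, "gard.tsv")
  gard <- dplyr::bind_rows(gard_rows)
  readr::write_tsv(gard, gard_path, progress = FALSE)

  golden_terms <- dplyr::bind_rows(golden) |> arrange(.data$mesh_id)
  golden_terms_path <- file.path(dir, "golden_terms.tsv")
  readr::write_tsv(golden_terms, golden_terms_path, progress = FALSE)

  # brute-force expansion oracle: pairwise scan over all descriptor tree
  # numbers, independent of the package's lexical-index implementation
  desc <- mesh_fixture$descriptors
  seed_tns <- unlist(desc$tree_numbers[desc$ui %in% golden_terms$mesh_id])
  descendants <- character()
  for (j in seq_len(nrow(desc))) {
    for (tn in desc$tree_numbers[[j]]) {
      for (st in seed_tns) {
        if (nchar(tn) > nchar(st) &&
            substr(tn, 1, nchar(st) + 1) == paste0(st, ".")) {
          descendants <- c(descendants, desc$ui[j])
        }
      }
    }
  }
  descendants <- setdiff(unique(descendants), golden_terms$mesh_id)
  golden_term_set <- dplyr::bind_rows(
    golden_terms,
    tibble(mesh_id = descendants, source = "tree_child",
           origin_node = NA_character_),
    tibble(mesh_id = "D035583", source = "seed_attribute_term",
           origin_node = NA_character_)
  ) |>
    distinct(.data$mesh_id, .keep_all = TRUE) |>
    arrange(.data$mesh_id)
  golden_term_set_path <- file.path(dir, "golden_term_set.tsv")
  readr::write_tsv(golden_term_set, golden_term_set_path, progress = FALSE)

  list(ontology_path = ontology_path, gard_path = gard_path,
       golden_terms = golden_terms, golden_terms_path = golden_terms_path,
       golden_term_set = golden_term_set,
       golden_term_set_path = golden_term_set_path)
}

# deterministic pseudo-text of exactly n_tokens tokens from a word bank
fixture_text <- function(bank, n_tokens) {
  paste(bank[sample.int(length(bank), n_tokens, replace = TRUE)],
        collapse = " ")
}

# heading sets per intended class, drawing from fixture roles / term set
fixture_headings <- function(class, term_set_ids, roles) {
  switch(class,
    RARE = unique(c(
      sample(term_set_ids, 1L),
      if (stats::runif(1) < 0.3) roles$rare_supp,
      sample(roles$nonrare, sample.int(2L, 1L)))),
    NON_RARE = sample(roles$nonrare, 1L + sample.int(2L, 1L)),
    OTHER = sample(roles$other, 1L + sample.int(2L, 1L))
  )
}

#' Generate the citation-corpus fixture with golden labels
#'
#' Emits PubMed-style citation XML: `n_citations_per_class` records per
#' class that pass every quality filter (RARE records carry at least one
#' term-set heading, NON_RARE records disease-tree headings only, OTHER
#' records non-disease headings; texts use the class's private vocabulary
#' and token counts inside `token_count_range`), plus records built to be
#' rejected — one under the 128-token floor, one duplicated PMID, one
#' missing its abstract, one non-journal publication type, and one without
#' MeSH headings. Golden per-record labels and the expected rejection log
#' are written as TSVs.
#'
#' @param spec A [fixture_spec()].
#' @param term_set A `rare_term_set` built from the ontology fixture.
#' @param mesh_fixture Result of [make_mesh_fixture()].
#' @param dir Output directory.
#' @return List with `citation_path`, `golden_labels` (tibble `pmid`,
#'   `label`), `golden_rejections` (tibble `pmid`, `reason`) and their
#'   paths.
#' @export
make_citation_fixture <- function(spec, term_set, mesh_fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  roles <- mesh_fixture$roles
  # only term-set members usable as citation headings: sample away D035583
  # sometimes too, it is a legitimate rare heading
  ts_ids <- term_set$mesh_id

  withr::with_seed(spec$seed + 1000L, {
    records <- list()
    golden <- list()
    pmid_n <- 10000L
    for (class in class_levels()) {
      for (i in seq_len(spec$n_citations_per_class)) {
        pmid_n <- pmid_n + 1L
        n_tok <- sample(seq(spec$token_count_range[1],
                            spec$token_count_range[2]), 1L)
        bank <- spec$vocab_per_class[[class]]
        title <- fixture_text(bank, 8L)
        abstract <- fixture_text(bank, n_tok - 8L)
        records[[length(records) + 1L]] <- list(
          pmid = as.character(pmid_n), pub_types = "Journal Article",
          year = sample(2015:2023, 1L), title = title, abstract = abstract,
          headings = fixture_headings(class, ts_ids, roles))
        golden[[length(golden) + 1L]] <- tibble(
          pmid = as.character(pmid_n), label = class)
      }
    }
    # rejection exercisers
    bank <- spec$vocab_per_class$OTHER
    rejects <- list(
      list(pmid = "20001", pub_types = "Journal Article", year = 2020L,
           title = fixture_text(bank, 8L),
           abstract = fixture_text(bank, 119L),  # 127 tokens joined
           headings = sample(roles$other, 2L), reason = "min_tokens"),
      list(pmid = golden[[1]]$pmid, pub_types = "Journal Article",
           year = 2021L, title = fixture_text(bank, 8L),
           abstract = fixture_text(bank, 150L),
           headings = sample(roles$other, 2L), reason = "duplicate_id"),
      list(pmid = "20003", pub_types = "Journal Article", year = 2020L,
           title = fixture_text(bank, 8L), abstract = "",
           headings = sample(roles$other, 2L), reason = "no_abstract"),
      list(pmid = "20004", pub_types = "Editorial", year = 2020L,
           title = fixture_text(bank, 8L),
           abstract = fixture_text(bank, 150L),
           headings = sample(roles$other, 2L),
           reason = "not_journal_article"),
      list(pmid = "20005", pub_types = "Journal Article", year = 2020L,
           title = fixture_text(bank, 8L),
           abstract = fixture_text(bank, 150L),
           headings = character(), reason = "no_mesh")
    )
    records <- c(records, purrr::map(rejects, function(r) r[names(r) != "reason"]))

    lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
               "<PubmedArticleSet>")
    for (r in records) {
      descr <- r$headings[startsWith(r$headings, "D")]
      supp <- r$headings[startsWith(r$headings, "C") &
                           grepl("^C\\d", r$headings)]
      lines <- c(lines,
        "  <PubmedArticle>",
        "    <MedlineCitation>",
        sprintf("      <PMID>%s</PMID>", r$pmid),
        "      <Article>",
        "        <Journal><JournalIssue><PubDate>",
        sprintf("          <Year>%d</Year><Month>Jan</Month>", r$year),
        "        </PubDate></JournalIssue></Journal>",
        sprintf("        <ArticleTitle>%s</ArticleTitle>", r$title),
        if (nzchar(r$abstract)) c(
          "        <Abstract>",
          sprintf('          <AbstractText Label="BACKGROUND">%s</AbstractText>',
                  r$abstract),
          "        </Abstract>") else character(),
        "        <PublicationTypeList>",
        sprintf("          <PublicationType>%s</PublicationType>",
                r$pub_types),
        "        </PublicationTypeList>",
        "      </Article>",
        if (length(descr) > 0) c(
          "      <MeshHeadingList>",
          sprintf('        <MeshHeading><DescriptorName UI="%s">x</DescriptorName></MeshHeading>',
                  descr),
          "      </MeshHeadingList>") else character(),
        if (length(supp) > 0) c(
          "      <ChemicalList>",
          sprintf('        <Chemical><NameOfSubstance UI="%s">x</NameOfSubstance></Chemical>',
                  supp),
          "      </ChemicalList>") else character(),
        "    </MedlineCitation>",
        "  </PubmedArticle>")
    }
    lines <- c(lines, "</PubmedArticleSet>")

    citation_path <- file.path(dir, "citations.xml")
    writeLines(lines, citation_path)

    golden_labels <- dplyr::bind_rows(golden)
    golden_labels_path <- file.path(dir, "golden_labels.tsv")
    readr::write_tsv(golden_labels, golden_labels_path, progress = FALSE)
    golden_rejections <- dplyr::bind_rows(purrr::map(rejects, function(r) {
      tibble(pmid = r$pmid, reason = r$reason)
    }))
    golden_rejections_path <- file.path(dir, "golden_rejections.tsv")
    readr::write_tsv(golden_rejections, golden_rejections_path,
                     progress = FALSE)

    list(citation_path = citation_path, golden_labels = golden_labels,
         golden_labels_path = golden_labels_path,
         golden_rejections = golden_rejections,
         golden_rejections_path = golden_rejections_path)
  })
}

#' Generate the news-article fixture with golden labels
#'
#' Emits expert-annotated-style news articles as JSONL (`id`, `text`,
#' `mesh_headings`). Texts reuse the per-class disjoint vocabularies but
#' are shorter than citations — news has no token floor.
#'
#' @param spec A [fixture_spec()].
#' @param term_set A `rare_term_set`.
#' @param mesh_fixture Result of [make_mesh_fixture()].
#' @param dir Output directory.
#' @return List with `news_path`, `golden_labels` tibble (`id`, `label`)
#'   and `golden_labels_path`.
#' @export
make_news_fixture <- function(spec, term_set, mesh_fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  roles <- mesh_fixture$roles
  withr::with_seed(spec$seed + 2000L, {
    rows <- list()
    golden <- list()
    k <- 0L
    for (class in class_levels()) {
      for (i in seq_len(spec$n_news_per_class)) {
        k <- k + 1L
        id <- sprintf("news-%03d", k)
        rows[[k]] <- jsonlite::toJSON(list(
          id = id,
          text = fixture_text(spec$vocab_per_class[[class]],
                              sample(30:80, 1L)),
          mesh_headings = as.list(fixture_headings(class, term_set$mesh_id,
                                                   roles))
        ), auto_unbox = TRUE)
        golden[[k]] <- tibble(id = id, label = class)
      }
    }
    news_path <- file.path(dir, "news.jsonl")
    writeLines(unlist(rows), news_path)
    golden_labels <- dplyr::bind_rows(golden)
    golden_labels_path <- file.path(dir, "golden_news_labels.tsv")
    readr::write_tsv(golden_labels, golden_labels_path, progress = FALSE)
    list(news_path = news_path, golden_labels = golden_labels,
         golden_labels_path = golden_labels_path)
  })
}

#' Generate a labeled, separable training corpus directly
#'
#' Convenience generator for model-training tests: labeled examples whose
#' texts are drawn from the pairwise-disjoint class vocabularies, making
#' the three classes separable by construction, without going through XML.
#'
#' @param spec A [fixture_spec()].
#' @param n_per_class Examples per class.
#' @param n_tokens_range Token-count range of each text.
#' @return Tibble `id`, `text`, `label`.
#' @export
make_labeled_corpus <- function(spec, n_per_class = 100L,
                                n_tokens_range = c(20L, 60L)) {
  withr::with_seed(spec$seed + 3000L, {
    rows <- purrr::map(class_levels(), function(class) {
      texts <- purrr::map_chr(seq_len(n_per_class), function(i) {
        fixture_text(spec$vocab_per_class[[class]],
                     sample(seq(n_tokens_range[1], n_tokens_range[2]), 1L))
      })
      tibble(id = sprintf("%s-%04d", tolower(class), seq_len(n_per_class)),
             text = texts,
             label = factor(class, levels = class_levels()))
    })
    dplyr::bind_rows(rows)
  })
}
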