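# Shared fixture suite, built once per test run in a temp directory.
.fixture_cache <- new.env(parent = emptyenv())

fixture_suite <- function(seed = 101L) {
  key <- paste0("s", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  dir <- file.path(tempdir(), paste0("raremesh-fixtures-", seed))
  spec <- fixture_spec(seed = seed)
  mesh_fix <- make_mesh_fixture(spec, file.path(dir, "mesh"))
  onto_fix <- make_ontology_fixture(spec, mesh_fix, file.path(dir, "onto"))
  vocab <- parse_mesh(mesh_fix$descriptor_path, mesh_fix$supplementary_path)
  graph <- parse_ontology(onto_fix$ontology_path)
  gard <- read_gard_mapping(onto_fix$gard_path)
  extracted <- suppressWarnings(extract_rare_mesh_terms(graph, gard))
  term_set <- build_rare_term_set(extracted, vocab)
  cite_fix <- make_citation_fixture(spec, term_set, mesh_fix,
                                    file.path(dir, "cite"))
  news_fix <- make_news_fixture(spec, term_set, mesh_fix,
                                file.path(dir, "news"))
  suite <- list(dir = dir, spec = spec, mesh_fix = mesh_fix,
                onto_fix = onto_fix, vocab = vocab, graph = graph,
                gard = gard, extracted = extracted, term_set = term_set,
                cite_fix = cite_fix, news_fix = news_fix)
  .fixture_cache[[key]] <- suite
  suite
}

# write a tiny OBO-graph JSON from a node/edge description
write_test_ontology <- function(nodes, edges = list(), path = tempfile(fileext = ".json")) {
  doc <- list(graphs = list(list(nodes = nodes, edges = edges)))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), path)
  path
}

onode <- function(id, rare = FALSE, xrefs = character(), lbl = id) {
  list(id = id, lbl = lbl,
       meta = list(
         subsets = if (rare) list("http://x.org/mondo#rare") else list(),
         xrefs = lapply(xrefs, function(x) list(val = x))))
}

oedge <- function(child, parent) list(sub = child, pred = "is_a", obj = parent)

# brute-force extraction oracle: scan every (node, xref) pair
oracle_extract <- function(graph, gard) {
  leaves <- setdiff(graph$nodes$id, graph$edges$parent)
  out <- list()
  for (i in seq_len(nrow(graph$nodes))) {
    n <- graph$nodes[i, ]
    if (!n$is_rare || !(n$id %in% leaves)) next
    xr <- n$xrefs[[1]]
    direct <- sub("^MESH:", "", xr[grepl("^MESH:", xr)])
    if (length(direct) > 0) {
      for (m in direct) {
        out[[length(out) + 1]] <- data.frame(mesh_id = m,
                                             source = "direct_xref",
                                             origin_node = n$id)
      }
      next
    }
    gids <- sub("^GARD:", "", xr[grepl("^GARD:", xr)])
    for (g in gids) {
      for (m in gard$mesh_id[gard$gard_id == g]) {
        out[[length(out) + 1]] <- data.frame(mesh_id = m,
                                             source = "via_gard",
                                             origin_node = n$id)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(mesh_id = character(), source = character(),
                      origin_node = character()))
  }
  res <- do.call(rbind, out)
  res$.rank <- ifelse(res$source == "direct_xref", 0, 1)
  res <- res[order(res$mesh_id, res$.rank, res$origin_node), ]
  res <- res[!duplicated(res$mesh_id), c("mesh_id", "source", "origin_node")]
  rownames(res) <- NULL
  res
}

# brute-force tree expansion oracle: pairwise prefix scan
oracle_expand <- function(seed, vocab) {
  desc <- vocab$descriptors
  seed_tns <- unlist(desc$tree_numbers[desc$ui %in% seed])
  hits <- character()
  for (j in seq_len(nrow(desc))) {
    for (tn in desc$tree_numbers[[j]]) {
      for (st in seed_tns) {
        if (nchar(tn) > nchar(st) &&
            substr(tn, 1, nchar(st) + 1) == paste0(st, ".")) {
          hits <- c(hits, desc$ui[j])
        }
      }
    }
  }
  sort(unique(c(seed, hits)))
}

# brute-force labeling oracle: independent triple scan
oracle_label <- function(headings, rare_ids, vocab, prefixes = c("C", "F03")) {
  headings <- unique(headings)
  for (h in headings) if (h %in% rare_ids) return("RARE")
  for (h in headings) {
    tns <- vocab$tree_index$tree_number[vocab$tree_index$ui == h]
    for (tn in tns) {
      for (p in prefixes) {
        ok <- if (nchar(p) == 1) substr(tn, 1, 1) == p else
          (tn == p || substr(tn, 1, nchar(p) + 1) == paste0(p, "."))
        if (ok) return("NON_RARE")
      }
    }
  }
  "OTHER"
}

# naive per-class metric recount used as the metrics oracle
oracle_class_metrics <- function(truth, pred, cl) {
  tp <- sum(truth == cl & pred == cl)
  fp <- sum(truth != cl & pred == cl)
  fn <- sum(truth == cl & pred != cl)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f)
}

random_heading_set <- function(pool, max_size = 6L) {
  n <- sample.int(max_size + 1L, 1L) - 1L
  if (n == 0) character() else sample(pool, n, replace = TRUE)
}
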