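#' Labeling configuration for the three-class rule cascade
#'
#' @param rare_terms A `rare_term_set` tibble (or character vector of MeSH
#'   UIs); must contain the rare-diseases attribute descriptor `D035583`.
#' @param disease_tree_prefixes Tree-number prefixes defining the non-rare
#'   disease rule: the MeSH Diseases category (`"C"`) and the Mental
#'   Disorders subtree (`"F03"`).
#' @param map_supplementary If `TRUE`, supplementary-concept headings are
#'   replaced by their mapped-to descriptors before the disease-tree test
#'   (they always count for the rare rule by plain set membership). Default
#'   `FALSE`, mirroring the literal rule text.
#' @return A `labeling_config` list.
#' @export
labeling_config <- function(rare_terms,
                            disease_tree_prefixes = c("C", "F03"),
                            map_supplementary = FALSE) {
  ids <- if (is.data.frame(rare_terms)) rare_terms$mesh_id else
    as.character(rare_terms)
  if (!"D035583" %in% ids) {
    abort("rare_terms must contain the rare-diseases attribute term D035583")
  }
  if (length(disease_tree_prefixes) == 0 ||
      any(!nzchar(disease_tree_prefixes))) {
    abort("disease_tree_prefixes must be nonempty strings")
  }
  structure(list(rare_ids = unique(ids),
                 disease_tree_prefixes = disease_tree_prefixes,
                 map_supplementary = isTRUE(map_supplementary)),
            class = "labeling_config")
}

# does any UI in `uis` sit under any configured tree prefix?
any_in_disease_tree <- function(uis, cfg, vocab) {
  if (length(uis) == 0) return(FALSE)
  if (cfg$map_supplementary && nrow(vocab$supplementary) > 0) {
    idx <- match(uis, vocab$supplementary$ui)
    mapped <- unlist(vocab$supplementary$mapped_to[idx[!is.na(idx)]])
    uis <- unique(c(uis, mapped))
  }
  tns <- vocab$tree_index$tree_number[vocab$tree_index$ui %in% uis]
  if (length(tns) == 0) return(FALSE)
  for (p in cfg$disease_tree_prefixes) {
    if (any(tree_matches_prefix(tns, p))) return(TRUE)
  }
  FALSE
}

#' Assign a class label to one set of MeSH headings
#'
#' The fixed rule cascade: `RARE` if any heading belongs to the rare term
#' set; otherwise `NON_RARE` if any heading is a descriptor with a tree
#' number under a configured disease-tree prefix; otherwise `OTHER`. UIs
#' unknown to the vocabulary simply fail the tree test; an empty heading set
#' is `OTHER`.
#'
#' @param headings Character vector of MeSH UIs (possibly empty).
#' @param cfg A [labeling_config()].
#' @param vocab A [parse_mesh()] vocabulary.
#' @return A single label, factor with levels [class_levels()].
#' @export
assign_label <- function(headings, cfg, vocab) {
  headings <- unique(as.character(headings))
  if (any(headings %in% cfg$rare_ids)) return(as_class_factor("RARE"))
  if (any_in_disease_tree(headings, cfg, vocab)) {
    return(as_class_factor("NON_RARE"))
  }
  as_class_factor("OTHER")
}

#' Label a tibble of documents by their MeSH headings
#'
#' Applies [assign_label()] to each row's `mesh_headings` set.
#'
#' @param docs Tibble with a `mesh_headings` list-column (e.g. from
#'   [filter_citations()] or [read_news_articles()]).
#' @param cfg A [labeling_config()].
#' @param vocab A [parse_mesh()] vocabulary.
#' @return `docs` with a `label` factor column appended.
#' @export
label_documents <- function(docs, cfg, vocab) {
  labels <- purrr::map_chr(docs$mesh_headings, function(h) {
    as.character(assign_label(h, cfg, vocab))
  })
  docs |> mutate(label = factor(labels, levels = class_levels()))
}

#' Read expert-annotated news articles from JSONL
#'
#' One JSON object per line with fields `id`, `text` and `mesh_headings`
#' (array of MeSH UIs).
#'
#' @param path Path to a JSONL file.
#' @return Tibble: `id`, `text`, `mesh_headings` (list-column).
#' @export
read_news_articles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(id = character(), text = character(),
                  mesh_headings = list()))
  }
  rows <- purrr::map(lines, function(l) {
    o <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    tibble(id = as.character(o$id),
           text = as.character(o$text %||% ""),
           mesh_headings = list(as.character(unlist(o$mesh_headings))))
  })
  dplyr::bind_rows(rows)
}

#' Label news articles with the citation rule cascade
#'
#' News articles are labeled by the same heading cascade as citations but
#' with no token-count filter; they serve exclusively as an external test
#' set, never as training data. Articles without headings are labeled
#' `OTHER` with a notice.
#'
#' @param news Tibble from [read_news_articles()].
#' @inheritParams label_documents
#' @return Tibble: `id`, `text`, `label`.
#' @export
label_news_articles <- function(news, cfg, vocab) {
  empty <- purrr::map_lgl(news$mesh_headings, function(h) length(h) == 0)
  if (any(empty)) {
    inform(paste0(sum(empty),
                  " news article(s) without MeSH headings labeled OTHER"))
  }
  label_documents(news, cfg, vocab) |>
    select("id", "text", "label")
}
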