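#' Parse MeSH descriptor and supplementary-concept XML
#'
#' Reads the NLM MeSH descriptor XML dialect (`DescriptorRecordSet` /
#' `DescriptorRecord` with `DescriptorUI`, `DescriptorName/String` and an
#' optional `TreeNumberList`) and, optionally, the supplementary-concept
#' dialect (`SupplementalRecordSet` / `SupplementalRecord` with
#' `SupplementalRecordUI` and `HeadingMappedToList`). Descriptors without
#' tree numbers are accepted (some have none); a descriptor without a UI is
#' a hard parse error. Leading `*` markers on mapped-to descriptor UIs are
#' stripped.
#'
#' @param descriptor_path Path to descriptor XML.
#' @param supplementary_path Optional path to supplementary-record XML.
#' @return A `mesh_vocabulary`: list with `descriptors` (tibble `ui`, `name`,
#'   `tree_numbers` list-column), `supplementary` (tibble `ui`, `name`,
#'   `mapped_to` list-column) and `tree_index` (tibble `tree_number`, `ui`,
#'   one row per descriptor/tree-number pair).
#' @export
parse_mesh <- function(descriptor_path, supplementary_path = NULL) {
  doc <- xml2::read_xml(descriptor_path)
  recs <- xml2::xml_find_all(doc, ".//DescriptorRecord")
  descriptors <- purrr::map(recs, function(r) {
    ui <- xml2::xml_text(xml2::xml_find_first(r, "./DescriptorUI"))
    if (is.na(ui) || !nzchar(ui)) abort("DescriptorRecord without DescriptorUI")
    name <- xml2::xml_text(xml2::xml_find_first(r, "./DescriptorName/String"))
    tns <- xml2::xml_text(xml2::xml_find_all(r, "./TreeNumberList/TreeNumber"))
    tibble(ui = ui, name = ifelse(is.na(name), "", name),
           tree_numbers = list(tns))
  })
  descriptors <- if (length(descriptors) > 0) dplyr::bind_rows(descriptors) else
    tibble(ui = character(), name = character(), tree_numbers = list())

  supplementary <- tibble(ui = character(), name = character(),
                          mapped_to = list())
  if (!is.null(supplementary_path)) {
    sdoc <- xml2::read_xml(supplementary_path)
    srecs <- xml2::xml_find_all(sdoc, ".//SupplementalRecord")
    rows <- purrr::map(srecs, function(r) {
      ui <- xml2::xml_text(xml2::xml_find_first(r, "./SupplementalRecordUI"))
      if (is.na(ui) || !nzchar(ui)) abort("SupplementalRecord without UI")
      name <- xml2::xml_text(xml2::xml_find_first(r, "./SupplementalRecordName/String"))
      mapped <- xml2::xml_text(xml2::xml_find_all(
        r, "./HeadingMappedToList/HeadingMappedTo/DescriptorReferredTo/DescriptorUI"))
      tibble(ui = ui, name = ifelse(is.na(name), "", name),
             mapped_to = list(sub("^\\*", "", mapped)))
    })
    if (length(rows) > 0) supplementary <- dplyr::bind_rows(rows)
  }

  tree_index <- descriptors |>
    select("ui", "tree_numbers") |>
    tidyr::unnest_longer("tree_numbers", values_to = "tree_number") |>
    filter(!is.na(.data$tree_number)) |>
    select("tree_number", "ui")

  structure(list(descriptors = descriptors, supplementary = supplementary,
                 tree_index = tree_index),
            class = "mesh_vocabulary")
}

#' @export
print.mesh_vocabulary <- function(x, ...) {
  cat(sprintf("<mesh_vocabulary> %d descriptors (%d tree numbers), %d supplementary concepts\n",
              nrow(x$descriptors), nrow(x$tree_index), nrow(x$supplementary)))
  invisible(x)
}

# tree numbers of a descriptor UI (character(0) if unknown / none)
mesh_tree_numbers <- function(vocab, ui) {
  vocab$tree_index$tree_number[vocab$tree_index$ui == ui]
}

#' Expand a seed set of MeSH UIs to all tree descendants
#'
#' For every seed descriptor present in the vocabulary, adds every
#' descriptor holding a tree number that strictly extends (by one or more
#' dotted components) one of the seed's tree numbers. The test is purely
#' lexical on tree-number strings. Seed UIs unknown to the vocabulary —
#' supplementary concepts have no tree numbers — pass through unexpanded.
#'
#' @param seed Character vector of MeSH UIs.
#' @param vocab A [parse_mesh()] vocabulary.
#' @return Character vector: `seed` plus all descendants, sorted, unique.
#' @export
expand_tree_children <- function(seed, vocab) {
  seed <- unique(as.character(seed))
  seed_tns <- vocab$tree_index$tree_number[vocab$tree_index$ui %in% seed]
  if (length(seed_tns) == 0) return(sort(seed))
  prefixes <- paste0(unique(seed_tns), ".")
  hit <- rep(FALSE, nrow(vocab$tree_index))
  for (p in prefixes) {
    hit <- hit | startsWith(vocab$tree_index$tree_number, p)
  }
  sort(unique(c(seed, vocab$tree_index$ui[hit])))
}

#' Build the final rare-disease term set
#'
#' Combines the ontology-extracted MeSH ids with (i) every MeSH-tree
#' descendant of those ids (`source = "tree_child"`) and (ii) the MeSH
#' rare-diseases attribute descriptor `D035583`
#' (`source = "seed_attribute_term"`), which is always included. Extraction
#' provenance wins over `tree_child` for ids reached both ways. The result
#' is closed under descendant expansion and idempotent: building from an
#' already-expanded set adds nothing.
#'
#' @param extracted Tibble from [extract_rare_mesh_terms()] (may have zero
#'   rows).
#' @param vocab A [parse_mesh()] vocabulary.
#' @return A `rare_term_set`: tibble (`mesh_id`, `source`, `origin_node`)
#'   sorted by `mesh_id`.
#' @export
build_rare_term_set <- function(extracted, vocab) {
  if (is.null(extracted) || nrow(extracted) == 0) {
    extracted <- tibble(mesh_id = character(), source = character(),
                        origin_node = character())
  }
  expanded <- expand_tree_children(extracted$mesh_id, vocab)
  children <- setdiff(expanded, extracted$mesh_id)
  out <- dplyr::bind_rows(
    extracted,
    tibble(mesh_id = children, source = "tree_child",
           origin_node = NA_character_),
    tibble(mesh_id = "D035583", source = "seed_attribute_term",
           origin_node = NA_character_)
  ) |>
    distinct(.data$mesh_id, .keep_all = TRUE) |>
    arrange(.data$mesh_id)
  class(out) <- c("rare_term_set", class(out))
  out
}

#' Read/write a rare term set as TSV
#'
#' @param x A `rare_term_set` tibble.
#' @param path Output/input TSV path (`mesh_id`, `source`, `origin_node`).
#' @return `write_rare_term_set()` returns `path` invisibly;
#'   `read_rare_term_set()` a `rare_term_set` tibble.
#' @export
write_rare_term_set <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_rare_term_set
#' @export
read_rare_term_set <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE) |>
    arrange(.data$mesh_id)
  class(out) <- c("rare_term_set", class(out))
  out
}
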