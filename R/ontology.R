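#' Parse a Mondo-style disease ontology from OBO-graph JSON
#'
#' Reads an OBO-graph-style JSON serialization (a `graphs` array whose first
#' element holds `nodes` and `edges`) into an `ontology_graph` object. Node
#' ids and xref CURIEs are kept verbatim; a node is flagged rare when any of
#' its `meta.subsets` entries (or `meta.basicPropertyValues` values), after
#' stripping any IRI path, equals `rare_marker`. Only `is_a` edges are
#' retained.
#'
#' @param path Path to an OBO-graph JSON file.
#' @param rare_marker Marker string identifying the rare-disease subset
#'   annotation (default `"rare"`); ontology releases vary in how the subset
#'   IRI is spelled, so matching is on the final path component.
#' @return An `ontology_graph`: a list with `nodes` (tibble: `id`, `name`,
#'   `is_rare`, `xrefs` list-column) and `edges` (tibble: `child`, `parent`),
#'   plus derived `children` / `parents` lookup environments.
#' @export
parse_ontology <- function(path, rare_marker = "rare") {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) abort(paste0("malformed ontology JSON: ", conditionMessage(e)))
  )
  graph <- if (!is.null(doc$graphs)) doc$graphs[[1]] else doc
  nodes_raw <- graph$nodes %||% list()
  edges_raw <- graph$edges %||% list()

  strip_iri <- function(x) sub(".*[/#]", "", x)

  nodes <- purrr::map(nodes_raw, function(n) {
    if (is.null(n$id)) abort("ontology node without an id")
    subsets <- unlist(n$meta$subsets) %||% character()
    props <- purrr::map_chr(n$meta$basicPropertyValues %||% list(),
                            function(p) as.character(p$val %||% ""))
    markers <- strip_iri(c(subsets, props))
    xrefs <- purrr::map_chr(n$meta$xrefs %||% list(),
                            function(x) as.character(x$val %||% ""))
    tibble(
      id = as.character(n$id),
      name = as.character(n$lbl %||% ""),
      is_rare = any(markers == rare_marker),
      xrefs = list(xrefs[nzchar(xrefs)])
    )
  })
  nodes <- if (length(nodes) > 0) dplyr::bind_rows(nodes) else
    tibble(id = character(), name = character(), is_rare = logical(),
           xrefs = list())

  if (anyDuplicated(nodes$id) > 0) {
    abort(paste0("duplicate ontology node id: ",
                 nodes$id[duplicated(nodes$id)][1]))
  }

  edges <- purrr::map(edges_raw, function(e) {
    pred <- as.character(e$pred %||% "")
    if (!pred %in% c("is_a", "subClassOf")) return(NULL)
    tibble(child = as.character(e$sub), parent = as.character(e$obj))
  })
  edges <- if (length(edges) > 0) dplyr::bind_rows(edges) else
    tibble(child = character(), parent = character())
  edges <- dplyr::distinct(edges)

  structure(list(nodes = nodes, edges = edges), class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("<ontology_graph> %d nodes (%d rare), %d is_a edges\n",
              nrow(x$nodes), sum(x$nodes$is_rare), nrow(x$edges)))
  invisible(x)
}

# ids of nodes with no is_a children anywhere in the graph
ontology_leaves <- function(graph) {
  setdiff(graph$nodes$id, unique(graph$edges$parent))
}

#' Read a GARD-to-MeSH mapping table
#'
#' @param path Two-column TSV (`gard_id`, `mesh_id`), one row per link. MeSH
#'   ids may carry a `MESH:` prefix, which is stripped.
#' @return Tibble with character columns `gard_id`, `mesh_id`.
#' @export
read_gard_mapping <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("gard_id", "mesh_id") %in% names(tbl))) {
    abort("GARD mapping must have columns gard_id and mesh_id")
  }
  tbl |>
    mutate(gard_id = as.character(.data$gard_id),
           mesh_id = sub("^MESH:", "", as.character(.data$mesh_id))) |>
    select("gard_id", "mesh_id") |>
    distinct()
}

#' Extract rare-disease MeSH identifiers from an ontology graph
#'
#' Scans every *leaf* node flagged rare (a leaf has no `is_a` children
#' anywhere in the graph) and collects MeSH identifiers from its xrefs:
#' `MESH:` CURIEs directly (`source = "direct_xref"`), and otherwise `GARD:`
#' CURIEs resolved through the GARD-to-MeSH mapping
#' (`source = "via_gard"`). The direct route takes precedence for a node
#' that has both. Non-leaf rare nodes and non-rare leaves contribute
#' nothing. GARD xrefs absent from the mapping are skipped with a warning.
#'
#' @param graph An [parse_ontology()] result.
#' @param gard Tibble from [read_gard_mapping()]; may have zero rows.
#' @return Tibble with one row per distinct MeSH id: `mesh_id` (bare UI,
#'   `MESH:` prefix stripped), `source`, `origin_node`; sorted by `mesh_id`.
#'   When a MeSH id is reachable from several nodes, `direct_xref` wins over
#'   `via_gard`, then the lexicographically smallest origin node.
#' @export
extract_rare_mesh_terms <- function(graph, gard = NULL) {
  if (is.null(gard)) {
    gard <- tibble(gard_id = character(), mesh_id = character())
  }
  leaves <- ontology_leaves(graph)
  cand <- graph$nodes |>
    filter(.data$is_rare, .data$id %in% leaves)

  unresolved <- character()
  rows <- purrr::pmap(list(cand$id, cand$xrefs), function(id, xrefs) {
    mesh <- xrefs[startsWith(xrefs, "MESH:")]
    if (length(mesh) > 0) {
      return(tibble(mesh_id = sub("^MESH:", "", mesh),
                    source = "direct_xref", origin_node = id))
    }
    gard_ids <- sub("^GARD:", "", xrefs[startsWith(xrefs, "GARD:")])
    if (length(gard_ids) == 0) return(NULL)
    hit <- gard$mesh_id[gard$gard_id %in% gard_ids]
    miss <- setdiff(gard_ids, gard$gard_id)
    if (length(miss) > 0) {
      unresolved <<- c(unresolved, paste0(id, " -> GARD:", miss))
    }
    if (length(hit) == 0) return(NULL)
    tibble(mesh_id = unique(hit), source = "via_gard", origin_node = id)
  })
  if (length(unresolved) > 0) {
    warn(paste0("GARD xrefs with no MeSH mapping were skipped:\n  ",
                paste(unresolved, collapse = "\n  ")))
  }

  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) {
    return(tibble(mesh_id = character(), source = character(),
                  origin_node = character()))
  }
  # one provenance row per MeSH id: direct beats via_gard, then smallest origin
  out |>
    mutate(.rank = ifelse(.data$source == "direct_xref", 0L, 1L)) |>
    arrange(.data$mesh_id, .data$.rank, .data$origin_node) |>
    distinct(.data$mesh_id, .keep_all = TRUE) |>
    select("mesh_id", "source", "origin_node")
}
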