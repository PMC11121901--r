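#' Read PubMed/MEDLINE citation XML into raw citation records
#'
#' Parses the PubMed citation-XML dialect (`MedlineCitation/PMID`,
#' `Article/ArticleTitle`, `Abstract/AbstractText`, `MeshHeadingList`,
#' `PublicationTypeList`). Multi-part abstracts (labelled Background /
#' Methods / ... sections) are concatenated with single spaces. MeSH UIs are
#' collected from `MeshHeadingList` descriptor UIs and from supplementary
#' concept records in the `ChemicalList` (`NameOfSubstance` UIs). Gzipped
#' files are read transparently. No quality filtering happens here — see
#' [filter_citations()].
#'
#' @param paths One or more citation XML files, read in the order given.
#' @return Tibble of raw records: `pmid`, `pub_types` (list), `year`,
#'   `month`, `day`, `title`, `abstract`, `mesh_headings` (list), in
#'   document order. Missing fields yield empty strings / `NA` / empty sets.
#' @export
read_citations <- function(paths) {
  rows <- purrr::map(paths, function(path) {
    doc <- tryCatch(
      xml2::read_xml(path),
      error = function(e) abort(paste0("malformed citation XML in ", path,
                                       ": ", conditionMessage(e)))
    )
    arts <- xml2::xml_find_all(doc, ".//MedlineCitation")
    purrr::map(arts, function(a) {
      text1 <- function(xp) {
        v <- xml2::xml_text(xml2::xml_find_first(a, xp))
        if (is.na(v)) "" else v
      }
      abstract_parts <- xml2::xml_text(
        xml2::xml_find_all(a, "./Article/Abstract/AbstractText"))
      year <- suppressWarnings(as.integer(
        text1("./Article/Journal/JournalIssue/PubDate/Year")))
      headings <- c(
        xml2::xml_attr(
          xml2::xml_find_all(a, "./MeshHeadingList/MeshHeading/DescriptorName"),
          "UI"),
        xml2::xml_attr(
          xml2::xml_find_all(a, "./ChemicalList/Chemical/NameOfSubstance"),
          "UI"))
      headings <- unique(headings[!is.na(headings) & nzchar(headings)])
      tibble(
        pmid = text1("./PMID"),
        pub_types = list(xml2::xml_text(xml2::xml_find_all(
          a, "./Article/PublicationTypeList/PublicationType"))),
        year = if (length(year) == 0) NA_integer_ else year,
        month = text1("./Article/Journal/JournalIssue/PubDate/Month"),
        day = text1("./Article/Journal/JournalIssue/PubDate/Day"),
        title = text1("./Article/ArticleTitle"),
        abstract = paste(abstract_parts, collapse = " "),
        mesh_headings = list(headings)
      )
    })
  })
  rows <- purrr::flatten(rows)
  if (length(rows) == 0) {
    return(tibble(pmid = character(), pub_types = list(), year = integer(),
                  month = character(), day = character(), title = character(),
                  abstract = character(), mesh_headings = list()))
  }
  dplyr::bind_rows(rows)
}

# rejection reasons, in the order the checks are applied
rejection_reasons <- function() {
  c("not_journal_article", "missing_id", "duplicate_id", "invalid_date",
    "no_title", "no_abstract", "no_mesh", "min_tokens")
}

# first failing reason for one record, or NA if accepted
first_rejection <- function(pub_types, pmid, year, title, abstract,
                            mesh_headings, dup, min_tokens) {
  if (!"Journal Article" %in% pub_types) return("not_journal_article")
  if (is.na(pmid) || !nzchar(pmid)) return("missing_id")
  if (dup) return("duplicate_id")
  if (is.na(year) || year < 1000 || year > 9999) return("invalid_date")
  if (!nzchar(title)) return("no_title")
  if (!nzchar(abstract)) return("no_abstract")
  if (length(mesh_headings) == 0) return("no_mesh")
  if (count_tokens(paste(title, abstract)) < min_tokens) return("min_tokens")
  NA_character_
}

#' Apply record-quality filters to raw citation records
#'
#' Accepts a record iff, in this order: "Journal Article" is among its
#' publication types; the PMID is nonempty and not previously accepted
#' (first occurrence wins); the publication date has a valid 4-digit year;
#' title and abstract are nonempty; at least one MeSH heading is present;
#' and the joined `title + " " + abstract` text contains at least
#' `min_tokens` whitespace-delimited tokens. A rejected record carries the
#' first failed reason.
#'
#' @param raw Tibble from [read_citations()].
#' @param min_tokens Minimum whitespace token count of the joined text
#'   (default 128).
#' @return Tibble of accepted records with a materialized `text` column
#'   (title joined to abstract with a single space) and an `n_tokens`
#'   column. The rejection log — tibble (`pmid`, `reason`) in input order —
#'   is attached as attribute `"rejections"`; see [citation_rejections()].
#' @export
filter_citations <- function(raw, min_tokens = 128L) {
  n <- nrow(raw)
  reason <- character(n)
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    pmid <- raw$pmid[i]
    dup <- nzchar(pmid) && !is.null(seen[[pmid]])
    r <- first_rejection(raw$pub_types[[i]], pmid, raw$year[i], raw$title[i],
                         raw$abstract[i], raw$mesh_headings[[i]], dup,
                         min_tokens)
    reason[i] <- r
    if (is.na(r)) seen[[pmid]] <- TRUE
  }
  accepted <- raw[is.na(reason), , drop = FALSE] |>
    mutate(text = paste(.data$title, .data$abstract),
           n_tokens = count_tokens(.data$text))
  rejections <- tibble(pmid = raw$pmid[!is.na(reason)],
                       reason = reason[!is.na(reason)])
  attr(accepted, "rejections") <- rejections
  accepted
}

#' Rejection log of a filtered corpus
#'
#' @param accepted Result of [filter_citations()].
#' @return Tibble (`pmid`, `reason`), one row per rejected record.
#' @export
citation_rejections <- function(accepted) {
  attr(accepted, "rejections") %||% tibble(pmid = character(),
                                           reason = character())
}
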