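#' Class labels used throughout the pipeline
#'
#' Documents are assigned exactly one of three classes: `RARE` (the document
#' carries at least one MeSH heading from the rare-disease term set),
#' `NON_RARE` (a heading falls in the MeSH Diseases tree or Mental Disorders
#' subtree), or `OTHER` (the catch-all background class). The integer
#' encoding RARE = 0, NON_RARE = 1, OTHER = 2 is fixed for serialization
#' stability.
#'
#' @return Character vector of the three labels, in canonical order.
#' @export
#' @examples
#' class_levels()
class_levels <- function() {
  c("RARE", "NON_RARE", "OTHER")
}

#' Convert labels to/from their canonical integer encoding
#'
#' @param label Character vector of class labels.
#' @param code Integer vector of class codes (0, 1 or 2).
#' @return `label_to_code()` returns integers; `code_to_label()` a factor
#'   with levels [class_levels()].
#' @export
label_to_code <- function(label) {
  code <- match(as.character(label), class_levels()) - 1L
  if (anyNA(code)) {
    abort(paste0("unknown class label: ",
                 paste(unique(setdiff(label, class_levels())), collapse = ", ")))
  }
  code
}

#' @rdname label_to_code
#' @export
code_to_label <- function(code) {
  factor(class_levels()[as.integer(code) + 1L], levels = class_levels())
}

# coerce a character vector of labels to the canonical factor, validating
as_class_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), class_levels())
  if (length(bad) > 0) {
    abort(paste0("unknown class label(s): ", paste(bad, collapse = ", ")))
  }
  factor(x, levels = class_levels())
}

#' Count whitespace-delimited tokens
#'
#' A token is a maximal nonempty run of non-whitespace characters; the count
#' is the record-quality statistic used to filter citation records (texts
#' need at least 128 tokens).
#'
#' @param text Character vector.
#' @return Integer vector of token counts; `NA` input counts as 0.
#' @export
#' @examples
#' count_tokens(c("", "a  b\tc\nd"))
count_tokens <- function(text) {
  text[is.na(text)] <- ""
  stringr::str_count(text, "\\S+")
}

# does tree number tn fall under prefix p?
# single-letter prefixes denote a whole MeSH category ("C" matches C06.100);
# longer prefixes must match a whole leading segment ("F03" matches F03 and
# F03.625 but not F030).
tree_matches_prefix <- function(tn, p) {
  if (nchar(p) == 1L) {
    return(startsWith(tn, p))
  }
  tn == p | startsWith(tn, paste0(p, "."))
}

# strict descendant test on dotted tree numbers: t2 extends t1 by >= 1 segment
tree_extends <- function(t2, t1) {
  startsWith(t2, paste0(t1, "."))
}
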