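#' Balanced sampling plan
#'
#' The study design draws the same number of documents per class and
#' assigns them to disjoint train/validation/test splits; the published
#' study used 24,000 per class split 20,000 / 2,000 / 2,000 (72,000 records
#' in total).
#'
#' @param per_class_total Records sampled per class.
#' @param per_class_train,per_class_val,per_class_test Per-class split
#'   sizes; must sum to `per_class_total`.
#' @param seed Integer seed controlling both selection and assignment.
#' @return A `sampling_plan` list.
#' @export
sampling_plan <- function(per_class_total = 24000L,
                          per_class_train = 20000L,
                          per_class_val = 2000L,
                          per_class_test = 2000L,
                          seed = 1L) {
  sizes <- c(per_class_total, per_class_train, per_class_val, per_class_test)
  if (any(sizes <= 0)) abort("all sampling-plan counts must be positive")
  if (per_class_train + per_class_val + per_class_test != per_class_total) {
    abort("train + val + test must equal per_class_total")
  }
  structure(list(per_class_total = as.integer(per_class_total),
                 per_class_train = as.integer(per_class_train),
                 per_class_val = as.integer(per_class_val),
                 per_class_test = as.integer(per_class_test),
                 seed = as.integer(seed)),
            class = "sampling_plan")
}

# Algorithm R reservoir over row indices, deterministic under the current RNG
reservoir_sample <- function(idx, k) {
  n <- length(idx)
  if (n <= k) return(idx)
  res <- idx[seq_len(k)]
  for (i in (k + 1L):n) {
    j <- sample.int(i, 1L)
    if (j <= k) res[j] <- idx[i]
  }
  res
}

#' Sample a class-balanced dataset and assign disjoint splits
#'
#' For each class (in canonical label order) a seeded single-pass reservoir
#' draws exactly `per_class_total` examples, which are then shuffled and cut
#' contiguously into train/validation/test. Selection and assignment are
#' uniform and fully determined by the plan's seed.
#'
#' @param labeled Tibble with columns `id`, `text`, `label` (one of
#'   [class_levels()]).
#' @param plan A [sampling_plan()].
#' @return Tibble `id`, `text`, `label`, `split` (factor train/val/test),
#'   with exact per-class, per-split counts.
#' @export
sample_balanced <- function(labeled, plan) {
  stopifnot(inherits(plan, "sampling_plan"))
  labeled <- labeled |> mutate(label = as_class_factor(.data$label))
  withr::with_seed(plan$seed, {
    parts <- purrr::map(class_levels(), function(cl) {
      idx <- which(labeled$label == cl)
      if (length(idx) < plan$per_class_total) {
        abort(sprintf(
          "class %s has only %d candidates; %d required (shortfall %d)",
          cl, length(idx), plan$per_class_total,
          plan$per_class_total - length(idx)))
      }
      chosen <- reservoir_sample(idx, plan$per_class_total)
      chosen <- chosen[sample.int(length(chosen))]
      split <- rep(c("train", "val", "test"),
                   times = c(plan$per_class_train, plan$per_class_val,
                             plan$per_class_test))
      labeled[chosen, , drop = FALSE] |>
        mutate(split = factor(split, levels = c("train", "val", "test")))
    })
    dplyr::bind_rows(parts)
  })
}

#' Per-split, per-class count table of a dataset
#'
#' @param dataset Tibble from [sample_balanced()] (columns `label`,
#'   `split`).
#' @return Tibble with one row per split plus a `Total` row, one column per
#'   class plus a `Total` column.
#' @export
dataset_summary <- function(dataset) {
  splits <- c("train", "val", "test")
  counts <- purrr::map(splits, function(s) {
    in_split <- dataset$split == s
    row <- purrr::map_int(class_levels(),
                          function(cl) sum(in_split & dataset$label == cl))
    tibble(split = s, !!!setNames(as.list(row), class_levels()),
           Total = sum(row))
  })
  out <- dplyr::bind_rows(counts)
  totals <- tibble(split = "Total",
                   !!!setNames(as.list(purrr::map_int(
                     class_levels(), function(cl) sum(out[[cl]]))),
                     class_levels()))
  totals$Total <- sum(out$Total)
  dplyr::bind_rows(out, totals)
}

#' Write/read a dataset as per-split JSONL files
#'
#' Each split goes to `<dir>/<split>.jsonl`, one object per line with
#' fields `id`, `text`, `label` (canonical integer code, RARE = 0,
#' NON_RARE = 1, OTHER = 2).
#'
#' @param dataset Tibble from [sample_balanced()].
#' @param dir Output directory (created if needed).
#' @param split Which split to read.
#' @return `write_dataset()` returns the paths invisibly; `read_dataset()`
#'   a tibble `id`, `text`, `label`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::map_chr(c("train", "val", "test"), function(s) {
    path <- file.path(dir, paste0(s, ".jsonl"))
    part <- dataset |> filter(.data$split == s)
    lines <- purrr::pmap_chr(
      list(part$id, part$text, label_to_code(part$label)),
      function(id, text, label) {
        jsonlite::toJSON(list(id = id, text = text, label = label),
                         auto_unbox = TRUE)
      })
    writeLines(lines, path)
    path
  })
  invisible(paths)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir, split = c("train", "val", "test")) {
  split <- match.arg(split)
  lines <- readLines(file.path(dir, paste0(split, ".jsonl")), warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(id = character(), text = character(),
                  label = factor(character(), levels = class_levels())))
  }
  rows <- purrr::map(lines, function(l) {
    o <- jsonlite::fromJSON(l)
    tibble(id = as.character(o$id), text = as.character(o$text),
           label = as.integer(o$label))
  })
  dplyr::bind_rows(rows) |> mutate(label = code_to_label(.data$label))
}
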