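#' Construct a multi-sorter card-sort dataset
#'
#' A sort dataset holds the pile assignments of `m` sorters over a shared set
#' of `n` excerpts, in long format: one record per (participant, excerpt,
#' pile). Pile labels are opaque and meaningful only *within* one
#' participant; the same label used by two participants does not imply any
#' relation between their piles.
#'
#' @param records A data frame with columns `participant_id`, `excerpt_id`
#'   and `pile_label` (all coerced to character).
#' @param allow_incomplete If `FALSE` (default), every participant must
#'   assign every excerpt seen anywhere in the data; missing assignments are
#'   an error. If `TRUE`, incomplete sorts are accepted and downstream
#'   similarity scores count only observed co-assignments.
#'
#' @return An object of class `sort_dataset`: a list with elements
#'   `records` (tibble), `excerpt_ids` and `participant_ids` (both in
#'   first-appearance order), and `complete` (logical).
#'
#' @details Duplicate (participant, excerpt) rows violate the one-pile-per-
#'   excerpt rule and raise an integrity error naming the offending pairs.
#' @examples
#' ds <- sort_dataset(data.frame(
#'   participant_id = c("P1", "P1", "P1", "P1"),
#'   excerpt_id     = c("A", "B", "C", "D"),
#'   pile_label     = c("g1", "g1", "g2", "g2")
#' ))
#' ds$excerpt_ids
#' @export
sort_dataset <- function(records, allow_incomplete = FALSE) {
  required <- c("participant_id", "excerpt_id", "pile_label")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    ts_error("themesort_format_error",
             paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  rec <- tibble::tibble(
    participant_id = as.character(records$participant_id),
    excerpt_id     = as.character(records$excerpt_id),
    pile_label     = as.character(records$pile_label)
  )
  if (anyNA(rec) || any(rec == "")) {
    ts_error("themesort_format_error",
             "empty or missing values in participant/excerpt/pile columns")
  }
  if (nrow(rec) == 0) {
    ts_error("themesort_format_error", "no sort records supplied")
  }

  key <- paste(rec$participant_id, rec$excerpt_id, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    dups <- gsub("\r", ", ", dups, fixed = TRUE)
    ts_error("themesort_integrity_error",
             paste0("excerpt assigned more than once by the same participant: (",
                    paste(dups, collapse = "), ("), ")"))
  }

  excerpt_ids <- unique(rec$excerpt_id)
  participant_ids <- unique(rec$participant_id)

  if (length(excerpt_ids) < 2) {
    ts_error("themesort_format_error", "a sort dataset needs at least 2 excerpts")
  }

  complete <- TRUE
  for (p in participant_ids) {
    seen <- rec$excerpt_id[rec$participant_id == p]
    miss <- setdiff(excerpt_ids, seen)
    if (length(miss) > 0) {
      if (!allow_incomplete) {
        ts_error("themesort_incomplete_error",
                 paste0("participant ", p, " did not sort excerpt(s): ",
                        paste(miss, collapse = ", ")),
                 participant = p, missing_excerpts = miss)
      }
      complete <- FALSE
    }
  }

  structure(
    list(records = rec,
         excerpt_ids = excerpt_ids,
         participant_ids = participant_ids,
         complete = complete),
    class = "sort_dataset"
  )
}

#' @export
print.sort_dataset <- function(x, ...) {
  cat("<sort_dataset> ", length(x$participant_ids), " sorter(s), ",
      length(x$excerpt_ids), " excerpts, ", nrow(x$records), " assignments",
      if (!x$complete) " (incomplete sorts allowed)", "\n", sep = "")
  invisible(x)
}

#' One participant's piles
#'
#' @param ds A [sort_dataset()].
#' @param participant Participant id.
#' @return Named list of character vectors, one per pile, members in
#'   record order.
#' @export
piles <- function(ds, participant) {
  stopifnot(inherits(ds, "sort_dataset"))
  if (!participant %in% ds$participant_ids) {
    ts_error("themesort_format_error",
             paste0("unknown participant: ", participant))
  }
  rec <- ds$records[ds$records$participant_id == participant, ]
  split(rec$excerpt_id, factor(rec$pile_label, levels = unique(rec$pile_label)))
}

#' Read a long-format sort table
#'
#' Reads a delimited text file with one row per (participant, excerpt, pile)
#' assignment — the spreadsheet layout in which card-sort sessions are
#' typically recorded. Column names are configurable so existing
#' spreadsheets need not be renamed.
#'
#' @param path Path to a delimited text file with a header row.
#' @param sep Field delimiter (default `","`; use `"\t"` for TSV).
#' @param col_participant,col_excerpt,col_pile Names of the three required
#'   columns in the file's header.
#' @inheritParams sort_dataset
#' @return A [sort_dataset()].
#' @export
read_sort_table <- function(path, sep = ",",
                            col_participant = "participant_id",
                            col_excerpt = "excerpt_id",
                            col_pile = "pile_label",
                            allow_incomplete = FALSE) {
  if (!file.exists(path)) {
    ts_error("themesort_format_error", paste0("file not found: ", path))
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           check.names = FALSE, comment.char = "")
  wanted <- c(col_participant, col_excerpt, col_pile)
  missing_cols <- setdiff(wanted, names(raw))
  if (length(missing_cols) > 0) {
    ts_error("themesort_format_error",
             paste0("file ", path, " lacks column(s): ",
                    paste(missing_cols, collapse = ", ")))
  }
  sort_dataset(
    data.frame(participant_id = raw[[col_participant]],
               excerpt_id     = raw[[col_excerpt]],
               pile_label     = raw[[col_pile]]),
    allow_incomplete = allow_incomplete
  )
}

#' Write a sort dataset back to a delimited table
#'
#' Labels containing the delimiter are quoted, so
#' `read_sort_table(write_sort_table(ds, f))` recovers the same record set.
#'
#' @param ds A [sort_dataset()].
#' @param path Output file path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_sort_table <- function(ds, path, sep = ",") {
  stopifnot(inherits(ds, "sort_dataset"))
  utils::write.table(ds$records, path, sep = sep, row.names = FALSE,
                     quote = TRUE, qmethod = "double")
  invisible(path)
}

#' Check a dataset against the sorting-task instructions
#'
#' Sorters are asked to make at least two piles and to avoid a catch-all
#' miscellaneous pile. These instructions bind the sorters, not the data, so
#' violations are reported as advisory warnings rather than errors.
#'
#' @param ds A [sort_dataset()].
#' @return A list with `pile_counts`, a tibble of per-participant pile
#'   counts, and `warnings`, a character vector (empty when every
#'   participant made at least two piles).
#' @export
validate_protocol <- function(ds) {
  stopifnot(inherits(ds, "sort_dataset"))
  counts <- vapply(ds$participant_ids,
                   function(p) length(piles(ds, p)), integer(1))
  warnings <- character(0)
  for (p in ds$participant_ids[counts < 2]) {
    warnings <- c(warnings,
                  paste0("participant ", p, " used fewer than 2 piles (",
                         counts[[p]], ")"))
  }
  list(pile_counts = tibble::tibble(participant_id = ds$participant_ids,
                                    n_piles = unname(counts)),
       warnings = warnings)
}

#' Read an excerpt catalogue
#'
#' A catalogue maps excerpt ids to their verbatim text, with optional
#' metadata columns (e.g. school, gender, time point).
#'
#' @param path Delimited text file with header; must contain columns
#'   `excerpt_id` and `text` (names configurable).
#' @param sep Field delimiter.
#' @param col_excerpt,col_text Column names for id and text.
#' @return A tibble with `excerpt_id`, `text` and any extra columns.
#' @export
read_excerpt_catalog <- function(path, sep = ",",
                                 col_excerpt = "excerpt_id",
                                 col_text = "text") {
  if (!file.exists(path)) {
    ts_error("themesort_format_error", paste0("file not found: ", path))
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           check.names = FALSE, comment.char = "")
  missing_cols <- setdiff(c(col_excerpt, col_text), names(raw))
  if (length(missing_cols) > 0) {
    ts_error("themesort_format_error",
             paste0("catalogue lacks column(s): ",
                    paste(missing_cols, collapse = ", ")))
  }
  names(raw)[names(raw) == col_excerpt] <- "excerpt_id"
  names(raw)[names(raw) == col_text] <- "text"
  if (anyDuplicated(raw$excerpt_id)) {
    ts_error("themesort_integrity_error",
             "duplicate excerpt_id in catalogue")
  }
  tibble::as_tibble(raw[, c("excerpt_id", "text",
                            setdiff(names(raw), c("excerpt_id", "text")))])
}
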