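#' Per-sorter pile-preservation diagnostics
#'
#' A sorter's pile is *preserved* when every excerpt it contains lands in
#' one and the same final group; a pile containing an unassigned excerpt is
#' never preserved. Counting how many of each sorter's piles survive the
#' combined model quantifies how well that sorter's perspective is
#' represented in the final themes.
#'
#' Single-excerpt piles are trivially coherent, so by default they are
#' counted in `piles` but excluded from both `piles_multi` and
#' `piles_preserved`; set `count_singletons = TRUE` to count a singleton
#' pile as preserved whenever its excerpt was assigned to a group.
#'
#' @param ds A [sort_dataset()].
#' @param clustering A `pte_clustering` covering every excerpt of `ds`.
#' @param count_singletons Include size-1 piles in the preserved count
#'   (default `FALSE`).
#' @return A tibble with one row per participant: `participant_id`,
#'   `piles`, `piles_multi` (piles with two or more excerpts) and
#'   `piles_preserved`.
#' @export
preservation_table <- function(ds, clustering, count_singletons = FALSE) {
  stopifnot(inherits(ds, "sort_dataset"), inherits(clustering, "pte_clustering"))
  missing_ids <- setdiff(ds$excerpt_ids, clustering$assignment$excerpt_id)
  if (length(missing_ids) > 0) {
    ts_error("themesort_consistency_error",
             paste0("clustering lacks excerpt(s): ",
                    paste(missing_ids, collapse = ", ")))
  }
  group_of <- stats::setNames(clustering$assignment$group,
                              clustering$assignment$excerpt_id)
  rows <- lapply(ds$participant_ids, function(p) {
    pl <- piles(ds, p)
    sizes <- lengths(pl)
    preserved_multi <- vapply(pl[sizes >= 2], function(members) {
      g <- group_of[members]
      !anyNA(g) && length(unique(g)) == 1
    }, logical(1))
    n_pres <- sum(preserved_multi)
    if (count_singletons) {
      n_pres <- n_pres + sum(!is.na(group_of[unlist(pl[sizes == 1])]))
    }
    tibble::tibble(participant_id = p,
                   piles = length(pl),
                   piles_multi = sum(sizes >= 2),
                   piles_preserved = as.integer(n_pres))
  })
  do.call(rbind, rows)
}

#' Flag sorters with low pile preservation
#'
#' Sorters whose preserved fraction falls below a threshold sorted a
#' substantially different structure than the combined model — candidates
#' for qualitative follow-up (e.g. an interview about their perspective).
#'
#' @param table A preservation table from [preservation_table()].
#' @param threshold Fraction in \[0, 1\]; participants with
#'   `piles_preserved / denominator < threshold` are flagged.
#' @param denominator `"multi"` (default; preserved over multi-excerpt
#'   piles) or `"all"` (over all piles).
#' @return A tibble of flagged participants with their `ratio`, sorted
#'   ascending by ratio (most divergent sorter first).
#' @export
low_preservation_flags <- function(table, threshold = 0.5,
                                   denominator = c("multi", "all")) {
  denominator <- match.arg(denominator)
  denom <- if (denominator == "multi") table$piles_multi else table$piles
  ratio <- ifelse(denom > 0, table$piles_preserved / denom, NA_real_)
  out <- tibble::tibble(participant_id = table$participant_id, ratio = ratio)
  out <- out[!is.na(out$ratio) & out$ratio < threshold, ]
  out[order(out$ratio), ]
}
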