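#' Design for a planted-theme sorting simulation
#'
#' Describes a population of `m` sorters who each start from the same `K`
#' latent themes over `n` excerpts and then individually distort them:
#' with probability `p_merge` a sorter merges one random pair of piles
#' (lumping two themes), with probability `p_split` splits one random pile
#' of at least 4 excerpts in two (a finer reading), and finally each
#' excerpt is moved to a uniformly chosen *other* pile with probability
#' `epsilon` (idiosyncratic noise). Defaults mirror a realistic sorting
#' session: 8 sorters over 40 excerpts around 4 latent themes.
#'
#' @param n Number of excerpts (default 40).
#' @param m Number of sorters (default 8).
#' @param K Number of latent themes (default 4); must be >= 2, since
#'   sorters are instructed to make at least two piles and `K = 1` leaves
#'   no way to honour that from the planted structure.
#' @param theme_sizes Integer partition of `n` into `K` parts (each >= 2);
#'   default: as even as possible.
#' @param p_merge,p_split,epsilon Distortion probabilities in \[0, 1\].
#' @param seed Root seed; each sorter draws from a substream at a fixed
#'   offset, so adding sorters never perturbs earlier sorters' draws.
#' @return A `planted_design` list.
#' @export
planted_design <- function(n = 40, m = 8, K = 4, theme_sizes = NULL,
                           p_merge = 0.2, p_split = 0.2, epsilon = 0.1,
                           seed = 1) {
  if (K < 2) {
    ts_error("themesort_design_error",
             "K must be >= 2: a single planted theme cannot satisfy the minimum of two piles")
  }
  if (is.null(theme_sizes)) {
    theme_sizes <- rep(n %/% K, K) + c(rep(1, n %% K), rep(0, K - n %% K))
  }
  if (length(theme_sizes) != K || sum(theme_sizes) != n) {
    ts_error("themesort_design_error",
             "theme_sizes must be a length-K partition of n")
  }
  if (any(theme_sizes < 2)) {
    ts_error("themesort_design_error", "every theme needs >= 2 excerpts")
  }
  probs <- c(p_merge = p_merge, p_split = p_split, epsilon = epsilon)
  if (any(probs < 0 | probs > 1)) {
    ts_error("themesort_design_error", "probabilities must lie in [0, 1]")
  }
  if (n < 4 || m < 1) {
    ts_error("themesort_design_error", "need n >= 4 and m >= 1")
  }
  structure(list(n = as.integer(n), m = as.integer(m), K = as.integer(K),
                 theme_sizes = as.integer(theme_sizes),
                 p_merge = p_merge, p_split = p_split, epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "planted_design")
}

# Internal: distort the planted piles for one sorter. `piles` is a list of
# integer vectors (excerpt indices).
distort_piles <- function(piles, p_merge, p_split, epsilon) {
  # at most one merge, only if it leaves at least two piles
  if (stats::runif(1) < p_merge && length(piles) >= 3) {
    pick <- sample.int(length(piles), 2)
    piles[[pick[1]]] <- c(piles[[pick[1]]], piles[[pick[2]]])
    piles[[pick[2]]] <- NULL
  }
  # at most one split of a pile with >= 4 members, both halves >= 2
  if (stats::runif(1) < p_split) {
    big <- which(lengths(piles) >= 4)
    if (length(big) > 0) {
      tgt <- if (length(big) == 1) big else sample(big, 1)
      members <- piles[[tgt]]
      take <- sample.int(length(members) - 3L, 1) + 1L  # uniform on 2..(size-2)
      moved <- sample(members, take)
      piles[[tgt]] <- setdiff(members, moved)
      piles[[length(piles) + 1L]] <- moved
    }
  }
  # per-excerpt epsilon reassignment to a uniformly random other pile
  if (epsilon > 0 && length(piles) >= 2) {
    all_members <- sort(unlist(piles))
    for (x in all_members) {
      if (stats::runif(1) < epsilon) {
        cur <- which(vapply(piles, function(p) x %in% p, logical(1)))
        other <- setdiff(seq_along(piles), cur)
        dest <- if (length(other) == 1) other else sample(other, 1)
        piles[[cur]] <- setdiff(piles[[cur]], x)
        piles[[dest]] <- c(piles[[dest]], x)
      }
    }
    piles <- piles[lengths(piles) > 0]
  }
  piles
}

#' Simulate a multi-sorter dataset with planted themes
#'
#' Generates each sorter's piles by distorting the planted partition per
#' the design (see [planted_design()]), fully reproducibly from the seed.
#'
#' @param design A `planted_design`.
#' @return A list with `dataset` (a [sort_dataset()]; excerpts `ID1..IDn`,
#'   sorters `P1..Pm`, pile labels `Gp1..`) and `truth` (tibble
#'   `excerpt_id`, `theme` — the planted theme of each excerpt).
#' @export
simulate_sorts <- function(design) {
  stopifnot(inherits(design, "planted_design"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })

  excerpt_ids <- paste0("ID", seq_len(design$n))
  theme <- rep(seq_len(design$K), design$theme_sizes)
  planted <- split(seq_len(design$n), theme)

  recs <- vector("list", design$m)
  for (j in seq_len(design$m)) {
    set.seed((design$seed + j * 1000003L) %% 2147483647L)
    pl <- distort_piles(unname(planted),
                        design$p_merge, design$p_split, design$epsilon)
    pile_of <- integer(design$n)
    for (i in seq_along(pl)) pile_of[pl[[i]]] <- i
    recs[[j]] <- tibble::tibble(
      participant_id = paste0("P", j),
      excerpt_id = excerpt_ids,
      pile_label = paste0("Gp", pile_of)
    )
  }
  list(
    dataset = sort_dataset(do.call(rbind, recs)),
    truth = tibble::tibble(excerpt_id = excerpt_ids, theme = theme)
  )
}

#' Adjusted Rand index between a clustering and the planted truth
#'
#' Chance-corrected agreement (permutation-model expectation) between the
#' recovered grouping and the planted themes. Unassigned excerpts are
#' treated as singleton clusters, so leaving excerpts out of every theme is
#' penalised exactly as splitting them off would be.
#'
#' @param clustering A `pte_clustering`, or a named membership vector.
#' @param truth A tibble with `excerpt_id` and `theme` (as returned by
#'   [simulate_sorts()]), or a named vector of theme ids.
#' @return The adjusted Rand index, in \[-1, 1\]; 1 for identical
#'   partitions, ~0 for unrelated ones.
#' @export
recovery_score <- function(clustering, truth) {
  if (inherits(clustering, "pte_clustering")) {
    a <- clustering$assignment
    got <- stats::setNames(a$group, a$excerpt_id)
  } else {
    got <- clustering
  }
  # unassigned excerpts become unique singleton labels
  nas <- which(is.na(got))
  if (length(nas) > 0) {
    got[nas] <- max(c(0, got), na.rm = TRUE) + seq_along(nas)
  }
  if (is.data.frame(truth)) {
    truth <- stats::setNames(truth$theme, truth$excerpt_id)
  }
  if (!setequal(names(got), names(truth))) {
    ts_error("themesort_consistency_error",
             "clustering and truth cover different excerpt sets")
  }
  mclust::adjustedRandIndex(unname(got[names(truth)]), unname(truth))
}
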