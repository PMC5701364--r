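# Two sorters over four food items: sorter 1 piles {raspberry, tomato,
# grapes} and {seaweed}; sorter 2 piles {raspberry, tomato} and
# {grapes, seaweed}. Known by-hand similarity scores: r-t 2, r-g 1, t-g 1,
# g-s 1, r-s 0, t-s 0.
fruit_dataset <- function() {
  sort_dataset(data.frame(
    participant_id = rep(c("p1", "p2"), each = 4),
    excerpt_id = rep(c("raspberry", "tomato", "grapes", "seaweed"), 2),
    pile_label = c("a", "a", "a", "b", "x", "x", "y", "y")
  ))
}

# Three sorters over five excerpts in long spreadsheet layout.
five_excerpt_dataset <- function() {
  sort_dataset(data.frame(
    participant_id = rep(c("P1", "P2", "P3"), each = 5),
    excerpt_id = rep(paste0("ID", 1:5), 3),
    pile_label = c("Gp5", "Gp5", "Gp7", "Gp7", "Gp5",
                   "Gp2", "Gp6", "Gp6", "Gp2", "Gp2",
                   "Gp2", "Gp2", "Gp6", "Gp6", "Gp7")
  ))
}

# Random complete sorts: each sorter draws an independent random partition.
random_sort_dataset <- function(n, m, seed, max_piles = 5) {
  set.seed(seed)
  recs <- do.call(rbind, lapply(seq_len(m), function(j) {
    k <- sample(2:max_piles, 1)
    data.frame(participant_id = paste0("P", j),
               excerpt_id = paste0("E", seq_len(n)),
               pile_label = paste0("g", sample.int(k, n, replace = TRUE)))
  }))
  sort_dataset(recs)
}

# Random weighted network built directly from sampled edges.
random_network <- function(n, p_edge, seed, max_score = 5) {
  set.seed(seed)
  nodes <- paste0("v", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- data.frame(excerpt_a = pairs[keep, 1], excerpt_b = pairs[keep, 2],
                      score = sample.int(max_score, sum(keep), replace = TRUE))
  similarity_network(nodes, edges, n_sorters = max_score)
}

# A random partition of n labelled items with every part of size >= 2.
random_partition_min2 <- function(n, K, seed) {
  set.seed(seed)
  stopifnot(n >= 2 * K)
  sizes <- rep(2L, K)
  extra <- n - 2L * K
  if (extra > 0) {
    add <- table(factor(sample.int(K, extra, replace = TRUE), levels = 1:K))
    sizes <- sizes + as.integer(add)
  }
  rep(seq_len(K), sizes)[sample.int(n)]
}
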