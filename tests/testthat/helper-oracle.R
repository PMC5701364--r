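# Independent oracles, deliberately naive: exhaustive simple-path
# enumeration for betweenness, pair concordance for the adjusted Rand
# index, full set-partition enumeration for modularity maxima. Only usable
# on small inputs.

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

# Betweenness of every node and edge by enumerating ALL simple paths
# between every unordered node pair and keeping the shortest ones; ties
# within relative tolerance share the count equally. Endpoints excluded
# from node scores; unreachable pairs contribute nothing.
oracle_betweenness <- function(net) {
  nodes <- net$nodes
  edges <- net$edges
  node_bt <- stats::setNames(numeric(length(nodes)), nodes)
  edge_bt <- stats::setNames(numeric(nrow(edges)),
                             edge_key(edges$excerpt_a, edges$excerpt_b))
  nbrs <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$excerpt_a[i]; b <- edges$excerpt_b[i]; d <- edges$distance[i]
    nbrs[[a]] <- rbind(nbrs[[a]], data.frame(to = b, d = d))
    nbrs[[b]] <- rbind(nbrs[[b]], data.frame(to = a, d = d))
  }
  all_paths <- function(s, t) {
    res <- list()
    dfs <- function(cur, visited, len) {
      if (cur == t) {
        res[[length(res) + 1L]] <<- list(len = len, nodes = visited)
        return()
      }
      nb <- nbrs[[cur]]
      if (is.null(nb)) return()
      for (i in seq_len(nrow(nb))) {
        v <- nb$to[i]
        if (!v %in% visited) dfs(v, c(visited, v), len + nb$d[i])
      }
    }
    dfs(s, s, 0)
    res
  }
  nn <- length(nodes)
  for (i in seq_len(nn - 1)) {
    for (j in (i + 1):nn) {
      ps <- all_paths(nodes[i], nodes[j])
      if (length(ps) == 0) next
      lens <- vapply(ps, `[[`, numeric(1), "len")
      dmin <- min(lens)
      sel <- which(lens <= dmin + 1e-9 * max(1, dmin))
      w <- 1 / length(sel)
      for (k in sel) {
        pn <- ps[[k]]$nodes
        if (length(pn) > 2) {
          mid <- pn[-c(1, length(pn))]
          node_bt[mid] <- node_bt[mid] + w
        }
        ek <- edge_key(pn[-length(pn)], pn[-1])
        edge_bt[ek] <- edge_bt[ek] + w
      }
    }
  }
  list(node = node_bt, edge = edge_bt)
}

# Adjusted Rand index from raw pair concordance counts.
oracle_ari <- function(x, y) {
  stopifnot(length(x) == length(y))
  a <- b <- cc <- d <- 0
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sx <- x[i] == x[j]
      sy <- y[i] == y[j]
      if (sx && sy) a <- a + 1
      else if (sx) b <- b + 1
      else if (sy) cc <- cc + 1
      else d <- d + 1
    }
  }
  den <- (a + b) * (b + d) + (a + cc) * (cc + d)
  if (den == 0) return(1)  # both partitions degenerate and identical in pattern
  2 * (a * d - b * cc) / den
}

# All set partitions of a vector of labels (Bell-number enumeration).
enum_partitions <- function(els) {
  if (length(els) == 1) return(list(list(els)))
  rest <- enum_partitions(els[-1])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(els[1], q[[i]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(els[1]), p)
  }
  out
}

# Convert a list-of-parts partition to a named membership vector.
parts_to_membership <- function(parts) {
  stats::setNames(rep(seq_along(parts), lengths(parts)),
                  unlist(parts, use.names = FALSE))
}
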