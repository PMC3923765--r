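# Independent oracles, deliberately naive: exhaustive enumeration and
# queue-based search, used to check the package's algorithmic paths.

# all loopless paths source -> target by depth-first enumeration
enumerate_simple_paths <- function(edges, source, target) {
  out <- list()
  recurse <- function(path, weight) {
    u <- path[length(path)]
    if (u == target) {
      out[[length(out) + 1]] <<- list(path = path, weight = weight)
      return(invisible(NULL))
    }
    nxt <- which(edges$source == u & !(edges$target %in% path))
    for (j in nxt) recurse(c(path, edges$target[j]), weight + edges$weight[j])
  }
  recurse(source, 0)
  if (length(out) == 0) return(out)
  key <- vapply(out, function(p) paste(p$path, collapse = "\r"), "")
  out[order(vapply(out, `[[`, 0, "weight"),
            vapply(out, function(p) length(p$path), 0L), key)]
}

# plain queue BFS hop distances (directed)
bfs_oracle <- function(edges, source, nodes) {
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[source] <- 0
  queue <- source
  while (length(queue) > 0) {
    u <- queue[1]; queue <- queue[-1]
    nb <- edges$target[edges$source == u]
    for (v in nb) if (!is.finite(dist[v])) {
      dist[v] <- dist[u] + 1
      queue <- c(queue, v)
    }
  }
  d <- dist[is.finite(dist)]
  d[order(names(d))]
}

# minimum crossings of a 2-layer bipartite drawing over all orderings
min_crossings_2layer <- function(top, bottom, edges) {
  count <- function(ord_t, ord_b) {
    pt <- stats::setNames(seq_along(ord_t), ord_t)
    pb <- stats::setNames(seq_along(ord_b), ord_b)
    tot <- 0L
    if (nrow(edges) < 2) return(0L)
    for (i in seq_len(nrow(edges) - 1)) for (j in (i + 1):nrow(edges)) {
      tot <- tot + as.integer(
        (pt[edges$source[i]] - pt[edges$source[j]]) *
          (pb[edges$target[i]] - pb[edges$target[j]]) < 0)
    }
    tot
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- Inf
  for (ot in perms(top)) for (ob in perms(bottom))
    best <- min(best, count(ot, ob))
  best
}

# crossings of a computed layered drawing, counted from coordinates
count_crossings_from_layout <- function(lay, edges) {
  pos <- stats::setNames(lay$nodes$x, lay$nodes$id)
  yy <- stats::setNames(lay$nodes$y, lay$nodes$id)
  tot <- 0L
  if (nrow(edges) < 2) return(0L)
  for (i in seq_len(nrow(edges) - 1)) for (j in (i + 1):nrow(edges)) {
    if (yy[edges$source[i]] != yy[edges$source[j]]) next
    tot <- tot + as.integer(
      (pos[edges$source[i]] - pos[edges$source[j]]) *
        (pos[edges$target[i]] - pos[edges$target[j]]) < 0)
  }
  tot
}
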