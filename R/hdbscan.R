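# Hierarchical density-based clustering (HDBSCAN) on a precomputed
# distance matrix: core distances -> mutual-reachability distances ->
# single-linkage hierarchy -> condensed tree (minimum cluster size) ->
# excess-of-mass cluster selection. Self-contained implementation of the
# published algorithm; no installed R package provides it.

hdbscan_labels <- function(D, min_cluster_size = 5, min_samples = 5) {
  n <- nrow(D)
  min_cluster_size <- max(2L, as.integer(min_cluster_size))
  if (n < min_cluster_size || n < 2L) return(rep(-1L, n))
  k <- min(as.integer(min_samples), n)

  # core distance: k-th smallest distance including the point itself
  core <- vapply(seq_len(n), function(i) sort(D[i, ])[k], numeric(1))
  MR <- pmax(D, outer(core, core, pmax))
  hc <- hclust(as.dist(MR), method = "single")

  # members of each internal node of the dendrogram
  members <- vector("list", n - 1L)
  get_members <- function(m) if (m < 0) -m else members[[m]]
  for (i in seq_len(n - 1L)) {
    members[[i]] <- c(get_members(hc$merge[i, 1]),
                      get_members(hc$merge[i, 2]))
  }
  node_size <- function(m) if (m < 0) 1L else length(members[[m]])
  lam <- function(h) 1 / max(h, 1e-10)

  # condensed tree: clusters[[id]] = list(parent, birth, points, lambdas,
  # children)
  clusters <- list(list(parent = 0L, birth = 0, points = integer(0),
                        lambdas = numeric(0), children = integer(0)))
  # iterative traversal: stack of (dendrogram node, condensed cluster id)
  stack <- list(list(node = n - 1L, cid = 1L))
  while (length(stack) > 0L) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- fr$node; cid <- fr$cid
    l <- hc$merge[node, 1]; r <- hc$merge[node, 2]
    lv <- lam(hc$height[node])
    szl <- node_size(l); szr <- node_size(r)
    if (szl >= min_cluster_size && szr >= min_cluster_size) {
      for (ch in list(l, r)) {
        clusters[[length(clusters) + 1L]] <-
          list(parent = cid, birth = lv, points = integer(0),
               lambdas = numeric(0), children = integer(0))
        nid <- length(clusters)
        clusters[[cid]]$children <- c(clusters[[cid]]$children, nid)
        stack[[length(stack) + 1L]] <- list(node = ch, cid = nid)
      }
    } else {
      for (ch in list(l, r)) {
        if (node_size(ch) < min_cluster_size) {
          pts <- get_members(ch)
          clusters[[cid]]$points <- c(clusters[[cid]]$points, pts)
          clusters[[cid]]$lambdas <- c(clusters[[cid]]$lambdas,
                                       rep(lv, length(pts)))
        } else {
          stack[[length(stack) + 1L]] <- list(node = ch, cid = cid)
        }
      }
    }
  }

  ncl <- length(clusters)
  # all points in the subtree of each cluster
  subtree_points <- vector("list", ncl)
  for (id in ncl:1) {
    pts <- clusters[[id]]$points
    for (ch in clusters[[id]]$children)
      pts <- c(pts, subtree_points[[ch]])
    subtree_points[[id]] <- pts
  }

  if (ncl == 1L) {
    # no viable split anywhere: one homogeneous cluster
    return(rep(1L, n))
  }

  # stability: points leave at their fall-out lambda; child clusters leave
  # at their birth lambda
  stability <- numeric(ncl)
  for (id in seq_len(ncl)) {
    cl <- clusters[[id]]
    s <- sum(cl$lambdas - cl$birth)
    for (ch in cl$children) {
      s <- s + length(subtree_points[[ch]]) *
        (clusters[[ch]]$birth - cl$birth)
    }
    stability[id] <- s
  }

  # excess-of-mass selection, children before parents; root never selected
  selected <- logical(ncl)
  subtree_stab <- numeric(ncl)
  deselect_subtree <- function(id) {
    for (ch in clusters[[id]]$children) {
      selected[ch] <<- FALSE
      deselect_subtree(ch)
    }
  }
  for (id in ncl:2) {
    ch <- clusters[[id]]$children
    if (length(ch) == 0L) {
      selected[id] <- TRUE
      subtree_stab[id] <- stability[id]
    } else {
      s_ch <- sum(subtree_stab[ch])
      if (stability[id] >= s_ch) {
        selected[id] <- TRUE
        deselect_subtree(id)
        subtree_stab[id] <- stability[id]
      } else {
        subtree_stab[id] <- s_ch
      }
    }
  }

  labels <- rep(-1L, n)
  sel <- which(selected)
  # deterministic label order by smallest member index
  sel <- sel[order(vapply(sel, function(id) min(subtree_points[[id]]),
                          numeric(1)))]
  for (q in seq_along(sel)) labels[subtree_points[[sel[q]]]] <- q
  labels
}
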