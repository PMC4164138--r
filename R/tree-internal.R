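# Internal rooted-binary tree toolkit backing the parsimony engine.
#
# A tree is a list with two parallel integer vectors indexed by node id:
#   parent : parent node id, 0 at the root
#   tiprow : for tip nodes, the row of the character-state matrix (and of the
#            taxon label vector); 0 for internal nodes
# The rooted representation stands in for an unrooted binary tree; the two
# edges incident to the root jointly represent a single unrooted branch, and
# all scores are rooting-invariant.

tx_root <- function(tr) which(tr$parent == 0L)

tx_init2 <- function(t1, t2) {
  list(parent = c(3L, 3L, 0L), tiprow = c(t1, t2, 0L))
}

tx_init3 <- function(t1, t2, t3) {
  list(parent = c(5L, 4L, 4L, 5L, 0L), tiprow = c(t1, t2, t3, 0L, 0L))
}

tx_ntip <- function(tr) sum(tr$tiprow > 0L)

# children lists indexed by node id
tx_children_vec <- function(tr) {
  m <- length(tr$parent)
  idx <- which(tr$parent > 0L)
  unname(split(idx, factor(tr$parent[idx], levels = seq_len(m))))
}

# edges identified by their child node; with dedup, one of the two root
# edges is dropped so each unrooted branch appears exactly once
tx_edges <- function(tr, dedup = TRUE) {
  e <- which(tr$parent > 0L)
  if (dedup) {
    rc <- which(tr$parent == tx_root(tr))
    if (length(rc) == 2L) e <- setdiff(e, rc[2L])
  }
  e
}

# insert a new tip (state row `taxon`) on the edge above `edge_child`;
# edge_child may be the root, which grafts above the old root
tx_insert <- function(tr, edge_child, taxon) {
  m <- length(tr$parent)
  w <- m + 1L
  t <- m + 2L
  parent <- c(tr$parent, 0L, 0L)
  parent[w] <- parent[edge_child]
  parent[edge_child] <- w
  parent[t] <- w
  list(parent = parent, tiprow = c(tr$tiprow, 0L, taxon))
}

# all node ids inside the clade rooted at v
tx_subtree_nodes <- function(tr, v, ch = tx_children_vec(tr)) {
  acc <- v
  front <- v
  while (length(front)) {
    front <- unlist(ch[front], use.names = FALSE)
    acc <- c(acc, front)
  }
  acc
}

tx_score <- function(tr, states, kind) {
  if (kind == "ordered") {
    wagner_length_cpp(tr$parent, tr$tiprow, states)
  } else {
    fitch_length_cpp(tr$parent, tr$tiprow, states)
  }
}

# nearest-neighbour interchange: parent vectors of every distinct unrooted
# NNI neighbour (two per internal branch)
tx_nni <- function(tr) {
  res <- vector("list", 0L)
  ch <- tx_children_vec(tr)
  root <- tx_root(tr)
  for (v in which(tr$tiprow == 0L)) {
    u <- tr$parent[v]
    if (u == 0L || u == root) next
    sib <- setdiff(ch[[u]], v)
    a <- ch[[v]][1L]
    b <- ch[[v]][2L]
    p1 <- tr$parent; p1[sib] <- v; p1[a] <- u
    p2 <- tr$parent; p2[sib] <- v; p2[b] <- u
    res[[length(res) + 1L]] <- p1
    res[[length(res) + 1L]] <- p2
  }
  # the branch hidden by the root: both root children internal
  rc <- ch[[root]]
  if (length(rc) == 2L && all(tr$tiprow[rc] == 0L)) {
    L <- rc[1L]; R <- rc[2L]
    c1 <- ch[[L]][1L]
    a <- ch[[R]][1L]
    b <- ch[[R]][2L]
    p1 <- tr$parent; p1[c1] <- R; p1[a] <- L
    p2 <- tr$parent; p2[c1] <- R; p2[b] <- L
    res[[length(res) + 1L]] <- p1
    res[[length(res) + 1L]] <- p2
  }
  res
}

# subtree prune and regraft: parent vectors of all SPR rearrangements
tx_spr <- function(tr) {
  res <- vector("list", 0L)
  root <- tx_root(tr)
  ch <- tx_children_vec(tr)
  for (v in seq_along(tr$parent)) {
    u <- tr$parent[v]
    if (u == 0L) next
    sib <- setdiff(ch[[u]], v)
    g <- tr$parent[u]
    base <- tr$parent
    if (g == 0L) base[sib] <- 0L else base[sib] <- g
    base[u] <- NA_integer_
    base[v] <- NA_integer_
    sub <- tx_subtree_nodes(tr, v, ch)
    avail <- which(!is.na(base) & base > 0L)
    avail <- setdiff(avail, sub)
    avail <- setdiff(avail, sib)          # restores the original tree
    newroot <- if (g == 0L) sib else root
    rc <- which(base[avail] == newroot)
    if (length(rc) == 2L) avail <- avail[-rc[2L]]   # unrooted duplicate
    for (w in avail) {
      p <- base
      p[u] <- p[w]
      p[w] <- u
      p[v] <- u
      res[[length(res) + 1L]] <- p
    }
  }
  res
}

# greedy stepwise addition in the given taxon order
tx_stepwise_addition <- function(order, states, kind) {
  n <- length(order)
  if (n < 3L) stop_("stepwise addition needs at least 3 taxa")
  tr <- tx_init3(order[1L], order[2L], order[3L])
  if (n == 3L) return(tr)
  for (k in 4:n) {
    best <- NULL
    bestlen <- Inf
    for (e in tx_edges(tr)) {
      cand <- tx_insert(tr, e, order[k])
      len <- tx_score(cand, states, kind)
      if (len < bestlen) {
        bestlen <- len
        best <- cand
      }
    }
    tr <- best
  }
  tr
}

# first-improvement hill climbing: NNI to a local optimum, then (optionally)
# SPR sweeps, returning to NNI after each improving SPR move
tx_hillclimb <- function(tr, states, kind, spr = TRUE) {
  len <- tx_score(tr, states, kind)
  nni_opt <- function() {
    repeat {
      moved <- FALSE
      for (p in tx_nni(tr)) {
        cand <- list(parent = p, tiprow = tr$tiprow)
        l <- tx_score(cand, states, kind)
        if (l < len) {
          tr <<- cand; len <<- l; moved <- TRUE
          break
        }
      }
      if (!moved) break
    }
  }
  nni_opt()
  if (spr) {
    repeat {
      moved <- FALSE
      for (p in tx_spr(tr)) {
        cand <- list(parent = p, tiprow = tr$tiprow)
        l <- tx_score(cand, states, kind)
        if (l < len) {
          tr <- cand; len <- l; moved <- TRUE
          break
        }
      }
      if (!moved) break
      nni_opt()
    }
  }
  list(tree = tr, length = len)
}

# canonical Newick string of the unrooted topology: re-rooted on the pendant
# edge of the lexicographically smallest taxon label, children sorted by
# their smallest descendant label; used for deduplication and tie-breaking
tx_canonical_newick <- function(tr, labels) {
  m <- length(tr$parent)
  adj <- vector("list", m)
  for (i in seq_len(m)) {
    p <- tr$parent[i]
    if (p > 0L) {
      adj[[i]] <- c(adj[[i]], p)
      adj[[p]] <- c(adj[[p]], i)
    }
  }
  root <- tx_root(tr)
  if (length(adj[[root]]) == 2L) {      # splice the root out of the cycle
    rc <- adj[[root]]
    adj[[rc[1L]]] <- c(setdiff(adj[[rc[1L]]], root), rc[2L])
    adj[[rc[2L]]] <- c(setdiff(adj[[rc[2L]]], root), rc[1L])
    adj[[root]] <- integer(0)
  }
  tips <- which(tr$tiprow > 0L)
  tlab <- labels[tr$tiprow[tips]]
  anchor <- tips[order(tlab)[1L]]
  desc <- function(node, from) {
    nb <- setdiff(adj[[node]], from)
    if (!length(nb)) {
      lab <- labels[tr$tiprow[node]]
      return(list(key = lab, str = lab))
    }
    parts <- lapply(nb, desc, from = node)
    keys <- vapply(parts, `[[`, "", "key")
    o <- order(keys)
    list(key = keys[o][1L],
         str = paste0("(", paste(vapply(parts[o], `[[`, "", "str"),
                                 collapse = ","), ")"))
  }
  inner <- desc(adj[[anchor]][1L], anchor)
  paste0("(", labels[tr$tiprow[anchor]], ",", inner$str, ");")
}

# conversions between the internal representation and ape's "phylo"

tx_to_phylo <- function(tr, labels) {
  tips <- which(tr$tiprow > 0L)
  ints <- which(tr$tiprow == 0L)
  ntip <- length(tips)
  root <- tx_root(tr)
  id <- integer(length(tr$parent))
  id[tips] <- seq_len(ntip)
  id[root] <- ntip + 1L
  rest <- setdiff(ints, root)
  id[rest] <- ntip + 1L + seq_along(rest)
  child <- which(tr$parent > 0L)
  phy <- structure(list(edge = cbind(id[tr$parent[child]], id[child]),
                        tip.label = labels[tr$tiprow[tips]],
                        Nnode = length(ints)),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

phylo_to_tx <- function(phy, taxa) {
  ntip <- length(phy$tip.label)
  m <- ntip + phy$Nnode
  parent <- integer(m)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  rows <- match(phy$tip.label, taxa)
  if (anyNA(rows)) stop_("tree tip labels do not match the matrix taxa")
  tiprow <- integer(m)
  tiprow[seq_len(ntip)] <- rows
  list(parent = parent, tiprow = tiprow)
}

# force a binary rooted representation (resolving a basal trifurcation from
# an unrooted ape tree); scores are unaffected
tx_binarize <- function(tr) {
  repeat {
    ch <- tx_children_vec(tr)
    bad <- which(lengths(ch) > 2L)
    if (!length(bad)) return(tr)
    v <- bad[1L]
    kids <- ch[[v]]
    w <- length(tr$parent) + 1L
    tr$parent <- c(tr$parent, v)
    tr$tiprow <- c(tr$tiprow, 0L)
    tr$parent[kids[-1L]] <- w
  }
}
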