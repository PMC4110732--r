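## Parsimony haplotype network as the union of all minimum spanning trees
## (a minimum spanning network, MSN) of the complete Hamming-distance graph
## over observed haplotypes.
##
## Where the MST is unique the MSN is a tree; ties among equally parsimonious
## connections appear as loops (reticulations). No median vectors (inferred
## Steiner haplotypes) are created: edges of length d > 1 are merely
## subdivided by d-1 degree-2 latent placeholders for display/export.

#' Hamming distance between two variant sets
#'
#' Size of the symmetric difference of two sets of variant labels.
#'
#' @param set_a,set_b Character vectors of variant labels.
#' @return Non-negative integer.
#' @export
hamming_distance <- function(set_a, set_b) {
  length(setdiff(set_a, set_b)) + length(setdiff(set_b, set_a))
}

## Pairwise Hamming distance matrix from a named list of label sets,
## via a binary haplotype x variant incidence matrix.
hamming_matrix <- function(variant_sets) {
  ids <- names(variant_sets)
  labs <- unique(unlist(variant_sets, use.names = FALSE))
  if (length(labs) == 0L) {
    d <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
    return(d)
  }
  M <- matrix(0L, nrow = length(ids), ncol = length(labs),
              dimnames = list(ids, labs))
  for (i in seq_along(ids)) M[i, variant_sets[[i]]] <- 1L
  S <- tcrossprod(M)
  r <- diag(S)
  d <- outer(r, r, "+") - 2L * S
  storage.mode(d) <- "integer"
  dimnames(d) <- list(ids, ids)
  d
}

## Minimal union-find.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]   # path halving
    i <- parent[i]
  }
  i
}

#' Build the haplotype network
#'
#' Constructs the union of all minimum spanning trees of the complete
#' Hamming-distance graph over the observed haplotypes. An edge of weight w
#' belongs to some MST exactly when its endpoints lie in different connected
#' components of the graph restricted to edges of weight < w; processing
#' weight levels in increasing order with a union-find yields all such edges
#' with no arbitrary tie-breaking.
#'
#' @param haplotypes A `"haplotype_table"` with at least 2 haplotypes.
#' @return An object of class `"haplotype_network"`: list with `nodes`
#'   (data frame `haplotype_id`, `n_total`), `edges` (data frame `from`,
#'   `to`, `length`), `edge_variants` (list of label vectors, the symmetric
#'   difference along each edge), `mst_weight`, `n_cycles` (dimension of the
#'   cycle space; 0 for a tree), `n_latent` (latent placeholder count) and
#'   the originating haplotype table.
#' @export
build_haplotype_network <- function(haplotypes) {
  stopifnot(inherits(haplotypes, "haplotype_table"))
  ids <- haplotypes$tab$haplotype_id
  h <- length(ids)
  if (h < 2L) stop("need at least 2 haplotypes to build a network")

  D <- hamming_matrix(haplotypes$variants[ids])
  if (any(D[upper.tri(D)] == 0L)) {
    stop("distinct haplotypes at Hamming distance 0; variant sets must be unique")
  }

  ## all-MST edge rule, by increasing weight level
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[pairs]
  ord <- order(w)
  pairs <- pairs[ord, , drop = FALSE]
  w <- w[ord]

  parent <- uf_new(h)
  keep <- logical(length(w))
  lev_start <- 1L
  mst_weight <- 0L
  n_components <- h
  for (lev in unique(w)) {
    idx <- which(w == lev)
    roots_a <- vapply(pairs[idx, 1], function(i) uf_find(parent, i), integer(1))
    roots_b <- vapply(pairs[idx, 2], function(i) uf_find(parent, i), integer(1))
    sel <- roots_a != roots_b
    keep[idx[sel]] <- TRUE
    ## merge after selecting the whole level (ties all retained)
    for (k in idx[sel]) {
      ra <- uf_find(parent, pairs[k, 1])
      rb <- uf_find(parent, pairs[k, 2])
      if (ra != rb) {
        parent[ra] <- rb
        mst_weight <- mst_weight + lev
        n_components <- n_components - 1L
      }
    }
    if (n_components == 1L) break  # higher levels cannot contribute MST edges
  }
  if (n_components != 1L) stop("internal error: Hamming graph not connected")

  e_from <- ids[pairs[keep, 1]]
  e_to <- ids[pairs[keep, 2]]
  e_len <- w[keep]
  edges <- data.frame(from = e_from, to = e_to, length = e_len,
                      stringsAsFactors = FALSE)
  ## canonical edge order: by length, then endpoint ids
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  edge_variants <- lapply(seq_len(nrow(edges)), function(i) {
    a <- haplotypes$variants[[edges$from[i]]]
    b <- haplotypes$variants[[edges$to[i]]]
    sort(c(setdiff(a, b), setdiff(b, a)))
  })

  structure(
    list(nodes = data.frame(haplotype_id = ids,
                            n_total = haplotypes$tab$n_total,
                            stringsAsFactors = FALSE),
         edges = edges,
         edge_variants = edge_variants,
         mst_weight = mst_weight,
         n_cycles = nrow(edges) - h + 1L,
         n_latent = sum(pmax(edges$length - 1L, 0L)),
         haplotypes = haplotypes),
    class = "haplotype_network"
  )
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("Haplotype network: ", nrow(x$nodes), " observed haplotypes, ",
      nrow(x$edges), " edges (", x$n_latent, " latent placeholders), ",
      x$n_cycles, " loop(s), MST weight ", x$mst_weight, "\n", sep = "")
  invisible(x)
}

net_igraph <- function(net, edge_idx = seq_len(nrow(net$edges))) {
  igraph::graph_from_data_frame(
    net$edges[edge_idx, c("from", "to"), drop = FALSE],
    directed = FALSE,
    vertices = net$nodes$haplotype_id)
}

#' Enumerate loop resolutions of a network
#'
#' Every reticulation (loop) marks a set of equally parsimonious
#' connections. A resolution is a spanning tree of the network obtained by
#' deleting one edge from each independent cycle; because the network is the
#' union of all minimum spanning trees, valid resolutions are exactly the
#' spanning trees of total weight equal to the MST weight. A loop-free
#' network has itself as the single resolution.
#'
#' @param net A `"haplotype_network"`.
#' @param max_resolutions Cap on the number of resolutions (default 64); if
#'   the count exceeds the cap an error naming the count is raised.
#' @return A list of integer vectors, each giving the retained edge indices
#'   (rows of `net$edges`) of one resolution.
#' @export
enumerate_resolutions <- function(net, max_resolutions = 64L) {
  stopifnot(inherits(net, "haplotype_network"))
  m <- nrow(net$edges)
  k <- net$n_cycles
  if (k == 0L) return(list(seq_len(m)))

  g <- net_igraph(net)
  br <- as.integer(igraph::bridges(g))
  candidates <- setdiff(seq_len(m), br)
  n_comb <- choose(length(candidates), k)
  if (n_comb > 2e5) {
    stop("loop structure too complex to enumerate (",
         format(n_comb, big.mark = ","), " candidate edge subsets)")
  }
  combos <- utils::combn(candidates, k)
  total_w <- sum(net$edges$length)
  res <- list()
  for (j in seq_len(ncol(combos))) {
    drop_idx <- combos[, j]
    if (total_w - sum(net$edges$length[drop_idx]) != net$mst_weight) next
    keep_idx <- setdiff(seq_len(m), drop_idx)
    sub <- net_igraph(net, keep_idx)
    if (igraph::is_connected(sub)) res[[length(res) + 1L]] <- keep_idx
  }
  if (length(res) > max_resolutions) {
    stop("network has ", length(res), " loop resolutions, exceeding ",
         "max_resolutions = ", max_resolutions)
  }
  res
}

#' Enumerate branches of a loop resolution
#'
#' A branch is an edge between observed haplotypes in a spanning tree of the
#' network (latent placeholders are interior to a branch, so a branch can be
#' defined by more than one variant). Cutting a branch bipartitions the
#' observed haplotypes into the clade (`side_a`, the subtree away from the
#' root) and the remainder (`side_b`). Branch ids are deterministic: the
#' tree is rooted at the haplotype with the largest total membership (ties
#' broken by lexicographic haplotype id) and edges are numbered in
#' breadth-first discovery order.
#'
#' @param net A `"haplotype_network"`.
#' @param resolution Integer vector of retained edge indices (one element of
#'   [enumerate_resolutions()]); defaults to the full network, which must
#'   then be loop-free.
#' @param resolution_id Identifier stored with each branch.
#' @return A data frame with one row per branch: `branch_id`,
#'   `resolution_id`, `from` (parent-side haplotype), `to` (clade-side
#'   haplotype), `n_variants`, plus list columns `variants` (defining
#'   variant labels) and `clade` (haplotype ids of `side_a`), and
#'   `n_clade`.
#' @export
enumerate_branches <- function(net, resolution = NULL, resolution_id = 1L) {
  stopifnot(inherits(net, "haplotype_network"))
  if (is.null(resolution)) resolution <- seq_len(nrow(net$edges))
  ids <- net$nodes$haplotype_id
  h <- length(ids)
  if (length(resolution) != h - 1L) {
    stop("input has loops: a resolution must have exactly ",
         h - 1L, " edges, got ", length(resolution))
  }
  edges <- net$edges[resolution, , drop = FALSE]

  ## adjacency
  adj <- stats::setNames(vector("list", h), ids)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$from[i]]] <- c(adj[[edges$from[i]]], i)
    adj[[edges$to[i]]] <- c(adj[[edges$to[i]]], i)
  }

  root <- ids[order(-net$nodes$n_total, ids)][1]

  ## BFS, recording parent edge and children
  parent_edge <- stats::setNames(rep(NA_integer_, h), ids)
  parent_node <- stats::setNames(rep(NA_character_, h), ids)
  visited <- stats::setNames(logical(h), ids)
  order_visited <- character(0)
  queue <- root
  visited[root] <- TRUE
  branch_order <- integer(0)     # edge indices (within `edges`) in BFS order
  while (length(queue)) {
    node <- queue[1]; queue <- queue[-1]
    order_visited <- c(order_visited, node)
    ## deterministic neighbour order: by neighbour id
    inc <- adj[[node]]
    nbrs <- ifelse(edges$from[inc] == node, edges$to[inc], edges$from[inc])
    o <- order(nbrs)
    for (k in o) {
      e <- inc[k]; nb <- nbrs[k]
      if (!visited[nb]) {
        visited[nb] <- TRUE
        parent_edge[nb] <- e
        parent_node[nb] <- node
        branch_order <- c(branch_order, e)
        queue <- c(queue, nb)
      }
    }
  }
  if (!all(visited)) stop("resolution is not connected")

  ## clade membership: accumulate subtrees bottom-up (reverse BFS order)
  clade <- stats::setNames(vector("list", h), ids)
  for (node in rev(order_visited)) {
    clade[[node]] <- c(clade[[node]], node)
    p <- parent_node[node]
    if (!is.na(p)) clade[[p]] <- c(clade[[p]], clade[[node]])
  }

  n_branch <- length(branch_order)
  child_of_edge <- stats::setNames(names(parent_edge)[!is.na(parent_edge)],
                                   parent_edge[!is.na(parent_edge)])
  out <- data.frame(branch_id = seq_len(n_branch),
                    resolution_id = resolution_id,
                    from = character(n_branch), to = character(n_branch),
                    n_variants = integer(n_branch),
                    n_clade = integer(n_branch),
                    stringsAsFactors = FALSE)
  out$variants <- vector("list", n_branch)
  out$clade <- vector("list", n_branch)
  for (b in seq_len(n_branch)) {
    e <- branch_order[b]
    child <- child_of_edge[[as.character(e)]]
    out$from[b] <- parent_node[child]
    out$to[b] <- child
    ev <- net$edge_variants[[resolution[e]]]
    out$variants[[b]] <- ev
    out$n_variants[b] <- length(ev)
    out$clade[[b]] <- sort(clade[[child]])
    out$n_clade[b] <- length(clade[[child]])
  }
  out
}

#' Export a network to GraphML
#'
#' Materialises latent degree-2 placeholder nodes so that every drawn edge
#' segment corresponds to a single variant, then writes GraphML via igraph.
#' Node attributes: `count` (membership; 0 for latent nodes) and `observed`;
#' edge attribute: `variant` label.
#'
#' @param net A `"haplotype_network"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
network_to_graphml <- function(net, path) {
  seg <- expand_segments(net)
  g <- igraph::graph_from_data_frame(seg$edges, directed = FALSE,
                                     vertices = seg$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

## One node per observed haplotype plus d-1 latent placeholders per edge of
## length d; one segment per variant along the edge (sorted label order).
expand_segments <- function(net) {
  nodes <- data.frame(name = net$nodes$haplotype_id,
                      count = net$nodes$n_total,
                      observed = TRUE, stringsAsFactors = FALSE)
  e_from <- character(0); e_to <- character(0); e_var <- character(0)
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$from[i]; b <- net$edges$to[i]
    vars <- net$edge_variants[[i]]
    d <- length(vars)
    chain <- c(a, if (d > 1) sprintf("latent_%d_%d", i, seq_len(d - 1L)), b)
    if (d > 1) {
      nodes <- rbind(nodes, data.frame(
        name = sprintf("latent_%d_%d", i, seq_len(d - 1L)),
        count = 0L, observed = FALSE, stringsAsFactors = FALSE))
    }
    e_from <- c(e_from, chain[-length(chain)])
    e_to <- c(e_to, chain[-1])
    e_var <- c(e_var, vars)
  }
  list(nodes = nodes,
       edges = data.frame(from = e_from, to = e_to, variant = e_var,
                          stringsAsFactors = FALSE))
}

#' Export a network to a JSON edge list
#'
#' @param net A `"haplotype_network"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
network_to_json <- function(net, path) {
  seg <- expand_segments(net)
  jsonlite::write_json(
    list(nodes = seg$nodes, edges = seg$edges,
         mst_weight = net$mst_weight, n_cycles = net$n_cycles),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a branch table to TSV
#'
#' @param branches Branch data frame from [enumerate_branches()] (or several
#'   row-bound resolutions).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_branch_table <- function(branches, path) {
  tab <- branches[, c("branch_id", "resolution_id", "from", "to",
                      "n_variants", "n_clade")]
  tab$variants <- vapply(branches$variants, paste, character(1), collapse = ",")
  tab$clade <- vapply(branches$clade, paste, character(1), collapse = ",")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
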