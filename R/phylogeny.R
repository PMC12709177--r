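#' Phylogeny configuration
#'
#' @param bootstrap_replicates Non-negative integer (default 1000).
#' @param distance_model `"poisson"` (default) or `"p"`.
#' @param clade_min_size Minimum leaves for a reported major clade
#'   (default 5).
#' @param clade_tightness Fraction `alpha` in `(0, 1)`: a subtree is a major
#'   clade when its mean pairwise leaf path length is at most `alpha` times
#'   the whole-tree mean (default 0.5).
#' @return A `phylo_config` object.
#' @export
phylo_config <- function(bootstrap_replicates = 1000L,
                         distance_model = "poisson",
                         clade_min_size = 5L, clade_tightness = 0.5) {
  abort_if(bootstrap_replicates < 0, "bootstrap_replicates must be >= 0",
           class = "nrnbkit_validation_error")
  abort_if(clade_tightness <= 0 || clade_tightness >= 1,
           "clade_tightness must be in (0, 1)",
           class = "nrnbkit_validation_error")
  abort_if(!distance_model %in% c("p", "poisson"),
           "distance_model must be 'p' or 'poisson'",
           class = "nrnbkit_validation_error")
  structure(list(bootstrap_replicates = as.integer(bootstrap_replicates),
                 distance_model = distance_model,
                 clade_min_size = as.integer(clade_min_size),
                 clade_tightness = clade_tightness),
            class = "phylo_config")
}

# saturation guard for the Poisson correction: p is capped so distances
# stay finite; cap chosen so d_max = -ln(1e-3) ~ 6.91
POISSON_P_CAP <- 1 - 1e-3

#' Evolutionary distance matrix from an alignment
#'
#' Per pair, `p` = mismatches over columns where both rows are non-gap
#' (pairwise deletion). Model `"p"` returns `p` itself; `"poisson"` applies
#' the Poisson correction `d = -ln(1 - p)` with saturated values clamped at
#' a finite ceiling.
#'
#' @param aln A `protein_alignment` with >= 2 rows.
#' @param model `"p"` or `"poisson"`.
#' @param on_incomparable `"error"` (default; a pair with zero comparable
#'   columns aborts, naming the pair) or `"max"` (assign the model ceiling;
#'   used internally by bootstrap resampling).
#' @return A `protein_distances` object (ids, symmetric matrix, model).
#' @export
distance_matrix <- function(aln, model = "poisson",
                            on_incomparable = c("error", "max")) {
  on_incomparable <- match.arg(on_incomparable)
  abort_if(!model %in% c("p", "poisson"), "unknown model: ", model,
           class = "nrnbkit_validation_error")
  n <- length(aln$row_ids)
  abort_if(n < 2L, "need >= 2 alignment rows",
           class = "nrnbkit_validation_error")
  m <- rows_to_matrix(aln$rows)
  nogap <- m != GAP_CHAR
  V <- matrix(0, n, n, dimnames = list(aln$row_ids, aln$row_ids))
  pmax_ <- if (model == "poisson") POISSON_P_CAP else 1
  dmax <- if (model == "poisson") -log(1 - POISSON_P_CAP) else 1
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      comp <- nogap[i, ] & nogap[j, ]
      nc <- sum(comp)
      if (nc == 0L) {
        abort_if(on_incomparable == "error",
                 "no comparable columns between '", aln$row_ids[i],
                 "' and '", aln$row_ids[j], "'",
                 class = "nrnbkit_validation_error")
        V[i, j] <- V[j, i] <- dmax
        next
      }
      p <- sum(m[i, comp] != m[j, comp]) / nc
      d <- if (model == "p") p else -log(1 - min(p, pmax_))
      V[i, j] <- V[j, i] <- d
    }
  }
  structure(list(ids = aln$row_ids, values = V, model = model),
            class = "protein_distances")
}

as_dist_values <- function(D) {
  if (inherits(D, "protein_distances")) D$values else as.matrix(D)
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration (Q criterion). Negative intermediate
#' branch lengths are clamped to zero.
#'
#' @param D A `protein_distances` object or a symmetric matrix with
#'   dimnames, >= 3 taxa.
#' @return An unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(D) {
  V <- as_dist_values(D)
  abort_if(nrow(V) < 3L, "neighbor joining needs >= 3 taxa",
           class = "nrnbkit_validation_error")
  tr <- ape::nj(V)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# adjacency list of an (un)rooted phylo: for each vertex, neighbor vertices
# and connecting edge lengths
phylo_adjacency <- function(tree) {
  nv <- length(tree$tip.label) + tree$Nnode
  adj <- vector("list", nv)
  el <- tree$edge.length %||% rep(1, nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, el[e]))
    adj[[b]] <- rbind(adj[[b]], c(a, el[e]))
  }
  adj
}

# build a rooted phylo by directing all edges away from `root_at`,
# where adj may contain an extra synthetic vertex (the new root).
# labels: character vector of tip labels (vertices 1..ntip);
# node_lab: old internal labels indexed by old vertex id (may be NULL).
rooted_from_adjacency <- function(adj, root_at, ntip, tip_labels, node_lab) {
  nv <- length(adj)
  parent <- rep(NA_integer_, nv); plen <- rep(NA_real_, nv)
  order_v <- integer(0)
  stack <- root_at
  visited <- rep(FALSE, nv)
  visited[root_at] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_v <- c(order_v, v)
    nb <- adj[[v]]
    if (is.null(nb)) next
    for (r in rev(seq_len(nrow(nb)))) {
      w <- nb[r, 1]
      if (!visited[w]) {
        visited[w] <- TRUE
        parent[w] <- v; plen[w] <- nb[r, 2]
        stack <- c(stack, w)
      }
    }
  }
  internals <- unique(c(root_at, order_v[order_v > ntip]))
  newid <- integer(nv)
  newid[seq_len(ntip)] <- seq_len(ntip)
  newid[internals] <- ntip + seq_along(internals)
  edges <- which(!is.na(parent))
  edge <- cbind(newid[parent[edges]], newid[edges])
  ord <- order(edge[, 1], edge[, 2])
  edge <- edge[ord, , drop = FALSE]
  elen <- plen[edges][ord]
  labs <- rep("", length(internals))
  if (!is.null(node_lab)) {
    for (i in seq_along(internals)) {
      v <- internals[i]
      if (v <= length(node_lab) && !is.na(node_lab[v])) labs[i] <- node_lab[v]
    }
  }
  tr <- list(edge = edge, edge.length = elen, Nnode = length(internals),
             tip.label = tip_labels)
  if (any(nzchar(labs))) tr$node.label <- labs
  class(tr) <- "phylo"
  tr <- ape::collapse.singles(ape::reorder.phylo(tr, "cladewise"))
  ape::reorder.phylo(tr, "cladewise")
}

#' Midpoint rooting
#'
#' Roots an unrooted tree at the midpoint of the longest leaf-to-leaf path
#' (path length = sum of branch lengths). If the midpoint falls exactly on
#' a node the tree is rooted at that node (no zero-length extra edge). Ties
#' between equally longest paths are broken by lexicographic leaf-pair
#' order. If all branch lengths are zero the tree is rooted at the first
#' internal node, with a warning.
#'
#' @param tree An [ape::phylo] with >= 2 leaves.
#' @return A rooted [ape::phylo].
#' @export
midpoint_root <- function(tree) {
  ntip <- length(tree$tip.label)
  abort_if(ntip < 2L, "midpoint rooting needs >= 2 leaves",
           class = "nrnbkit_validation_error")
  node_lab <- NULL
  if (!is.null(tree$node.label)) {
    node_lab <- rep(NA_character_, ntip + tree$Nnode)
    node_lab[ntip + seq_len(tree$Nnode)] <- tree$node.label
  }
  Dn <- ape::dist.nodes(tree)
  Dl <- Dn[seq_len(ntip), seq_len(ntip), drop = FALSE]
  maxd <- max(Dl)
  if (maxd <= 0) {
    warning("all branch lengths are zero; rooting at the first internal node")
    adj <- phylo_adjacency(tree)
    return(rooted_from_adjacency(adj, ntip + 1L, ntip, tree$tip.label,
                                 node_lab))
  }
  cand <- which(Dl >= maxd - 1e-12 & upper.tri(Dl), arr.ind = TRUE)
  pair_lab <- matrix(apply(cand, 1, function(ix) sort(tree$tip.label[ix])),
                     nrow = 2)
  pick <- order(pair_lab[1, ], pair_lab[2, ])[1]
  i <- cand[pick, 1]; j <- cand[pick, 2]
  path <- ape::nodepath(tree, i, j)
  adj <- phylo_adjacency(tree)
  edge_len <- function(u, v) {
    nb <- adj[[u]]
    nb[match(v, nb[, 1]), 2]
  }
  cum <- c(0, cumsum(vapply(seq_len(length(path) - 1L), function(t) {
    edge_len(path[t], path[t + 1L])
  }, numeric(1))))
  half <- maxd / 2
  t_at <- which(abs(cum - half) <= 1e-9)
  if (length(t_at) && path[t_at[1]] > ntip) {
    # midpoint coincides with an internal node: root there
    return(rooted_from_adjacency(adj, path[t_at[1]], ntip, tree$tip.label,
                                 node_lab))
  }
  t2 <- which(cum > half)[1]
  u <- path[t2 - 1L]; v <- path[t2]
  a <- half - cum[t2 - 1L]           # distance from u into edge (u, v)
  full <- edge_len(u, v)
  # splice a new root vertex into edge (u, v)
  nv <- length(adj)
  rootv <- nv + 1L
  adj[[u]] <- adj[[u]][adj[[u]][, 1] != v, , drop = FALSE]
  adj[[v]] <- adj[[v]][adj[[v]][, 1] != u, , drop = FALSE]
  adj[[rootv]] <- rbind(c(u, a), c(v, full - a))
  adj[[u]] <- rbind(adj[[u]], c(rootv, a))
  adj[[v]] <- rbind(adj[[v]], c(rootv, full - a))
  rooted_from_adjacency(adj, rootv, ntip, tree$tip.label, node_lab)
}

#' Bootstrap support by column resampling
#'
#' Resamples alignment columns with replacement, rebuilds the
#' neighbor-joining tree per replicate, and reports the recovery fraction
#' of every internal bipartition of the original tree. Supports (in
#' `[0, 1]`) are attached to the returned tree as `node.label` and as the
#' numeric attribute `support`. Seeded and reproducible.
#'
#' @param aln A `protein_alignment` with >= 4 rows.
#' @param config A [phylo_config()] (uses `bootstrap_replicates` and
#'   `distance_model`).
#' @param seed Integer RNG seed.
#' @return The original NJ tree; with supports attached unless
#'   `bootstrap_replicates` is 0.
#' @export
bootstrap_support <- function(aln, config = phylo_config(), seed = 1L) {
  abort_if(length(aln$row_ids) < 4L, "need >= 4 alignment rows",
           class = "nrnbkit_validation_error")
  D <- distance_matrix(aln, config$distance_model)
  orig <- neighbor_joining(D)
  B <- config$bootstrap_replicates
  if (B == 0L) return(orig)
  set.seed(seed)
  m <- rows_to_matrix(aln$rows)
  nc <- ncol(m)
  boots <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    sub <- new_alignment(aln$row_ids,
                         apply(m[, cols, drop = FALSE], 1, paste,
                               collapse = ""))
    Db <- distance_matrix(sub, config$distance_model,
                          on_incomparable = "max")
    boots[[b]] <- neighbor_joining(Db)
  }
  counts <- ape::prop.clades(orig, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- counts / B
  orig$node.label <- formatC(support, digits = 3, format = "f")
  attr(orig, "support") <- support
  orig
}

# leaf indices under each internal node of a rooted tree
node_descendants <- function(tree) {
  ntip <- length(tree$tip.label)
  nv <- ntip + tree$Nnode
  kids <- vector("list", nv)
  for (e in seq_len(nrow(tree$edge))) {
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  }
  desc <- vector("list", nv)
  fill <- function(v) {
    if (v <= ntip) {
      desc[[v]] <<- v
    } else {
      out <- integer(0)
      for (w in kids[[v]]) {
        fill(w)
        out <- c(out, desc[[w]])
      }
      desc[[v]] <<- out
    }
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  fill(root)
  list(desc = desc, kids = kids, root = root)
}

#' Extract major clades by subtree tightness
#'
#' Depth-first from the root, a node is reported as a major-clade root when
#' its subtree holds at least `clade_min_size` leaves and the mean pairwise
#' leaf path length within the subtree is at most `clade_tightness` times
#' the whole-tree mean. Descendants of a reported node are skipped, so the
#' reported leaf sets are disjoint.
#'
#' @param tree A rooted [ape::phylo].
#' @param config A [phylo_config()].
#' @return List of character vectors of leaf labels (possibly empty list).
#' @export
extract_major_clades <- function(tree, config = phylo_config()) {
  ntip <- length(tree$tip.label)
  if (ntip < config$clade_min_size) return(list())
  coph <- ape::dist.nodes(tree)[seq_len(ntip), seq_len(ntip), drop = FALSE]
  whole_mean <- mean(coph[upper.tri(coph)])
  nd <- node_descendants(tree)
  out <- list()
  visit <- function(v) {
    leaves <- nd$desc[[v]]
    if (length(leaves) >= config$clade_min_size) {
      sub <- coph[leaves, leaves, drop = FALSE]
      msub <- mean(sub[upper.tri(sub)])
      if (whole_mean > 0 && msub <= config$clade_tightness * whole_mean) {
        out[[length(out) + 1L]] <<- tree$tip.label[leaves]
        return(invisible(NULL))
      }
    }
    if (v > ntip) for (w in nd$kids[[v]]) visit(w)
    invisible(NULL)
  }
  visit(nd$root)
  out
}

#' Read a Newick tree
#'
#' Parses standard Newick with branch lengths and support values stored as
#' internal-node labels. Unbalanced parentheses are reported with the
#' character offset of the imbalance.
#'
#' @param path Path to a Newick file (or use `text`).
#' @param text Newick string.
#' @return An [ape::phylo].
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    abort_if(is.null(path) || !file.exists(path), "file not found: ",
             path %||% "<missing>")
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1L
    if (chars[k] == ")") depth <- depth - 1L
    abort_if(depth < 0L, "Newick parse error: unbalanced ')' at offset ", k,
             class = "nrnbkit_parse_error")
  }
  abort_if(depth != 0L, "Newick parse error: ", depth,
           " unclosed '(' at offset ", length(chars),
           class = "nrnbkit_parse_error")
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  abort_if(is.null(tr), "Newick parse error: unparseable input",
           class = "nrnbkit_parse_error")
  tr
}

#' Write a tree as Newick
#'
#' Branch lengths are written with 6 decimal digits; internal-node labels
#' (bootstrap supports) are preserved.
#'
#' @param tree An [ape::phylo].
#' @param path Output path; when `NULL` the Newick string is returned.
#' @return The path (invisibly) or the Newick string.
#' @export
write_newick <- function(tree, path = NULL) {
  if (!is.null(tree$edge.length)) {
    tree$edge.length <- round(tree$edge.length, 6)
  }
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
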