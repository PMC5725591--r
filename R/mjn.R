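hamming <- function(p, q) sum(p != q)

hamming_matrix <- function(prof) {
  n <- nrow(prof)
  D <- matrix(0L, n, n, dimnames = list(rownames(prof), rownames(prof)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- hamming(prof[i, ], prof[j, ])
  }
  D
}

# relaxed minimum spanning network: process weight classes in ascending
# order; an edge is kept when its endpoints lie in different components at
# the start of its weight class (so all co-minimal alternatives are kept).
msn_edges <- function(D, epsilon = 0) {
  n <- nrow(D)
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[pairs]
  classes <- sort(unique(w))
  keep <- logical(nrow(pairs))
  for (cw in classes) {
    in_class <- which(w >= cw & w <= cw + epsilon & !keep)
    snapshot <- vapply(seq_len(n), find, integer(1))
    sel <- in_class[snapshot[pairs[in_class, 1]] != snapshot[pairs[in_class, 2]]]
    keep[sel] <- TRUE
    for (s in sel) {
      a <- find(pairs[s, 1]); b <- find(pairs[s, 2])
      if (a != b) comp[a] <- b
    }
  }
  cbind(pairs[keep, , drop = FALSE], weight = w[keep])
}

mst_weight <- function(prof) {
  D <- hamming_matrix(prof)
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected", weighted = TRUE)
  sum(igraph::E(igraph::mst(g))$weight)
}

# quasi-medians of three profiles: majority state per locus; loci where
# all three states differ branch into one candidate per state
quasi_medians <- function(u, v, w, max_branch = 2) {
  L <- length(u)
  fixed <- character(L)
  open <- list()
  for (l in seq_len(L)) {
    states <- c(u[l], v[l], w[l])
    tab <- table(states)
    if (max(tab) >= 2) {
      fixed[l] <- names(tab)[which.max(tab)]
    } else {
      open[[length(open) + 1]] <- list(locus = l, states = unique(states))
    }
  }
  if (length(open) > max_branch) return(list())
  grids <- expand.grid(lapply(open, function(o) o$states),
                       stringsAsFactors = FALSE)
  if (nrow(grids) == 0) grids <- data.frame(row.names = 1)
  out <- list()
  for (r in seq_len(nrow(grids))) {
    m <- fixed
    for (k in seq_along(open)) m[open[[k]]$locus] <- grids[r, k]
    out[[r]] <- m
  }
  out
}

#' Median-joining network of genotype profiles
#'
#' Builds a median-joining network over multilocus token profiles: the
#' relaxed minimum spanning network (all co-minimal connections kept)
#' under Hamming distance is iteratively augmented with quasi-median
#' (consensus) profiles of mutually connected triples whenever the added
#' profile strictly reduces the total minimum-spanning-tree cost, then
#' inferred nodes that no longer reduce the cost are pruned. Observed
#' profiles always remain nodes; with `epsilon = 0` the network contains
#' a minimum spanning tree of the final node set.
#'
#' @param classes a `genotype_classes` object (profiles must be pairwise
#'   distinct), or a character matrix of profiles with labelled rows.
#' @param frequencies optional named counts per profile (taken from class
#'   member counts when `classes` is a `genotype_classes`).
#' @param epsilon tolerance on connection weights (default 0).
#' @return object of class `median_network`: list with `nodes` (data
#'   frame: name, observed, frequency, profile columns), `edges` (data
#'   frame: from, to, weight, loci — differing markers joined with `,`)
#'   and `graph` (an [igraph] graph with the same attributes).
#' @export
median_joining_network <- function(classes, frequencies = NULL, epsilon = 0) {
  if (inherits(classes, "genotype_classes")) {
    prof <- class_profile_matrix(classes)
    frequencies <- class_counts(classes)
  } else {
    prof <- as.matrix(classes)
    if (is.null(frequencies)) {
      frequencies <- stats::setNames(rep(1L, nrow(prof)), rownames(prof))
    }
  }
  if (anyDuplicated(apply(prof, 1, paste, collapse = "|"))) {
    stopf("duplicate profiles across classes")
  }
  observed_names <- rownames(prof)
  nodes <- prof
  n_median <- 0L
  repeat {
    D <- hamming_matrix(nodes)
    net <- msn_edges(D, epsilon)
    base_w <- mst_weight(nodes)
    g <- igraph::graph_from_edgelist(cbind(net[, 1], net[, 2]), directed = FALSE)
    tri <- if (igraph::gorder(g) >= 3) igraph::triangles(g) else integer(0)
    added <- FALSE
    if (length(tri)) {
      tri <- matrix(as.integer(tri), nrow = 3)
      keys <- apply(nodes, 1, paste, collapse = "|")
      for (t in seq_len(ncol(tri))) {
        cands <- quasi_medians(nodes[tri[1, t], ], nodes[tri[2, t], ],
                               nodes[tri[3, t], ])
        for (m in cands) {
          if (paste(m, collapse = "|") %in% keys) next
          trial <- rbind(nodes, m)
          if (mst_weight(trial) < base_w) {
            n_median <- n_median + 1L
            rownames(trial)[nrow(trial)] <- paste0("mv", n_median)
            nodes <- trial
            added <- TRUE
            break
          }
        }
        if (added) break
      }
    }
    if (!added) break
  }
  # prune inferred nodes that no longer pay for themselves
  repeat {
    medians <- setdiff(rownames(nodes), observed_names)
    if (!length(medians)) break
    w_all <- mst_weight(nodes)
    dropped <- FALSE
    for (m in medians) {
      trial <- nodes[rownames(nodes) != m, , drop = FALSE]
      if (mst_weight(trial) <= w_all) {
        nodes <- trial
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  D <- hamming_matrix(nodes)
  net <- msn_edges(D, epsilon)
  edge_loci <- vapply(seq_len(nrow(net)), function(e) {
    diff <- which(nodes[net[e, 1], ] != nodes[net[e, 2], ])
    paste(colnames(nodes)[diff], collapse = ",")
  }, "")
  nodes_df <- data.frame(
    name = rownames(nodes),
    observed = rownames(nodes) %in% observed_names,
    frequency = as.integer(ifelse(rownames(nodes) %in% names(frequencies),
                                  frequencies[rownames(nodes)], 0L)),
    stringsAsFactors = FALSE
  )
  nodes_df <- cbind(nodes_df, as.data.frame(nodes, stringsAsFactors = FALSE))
  edges_df <- data.frame(from = rownames(nodes)[net[, 1]],
                         to = rownames(nodes)[net[, 2]],
                         weight = net[, "weight"], loci = edge_loci,
                         stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges_df, directed = FALSE,
                                     vertices = nodes_df)
  structure(list(nodes = nodes_df, edges = edges_df, graph = g),
            class = "median_network")
}

#' @export
print.median_network <- function(x, ...) {
  cat(sprintf("<median_network> %d nodes (%d observed, %d inferred), %d edges\n",
              nrow(x$nodes), sum(x$nodes$observed), sum(!x$nodes$observed),
              nrow(x$edges)))
  invisible(x)
}

#' Write a median network as GML
#'
#' Nodes carry `label`, `observed` (0/1) and `frequency` attributes;
#' edges carry `weight` and the comma-joined differing `loci`. Output is
#' deterministic (no timestamps).
#'
#' @param network a `median_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_gml <- function(network, path) {
  nodes <- network$nodes; edges <- network$edges
  id <- stats::setNames(seq_len(nrow(nodes)) - 1L, nodes$name)
  lines <- c("graph [", "  directed 0")
  for (i in seq_len(nrow(nodes))) {
    lines <- c(lines, "  node [",
               sprintf("    id %d", id[[nodes$name[i]]]),
               sprintf("    label \"%s\"", nodes$name[i]),
               sprintf("    observed %d", as.integer(nodes$observed[i])),
               sprintf("    frequency %d", nodes$frequency[i]),
               "  ]")
  }
  for (e in seq_len(nrow(edges))) {
    lines <- c(lines, "  edge [",
               sprintf("    source %d", id[[edges$from[e]]]),
               sprintf("    target %d", id[[edges$to[e]]]),
               sprintf("    weight %d", as.integer(edges$weight[e])),
               sprintf("    loci \"%s\"", edges$loci[e]),
               "  ]")
  }
  writeLines(c(lines, "]"), path)
  invisible(path)
}
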