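#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage (unweighted pair-group, arithmetic mean) agglomeration
#' with node height = merge distance / 2, so the result is ultrametric.
#' Ties in the minimum distance are broken deterministically by joining
#' the pair whose (lexicographically smallest member label, then second
#' label) sorts first; sibling order inside the tree follows the same
#' rule, making the output invariant to input label order up to
#' isomorphism.
#'
#' @param dm symmetric numeric distance matrix with labelled dimnames.
#' @return an [ape] `phylo` tree (rooted, with branch lengths); merge
#'   clades and heights are attached as attribute `"clades"`.
#' @export
upgma_tree <- function(dm) {
  dm <- as.matrix(dm)
  labels <- rownames(dm)
  if (is.null(labels) || length(labels) < 2) {
    stopf("upgma_tree needs a labelled matrix with at least 2 taxa")
  }
  stopifnot(isTRUE(all.equal(dm, t(dm), tolerance = 1e-9)),
            all(diag(dm) == 0))
  clusters <- lapply(labels, function(l) {
    list(labels = l, rep = l, size = 1L, height = 0, newick = l)
  })
  D <- dm
  dimnames(D) <- NULL
  clades <- list()
  while (length(clusters) > 1) {
    n <- length(clusters)
    pair <- NULL; best <- Inf
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- D[i, j]
      if (d < best - 1e-12) {
        best <- d; pair <- c(i, j)
      } else if (abs(d - best) <= 1e-12) {
        cand <- sort(c(clusters[[i]]$rep, clusters[[j]]$rep))
        cur <- sort(c(clusters[[pair[1]]]$rep, clusters[[pair[2]]]$rep))
        if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])) {
          pair <- c(i, j)
        }
      }
    }
    i <- pair[1]; j <- pair[2]
    a <- clusters[[i]]; b <- clusters[[j]]
    if (a$rep > b$rep) { tmp <- a; a <- b; b <- tmp }
    h <- best / 2
    merged <- list(
      labels = sort(c(a$labels, b$labels)), rep = min(a$rep, b$rep),
      size = a$size + b$size, height = h,
      newick = sprintf("(%s:%.10g,%s:%.10g)", a$newick, h - a$height,
                       b$newick, h - b$height)
    )
    clades[[length(clades) + 1]] <- list(labels = merged$labels, height = h)
    keep <- setdiff(seq_len(n), pair)
    newD <- matrix(0, n - 1, n - 1)
    if (length(keep)) {
      newD[seq_along(keep), seq_along(keep)] <- D[keep, keep, drop = FALSE]
      dmerge <- (clusters[[i]]$size * D[i, keep] +
                   clusters[[j]]$size * D[j, keep]) /
        (clusters[[i]]$size + clusters[[j]]$size)
      newD[n - 1, seq_along(keep)] <- dmerge
      newD[seq_along(keep), n - 1] <- dmerge
    }
    clusters <- c(clusters[keep], list(merged))
    D <- newD
  }
  phy <- ape::read.tree(text = paste0(clusters[[1]]$newick, ";"))
  attr(phy, "clades") <- clades
  phy
}

# sorted tip-label sets for every internal node of a phylo tree
phylo_clades <- function(phy) {
  phy <- stats::reorder(phy, "postorder")
  n <- length(phy$tip.label)
  sets <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) sets[[i]] <- phy$tip.label[i]
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(sets[(n + 1):(n + phy$Nnode)], sort)
}

clade_key <- function(labels) paste(labels, collapse = "\r")

#' Bootstrap support for UPGMA clades by locus resampling
#'
#' Loci are resampled with replacement `n_reps` times; for each replicate
#' the allele-sharing distance matrix and UPGMA tree are rebuilt and each
#' reference clade is scored as recovered when a replicate clade contains
#' exactly the same taxa. Deterministic given `seed`.
#'
#' @param profiles character matrix of genotype tokens, rows = taxa
#'   (labelled), columns = loci.
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return list with `tree` (the reference UPGMA tree with node labels =
#'   integer support percentages), `support` (named numeric vector of
#'   support fractions per internal node, named by the clade's taxa
#'   joined with `,`) and `n_reps`.
#' @export
bootstrap_support <- function(profiles, n_reps = 1000, seed = 1) {
  stopifnot(ncol(profiles) >= 2, nrow(profiles) >= 2)
  set.seed(seed)
  arr <- pairwise_shared_array(profiles)
  ref_tree <- upgma_tree(dist_from_shared(arr))
  ref_clades <- phylo_clades(ref_tree)
  keys <- vapply(ref_clades, clade_key, "")
  counts <- stats::setNames(numeric(length(keys)), keys)
  L <- dim(arr)[3]
  for (r in seq_len(n_reps)) {
    loci <- sample.int(L, L, replace = TRUE)
    phy <- upgma_tree(dist_from_shared(arr, loci))
    rep_keys <- unique(vapply(phylo_clades(phy), clade_key, ""))
    hit <- keys %in% rep_keys
    counts[hit] <- counts[hit] + 1
  }
  support <- counts / n_reps
  names(support) <- vapply(ref_clades, paste, "", collapse = ",")
  ref_tree$node.label <- as.character(round(100 * support))
  list(tree = ref_tree, support = support, n_reps = n_reps)
}

#' Genotype-relationship tree with optional bootstrap
#'
#' Convenience wrapper building the allele-sharing distance matrix from
#' genotype classes (optionally with a reference profile) and returning a
#' UPGMA dendrogram — the stated procedure — or, as an alternative, a
#' neighbour-joining tree via [ape::nj].
#'
#' @param classes a `genotype_classes` object or profile matrix.
#' @param method `"upgma"` (default) or `"nj"`.
#' @param reference optional reference profile (see
#'   [class_distance_matrix]).
#' @param n_reps bootstrap replicates; 0 disables bootstrapping.
#' @param seed RNG seed for the bootstrap.
#' @return a `phylo` tree; with bootstrapping, node labels carry integer
#'   support percentages and the support vector is attached as attribute
#'   `"support"`.
#' @export
genotype_tree <- function(classes, method = c("upgma", "nj"),
                          reference = NULL, n_reps = 0, seed = 1) {
  method <- match.arg(method)
  prof <- if (inherits(classes, "genotype_classes")) {
    class_profile_matrix(classes)
  } else {
    as.matrix(classes)
  }
  if (!is.null(reference)) prof <- rbind(prof, REF = reference[colnames(prof)])
  dm <- dist_from_shared(pairwise_shared_array(prof))
  if (method == "nj") {
    return(ape::nj(stats::as.dist(dm)))
  }
  if (n_reps > 0) {
    bootstrap_support(prof, n_reps = n_reps, seed = seed)$tree
  } else {
    upgma_tree(dm)
  }
}
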