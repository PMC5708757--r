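#' Jaccard similarity between samples on the band matrix
#'
#' S(i, j) = |shared bands| / |union of bands| over band columns observed
#' (unmasked) in both samples. `jaccard_distance()` returns 1 - S as an
#' `indel_dist` matrix suitable for [upgma()].
#'
#' @param bm a [band_matrix()]
#' @return a symmetric similarity (respectively distance) matrix
#' @export
jaccard_similarity <- function(bm) {
  n <- nrow(bm$x)
  if (n < 2) stop_validation("need at least 2 samples")
  x0 <- bm$x
  x0[is.na(x0)] <- 0L
  obs <- (!is.na(bm$x)) * 1L
  inter <- x0 %*% t(x0)
  # union over mutually observed columns: presences of i seen by j + vice versa - inter
  pres_i <- x0 %*% t(obs)
  pres_j <- obs %*% t(x0)
  uni <- pres_i + pres_j - inter
  if (any(uni[upper.tri(uni)] == 0)) {
    bad <- which(uni == 0 & upper.tri(uni), arr.ind = TRUE)[1, ]
    stop_computation("samples '%s' and '%s' have an empty band union",
                     rownames(x0)[bad[1]], rownames(x0)[bad[2]])
  }
  s <- inter / uni
  diag(s) <- 1
  dimnames(s) <- list(rownames(bm$x), rownames(bm$x))
  s
}

#' @rdname jaccard_similarity
#' @export
jaccard_distance <- function(bm) {
  d <- 1 - jaccard_similarity(bm)
  structure(d, metric = "one_minus_jaccard", class = c("indel_dist", "matrix"))
}

#' UPGMA dendrogram
#'
#' Average-linkage agglomerative clustering of a distance matrix. Merge
#' heights follow the ultrametric convention (height = inter-cluster
#' average distance / 2), so the cophenetic distance between two leaves
#' equals the average-linkage distance at which their clusters merged.
#'
#' @param d an `indel_dist` (or any symmetric distance matrix / `dist`)
#' @return an `indel_upgma` object wrapping the `hclust` fit, with `merges`
#'   (tibble of merge heights in the distance/2 convention) and `labels`
#' @export
upgma <- function(d) {
  dd <- stats::as.dist(as.matrix(d))
  hc <- stats::hclust(dd, method = "average")
  merges <- tibble::tibble(step = seq_along(hc$height),
                           height = hc$height / 2)
  structure(list(hclust = hc, merges = merges, labels = hc$labels),
            class = "indel_upgma")
}

#' @export
print.indel_upgma <- function(x, ...) {
  cat(sprintf("<indel_upgma> %d leaves, tree height %.4g (distance/2 units)\n",
              length(x$labels), max(x$merges$height)))
  invisible(x)
}

#' Cophenetic distances implied by a UPGMA tree
#'
#' Twice the merge height of the lowest common ancestor of each leaf pair,
#' i.e. the average-linkage distance at which the pair's clusters merged.
#'
#' @param tree an `indel_upgma`
#' @return a `dist` of tree-implied pairwise distances
#' @export
cophenetic_distances <- function(tree) stats::cophenetic(tree$hclust)

#' Cophenetic correlation
#'
#' Pearson correlation between the tree-implied (cophenetic) distances and
#' the input distances over all sample pairs; 1 indicates the dendrogram
#' reproduces the distance matrix exactly (ultrametric input).
#'
#' @param tree an `indel_upgma`
#' @param d the distance matrix the tree was built from
#' @return correlation in \[-1, 1\]
#' @export
cophenetic_correlation <- function(tree, d) {
  dd <- stats::as.dist(as.matrix(d))
  cd <- cophenetic_distances(tree)
  if (attr(dd, "Size") != length(tree$labels))
    stop_validation("tree and distance matrix have different leaf sets")
  labs <- attr(dd, "Labels")
  if (!is.null(labs) && !identical(labs, tree$labels)) {
    m <- as.matrix(cd)[labs, labs]
    cd <- stats::as.dist(m)
  }
  if (length(dd) < 3 || stats::sd(dd) == 0 || stats::sd(cd) == 0)
    stop_computation("cophenetic correlation undefined (too few pairs or constant distances)")
  stats::cor(as.vector(dd), as.vector(cd))
}

#' Convert a UPGMA tree to an ape phylogeny / Newick
#'
#' Branch lengths are height differences in the distance/2 convention, so
#' patristic distances on the exported tree equal the cophenetic distances.
#'
#' @param tree an `indel_upgma`
#' @return an `ape::phylo`
#' @export
as_phylo <- function(tree) ape::as.phylo(tree$hclust)

#' @rdname as_phylo
#' @param path output Newick file
#' @return (write_newick) invisibly, the path
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(as_phylo(tree), file = path)
  invisible(path)
}

#' Cut a UPGMA tree at a similarity threshold
#'
#' For trees built on 1 - Jaccard distances, cutting at similarity `s`
#' groups samples whose pairwise cophenetic similarity exceeds `s` (e.g.
#' `similarity = 0.30` reproduces a two-major-group partition of a
#' structured panel).
#'
#' @param tree an `indel_upgma` built on a similarity-derived distance
#' @param similarity similarity level in (0, 1) at which to cut
#' @return tibble `sample_id`, `cluster` (integer memberships)
#' @export
cut_clusters <- function(tree, similarity = 0.30) {
  if (similarity <= 0 || similarity >= 1)
    stop_validation("similarity must be in (0, 1)")
  memb <- stats::cutree(tree$hclust, h = 1 - similarity)
  tibble::tibble(sample_id = names(memb), cluster = as.integer(memb))
}
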