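#' Read a rooted phylogeny from a newick file
#'
#' Wraps [ape::read.tree()] with the validation the downstream UniFrac
#' computation needs: unique tip labels, a branch length on every edge,
#' and no negative lengths. Unrooted trees are midpoint-rooted with a
#' warning. Tips without abundance data are allowed.
#'
#' @param path Path to a newick file (or a newick string via `text`).
#' @param text Optional newick string, used instead of `path`.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path, text = NULL) {
  tree <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tree)) stop("malformed newick")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate tip label(s): ", paste(unique(dup), collapse = ", "))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    node <- if (is.null(tree$edge.length)) "all nodes" else {
      child <- tree$edge[which(is.na(tree$edge.length))[1], 2]
      if (child <= length(tree$tip.label)) tree$tip.label[child]
      else paste("internal node", child)
    }
    stop("missing branch length at ", node)
  }
  if (any(tree$edge.length < 0))
    stop("negative branch length(s)")
  if (!ape::is.rooted(tree)) {
    warning("unrooted input tree; midpoint-rooting")
    tree <- phangorn::midpoint(tree)
  }
  tree
}

#' @rdname read_newick
#' @param tree An [ape::phylo] object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# Per-branch descendant-tip proportion totals for a set of abundance
# vectors, by one post-order accumulation. Returns a matrix, edges x
# vectors, aligned with tree$edge.
branch_proportions <- function(tree, p) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  acc <- matrix(0, ntip + tree$Nnode, ncol(p))
  idx <- match(rownames(p), tree$tip.label)
  if (anyNA(idx))
    stop("tip(s) absent from tree: ",
         paste(rownames(p)[is.na(idx)], collapse = ", "))
  acc[idx, ] <- p
  for (e in seq_len(nrow(tree$edge)))
    acc[tree$edge[e, 1], ] <- acc[tree$edge[e, 1], ] + acc[tree$edge[e, 2], ]
  list(props = acc[tree$edge[, 2], , drop = FALSE],
       lengths = tree$edge.length)
}

#' Generalized UniFrac distance between two communities
#'
#' Computes the generalized UniFrac distance
#' \deqn{d = \frac{\sum_i b_i (p_{Ai}+p_{Bi})^\alpha \,
#'   |p_{Ai}-p_{Bi}|/(p_{Ai}+p_{Bi})}{\sum_i b_i (p_{Ai}+p_{Bi})^\alpha}}
#' where the sum runs over branches, \eqn{b_i} is the branch length and
#' \eqn{p_{Xi}} the total proportion of community X descending from the
#' branch. `alpha` down-weights abundant lineages; `alpha = 1` is the
#' weighted-normalized UniFrac. Branches subtending no abundance in
#' either community contribute nothing. The root has no branch and is
#' excluded.
#'
#' @param tree Rooted [ape::phylo] with branch lengths; tips are OTU ids.
#' @param p_a,p_b Named non-negative vectors over (a subset of) the tips,
#'   each summing to 1 within `1e-6`.
#' @param alpha Abundance weight in \[0, 1\] (default 0.5).
#' @return The distance, a number in \[0, 1\].
#' @export
gunifrac <- function(tree, p_a, p_b, alpha = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1)
  for (p in list(p_a, p_b))
    if (abs(sum(p) - 1) > 1e-6)
      stop("abundance vector does not sum to 1 (off by ",
           format(sum(p) - 1), ")")
  tips <- union(names(p_a), names(p_b))
  p <- matrix(0, length(tips), 2, dimnames = list(tips, c("A", "B")))
  p[names(p_a), "A"] <- p_a
  p[names(p_b), "B"] <- p_b
  br <- branch_proportions(tree, p)
  pa <- br$props[, 1]
  pb <- br$props[, 2]
  tot <- pa + pb
  keep <- tot > 0
  num <- sum(br$lengths[keep] * tot[keep]^alpha *
               abs(pa[keep] - pb[keep]) / tot[keep])
  den <- sum(br$lengths[keep] * tot[keep]^alpha)
  num / den
}

#' Pairwise phylogenetic distances between layer-preferential OTU sets
#'
#' Builds one abundance vector per water layer from the OTUs assigned to
#' that layer by [layer_of_max_activity()] (summed relative abundances,
#' renormalized; or presence/absence weights) and returns the matrix of
#' generalized UniFrac distances among layers — the phylogenetic
#' diversity associated with each layer's preferentially active taxa.
#'
#' @param tree Rooted [ape::phylo] over the OTUs.
#' @param layer_sets Named list, layer -> named abundance vector over
#'   that layer's OTUs (need not be normalized; renormalized internally).
#' @param alpha Generalized UniFrac alpha (default 0.5).
#' @param weighted If `FALSE`, replace abundances by equal weights.
#' @return Symmetric layers x layers matrix with zero diagonal.
#' @export
layer_phylo_distances <- function(tree, layer_sets, alpha = 0.5,
                                  weighted = TRUE) {
  empty <- names(layer_sets)[lengths(layer_sets) == 0]
  if (length(empty))
    stop("empty layer set(s): ", paste(empty, collapse = ", "))
  vecs <- lapply(layer_sets, function(v) {
    if (!weighted) v[] <- 1
    v / sum(v)
  })
  k <- length(vecs)
  d <- matrix(0, k, k, dimnames = list(names(vecs), names(vecs)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    d[i, j] <- d[j, i] <- gunifrac(tree, vecs[[i]], vecs[[j]], alpha)
  d
}

#' Abundance vectors of layer-preferential OTUs
#'
#' Helper joining [layer_of_max_activity()] output with a relative
#' abundance table: for each layer, the summed relative abundance of the
#' OTUs whose activity peaks there.
#'
#' @param max_act Data frame from [layer_of_max_activity()].
#' @param rel A [relative_abundance()] matrix (rRNA survey).
#' @return Named list, layer -> named abundance vector.
#' @export
layer_abundance_sets <- function(max_act, rel) {
  max_act <- max_act[!max_act$ambiguous & !is.na(max_act$max_layer), ]
  out <- lapply(split(max_act$otu_id, max_act$max_layer), function(otus) {
    otus <- intersect(otus, rownames(rel))
    rowSums(rel[otus, , drop = FALSE])
  })
  out[lengths(out) > 0]
}
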