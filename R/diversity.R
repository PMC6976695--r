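#' Alpha diversity: Shannon index and OTU richness
#'
#' `shannon()` returns the Shannon index H' = -sum p_i log p_i in natural
#' log units (nats); `richness()` returns the number of OTUs with at
#' least one read.
#'
#' @param x Non-negative numeric vector of counts or proportions (for
#'   `shannon`, not all zero), or a matrix with samples as columns.
#' @return Numeric value per sample.
#' @export
shannon <- function(x) {
  if (is.matrix(x)) return(apply(strip_table_class(x), 2, shannon))
  if (any(x < 0)) stop("negative abundance")
  if (sum(x) == 0) stop("all-zero abundance vector")
  as.numeric(vegan::diversity(x, index = "shannon"))
}

#' @rdname shannon
#' @export
richness <- function(x) {
  if (is.matrix(x)) return(apply(strip_table_class(x), 2, richness))
  if (any(x < 0)) stop("negative abundance")
  sum(x > 0)
}

#' Bray-Curtis dissimilarity between samples
#'
#' BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i) over OTUs, computed
#' between every pair of samples (columns).
#'
#' @param x An [otu_table()] or [relative_abundance()] matrix (OTUs x
#'   samples), with at least two samples and no all-zero sample.
#' @return A `dist` object labelled by sample id, values in \[0, 1\].
#' @export
bray_curtis <- function(x) {
  m <- strip_table_class(as.matrix(x))
  if (ncol(m) < 2) stop("need at least two samples")
  if (any(colSums(m) == 0))
    stop("all-zero sample(s): ",
         paste(colnames(m)[colSums(m) == 0], collapse = ", "))
  vegan::vegdist(t(m), method = "bray")
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 NMDS with monotone regression, best configuration of
#' `n_starts` random starts. Deterministic given `seed`.
#'
#' @param d A `dist` object (e.g. from [bray_curtis()]).
#' @param k Number of ordination dimensions (default 2).
#' @param n_starts Number of random starts (default 20).
#' @param seed Integer seed.
#' @return List with `points` (samples x k coordinate matrix) and
#'   `stress` (final stress-1, as a fraction in \[0, 1\]).
#' @export
nmds <- function(d, k = 2, n_starts = 20, seed = 1L) {
  n <- attr(d, "Size")
  if (k >= n) stop("'k' must be smaller than the number of samples")
  fit <- withr::with_seed(seed,
    vegan::metaMDS(d, k = k, try = n_starts, trymax = max(n_starts, 20),
                   trace = 0, autotransform = FALSE, wascores = FALSE))
  list(points = fit$points, stress = fit$stress, converged = fit$converged)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities. The statistic is Clarke's R
#' (mid-ranks for ties), in \[-1, 1\]; the p-value is one-sided for large
#' R, computed as (number of permuted R >= observed + 1) / (n_perm + 1).
#'
#' @param d A `dist` object.
#' @param grouping Factor-like group labels, one per sample; every group
#'   needs at least two members.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List with `statistic` (R), `p_value` and `n_perm`.
#' @export
anosim_test <- function(d, grouping, n_perm = 1000, seed = 1L) {
  grouping <- as.factor(grouping)
  if (nlevels(droplevels(grouping)) < 2)
    stop("need at least two groups")
  if (any(table(grouping) < 2))
    stop("every group needs at least two members")
  fit <- withr::with_seed(seed,
    vegan::anosim(d, grouping, permutations = n_perm))
  list(statistic = unname(fit$statistic),
       p_value = fit$signif,
       n_perm = n_perm)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Distance-based variance partitioning with Anderson's pseudo-F and
#' sequential (Type I) sums of squares in the order the terms are given;
#' permutes raw rows. The residual R2 is reported so explained plus
#' residual R2 sum to 1.
#'
#' @param d A `dist` object.
#' @param data Data frame of factors/covariates aligned with the samples
#'   of `d`.
#' @param terms Character vector naming columns of `data`, in the order
#'   they should enter the model; defaults to all columns.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return Data frame with one row per term plus `Residual` and `Total`:
#'   `df`, `SS`, `R2`, `pseudo_F`, `p_value`.
#' @export
permanova <- function(d, data, terms = names(data), n_perm = 999, seed = 1L) {
  stopifnot(nrow(data) == attr(d, "Size"))
  keep <- vapply(terms, function(t) length(unique(data[[t]])) > 1, logical(1))
  if (any(!keep))
    warning("dropping constant term(s): ",
            paste(terms[!keep], collapse = ", "))
  terms <- terms[keep]
  if (!length(terms)) stop("no non-constant terms")
  fml <- stats::as.formula(paste("d ~", paste(terms, collapse = " + ")))
  fit <- withr::with_seed(seed,
    vegan::adonis2(fml, data = data, permutations = n_perm, by = "terms"))
  data.frame(term = rownames(fit), df = fit$Df, SS = fit$SumOfSqs,
             R2 = fit$R2, pseudo_F = fit$F, p_value = fit$`Pr(>F)`,
             row.names = NULL)
}
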