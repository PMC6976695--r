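#' Per-layer distributions of community dissimilarity
#'
#' Collects, for each water layer (or sublayer), all pairwise
#' dissimilarities among the samples of that stratum — the horizontal
#' distance-decay signal. Comparing one sample per station per stratum is
#' the intended design; set `one_per_station = TRUE` to select the
#' shallowest sample of each station within each stratum.
#'
#' @param d A `dist` object over samples (e.g. [bray_curtis()]).
#' @param meta Metadata covering the samples of `d`.
#' @param stratum `"layer"` or `"sublayer"`.
#' @param one_per_station Keep only one (the shallowest) sample per
#'   station within each stratum (default `FALSE`).
#' @return Named list, one numeric vector of dissimilarities per stratum
#'   (strata with fewer than two samples are skipped with a message).
#' @export
layer_dissimilarity_distributions <- function(d, meta, stratum = c("layer", "sublayer"),
                                              one_per_station = FALSE) {
  stratum <- match.arg(stratum)
  m <- as.matrix(d)
  meta <- meta[match(rownames(m), meta$sample_id), ]
  levels <- if (stratum == "layer") PICO_LAYERS else PICO_SUBLAYERS
  out <- list()
  skipped <- character()
  for (s in intersect(levels, unique(meta[[stratum]]))) {
    rows <- meta[meta[[stratum]] %in% s, ]
    if (one_per_station)
      rows <- do.call(rbind, lapply(split(rows, rows$station),
                                    function(g) g[which.min(g$depth_m), ]))
    ids <- rows$sample_id
    if (length(ids) < 2) {
      skipped <- c(skipped, s)
      next
    }
    sub <- m[ids, ids]
    out[[s]] <- sub[lower.tri(sub)]
  }
  if (length(skipped))
    message("skipping stratum(s) with <2 samples: ",
            paste(skipped, collapse = ", "))
  out
}

#' OTU prevalence curves per water layer
#'
#' For each layer, counts how many OTUs are detected (>= 1 read) in
#' exactly n stations, for n = 1..N. Also reports the fraction of the
#' layer's OTUs present in at least a fraction `q` of its stations
#' (the "core" fraction).
#'
#' @param x An [otu_table()].
#' @param meta Metadata covering the samples of `x`.
#' @param q Core prevalence fraction (default 0.8).
#' @return Named list per layer, each with `counts` (named vector over
#'   n = 1..N stations), `n_stations`, `n_otus` and `core_fraction`.
#' @export
prevalence_curves <- function(x, meta, q = 0.8) {
  meta <- meta[match(colnames(x), meta$sample_id), ]
  out <- list()
  for (l in intersect(PICO_LAYERS, unique(meta$layer))) {
    ids <- meta$sample_id[meta$layer == l]
    stations <- meta$station[meta$layer == l]
    sub <- strip_table_class(x)[, ids, drop = FALSE]
    det <- rowsum(t(sub > 0) * 1L, group = stations)  # station x OTU
    prev <- colSums(det > 0)
    prev <- prev[prev > 0]
    n_st <- length(unique(stations))
    counts <- tabulate(prev, nbins = n_st)
    names(counts) <- seq_len(n_st)
    out[[l]] <- list(counts = counts, n_stations = n_st,
                     n_otus = length(prev),
                     core_fraction = mean(prev >= q * n_st))
  }
  out
}

#' Layer-restricted (unique) OTUs
#'
#' An OTU is restricted to a layer when all of its reads across the whole
#' dataset fall in samples of that layer. Only OTUs with strictly more
#' than `min_reads` total reads are considered; fractions are computed
#' over that filtered set.
#'
#' @param x An [otu_table()].
#' @param meta Metadata covering the samples of `x`.
#' @param min_reads Total-read filter, strict inequality (default 5).
#' @return Named list per layer with `otus` (character vector) and
#'   `fraction` (of the filtered OTU set); attribute `"n_filtered"`
#'   carries the size of the filtered set.
#' @export
layer_restricted_otus <- function(x, meta, min_reads = 5) {
  meta <- meta[match(colnames(x), meta$sample_id), ]
  m <- strip_table_class(x)
  m <- m[rowSums(m) > min_reads, , drop = FALSE]
  by_layer <- rowsum(t(m), group = factor(meta$layer, levels = PICO_LAYERS))
  present <- by_layer > 0  # layer x OTU
  n_layers_present <- colSums(present)
  out <- lapply(stats::setNames(PICO_LAYERS, PICO_LAYERS), function(l) {
    otus <- colnames(present)[present[l, ] & n_layers_present == 1]
    list(otus = otus, fraction = length(otus) / nrow(m))
  })
  attr(out, "n_filtered") <- nrow(m)
  out
}

#' Matrix of OTUs shared between water layers
#'
#' Symmetric 4x4 matrix counting OTUs detected in both layers of each
#' pair; the diagonal holds the number of OTUs detected in each layer.
#'
#' @param x An [otu_table()].
#' @param meta Metadata covering the samples of `x`.
#' @return Integer matrix, layers x layers.
#' @export
shared_otu_matrix <- function(x, meta) {
  meta <- meta[match(colnames(x), meta$sample_id), ]
  by_layer <- rowsum(t(strip_table_class(x)),
                     group = factor(meta$layer, levels = PICO_LAYERS))
  present <- (by_layer > 0) * 1L  # layer x OTU
  present %*% t(present)
}
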