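#' Pair rDNA and rRNA samples by station and depth
#'
#' The rRNA:rDNA ratio is defined per water sample, so each (station,
#' depth) must contribute exactly one DNA-derived and one RNA-derived
#' sample. Station-depths missing either template are reported with a
#' message and excluded; two samples of the same template at one
#' station-depth is an error.
#'
#' @param meta Metadata data frame (see [read_metadata()]).
#' @return Data frame with columns `station`, `depth_m`, `layer`,
#'   `rdna_sample_id`, `rrna_sample_id`, plus `dsl`/`omz` flags when
#'   present in the metadata.
#' @export
pair_samples <- function(meta) {
  cols <- c("station", "depth_m", "layer",
            intersect(c("dsl", "omz", "sublayer", "ocean"), names(meta)))
  key <- interaction(meta$station, meta$depth_m, drop = TRUE)
  out <- lapply(split(meta, key), function(g) {
    for (t in PICO_TEMPLATES)
      if (sum(g$template == t) > 1)
        stop("two ", t, " samples at station ", g$station[1], ", ",
             g$depth_m[1], " m")
    if (!all(PICO_TEMPLATES %in% g$template)) return(NULL)
    cbind(g[1, cols, drop = FALSE],
          rdna_sample_id = g$sample_id[g$template == "rDNA"],
          rrna_sample_id = g$sample_id[g$template == "rRNA"])
  })
  n_unpaired <- sum(vapply(out, is.null, logical(1)))
  if (n_unpaired)
    message("pair_samples: ", n_unpaired,
            " station-depth(s) lack one template and were excluded")
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(station = character(), depth_m = numeric(),
                      layer = character(), rdna_sample_id = character(),
                      rrna_sample_id = character())
  out <- out[order(out$station, out$depth_m), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-OTU rRNA:rDNA relative-activity ratios
#'
#' For every paired sample and every OTU detected in *both* templates of
#' that pair, the ratio of its relative abundance in the RNA survey to
#' its relative abundance in the DNA survey. OTUs present in only one
#' template of a pair yield no record: zeros exclude, they are never
#' stored as 0 or infinity, and no pseudo-counts are added. Both tables
#' should come from the same rarefaction depth so proportions are
#' comparable.
#'
#' @param rdna_rel,rrna_rel [relative_abundance()] matrices for the DNA
#'   and RNA surveys.
#' @param pairs Sample pairing from [pair_samples()].
#' @param tax Optional taxonomy data frame; OTUs without an assignment
#'   are labelled `"IncertaeSedis Eukaryota"`.
#' @param whole_dataset_filter If `TRUE`, additionally drop OTUs absent
#'   from either survey as a whole before computing per-pair ratios (an
#'   alternative reading of the exclusion rule; default `FALSE`, i.e.
#'   exclusion is decided pair by pair).
#' @return Data frame of activity records: `otu_id`, `station`,
#'   `depth_m`, `layer`, `group`, `ratio`, plus the paired sample ids.
#' @export
activity_ratios <- function(rdna_rel, rrna_rel, pairs, tax = NULL,
                            whole_dataset_filter = FALSE) {
  missing <- c(setdiff(pairs$rdna_sample_id, colnames(rdna_rel)),
               setdiff(pairs$rrna_sample_id, colnames(rrna_rel)))
  if (length(missing))
    stop("pair references missing sample column(s): ",
         paste(missing, collapse = ", "))
  otus <- intersect(rownames(rdna_rel), rownames(rrna_rel))
  if (whole_dataset_filter)
    otus <- otus[rowSums(rdna_rel[otus, , drop = FALSE]) > 0 &
                 rowSums(rrna_rel[otus, , drop = FALSE]) > 0]
  extra <- intersect(c("dsl", "omz", "sublayer", "ocean"), names(pairs))
  recs <- lapply(seq_len(nrow(pairs)), function(i) {
    pd <- rdna_rel[otus, pairs$rdna_sample_id[i]]
    pr <- rrna_rel[otus, pairs$rrna_sample_id[i]]
    both <- pd > 0 & pr > 0
    if (!any(both)) return(NULL)
    cbind(data.frame(otu_id = otus[both],
                     station = pairs$station[i],
                     depth_m = pairs$depth_m[i],
                     layer = pairs$layer[i],
                     ratio = pr[both] / pd[both],
                     rdna_sample_id = pairs$rdna_sample_id[i],
                     rrna_sample_id = pairs$rrna_sample_id[i]),
          pairs[i, extra, drop = FALSE])
  })
  out <- do.call(rbind, recs)
  if (is.null(out))
    return(data.frame(otu_id = character(), station = character(),
                      depth_m = numeric(), layer = character(),
                      ratio = numeric(), group = character()))
  rownames(out) <- NULL
  grp <- if (is.null(tax)) NA_character_ else
    tax$group[match(out$otu_id, tax$otu_id)]
  grp[is.na(grp)] <- PICO_UNASSIGNED
  out$group <- grp
  out
}

#' Classify rRNA:rDNA ratios into activity levels
#'
#' Ratios well above parity flag metabolically hyperactive taxa, ratios
#' well below parity hypoactive taxa, and ratios near 1 average activity.
#' "Near 1" needs an operational width; the default band (0.5, 2) calls
#' anything within two-fold of parity average. The band is echoed into
#' pipeline output headers because results depend on it.
#'
#' @param ratio Numeric vector of positive ratios.
#' @param band Length-2 numeric `(low, high)` with 0 < low < 1 < high.
#' @return Character vector: `"hypoactive"`, `"average"` or
#'   `"hyperactive"`.
#' @export
classify_activity <- function(ratio, band = c(0.5, 2)) {
  if (length(band) != 2 || !(band[1] > 0 && band[1] < 1 && band[2] > 1))
    stop("'band' must satisfy 0 < low < 1 < high")
  ifelse(ratio > band[2], "hyperactive",
         ifelse(ratio < band[1], "hypoactive", "average"))
}

#' Layer-wise activity contrasts per taxonomic group
#'
#' Pools all per-OTU-per-pair ratios of a taxonomic group within each
#' water layer, then compares layers pairwise with two-sided unpaired
#' Wilcoxon rank-sum tests (layers hold different numbers of pairs, so a
#' paired test is not possible). P-values are Benjamini-Hochberg adjusted
#' across the pairwise comparisons within a group; both raw and adjusted
#' values are kept. A layer is "significantly high" for a group when its
#' median exceeds every other tested layer's median and all its pairwise
#' tests reach `alpha` after adjustment; "significantly low" is the
#' mirror rule.
#'
#' @param records Activity records from [activity_ratios()].
#' @param alpha Significance level after adjustment (default 0.05).
#' @param min_n Minimum number of ratios for a (group, layer) cell to
#'   enter testing (default 2).
#' @param p_adjust Multiplicity correction passed to [stats::p.adjust()]
#'   (default `"BH"`).
#' @return Object of class `"layer_contrasts"`: list with `medians`
#'   (groups x layers matrix), `n` (cell sizes), `p_raw` and `p_adj`
#'   (per-group layer x layer matrices), `significantly_high` and
#'   `significantly_low` (named lists of layer labels), and the
#'   parameters used.
#' @export
layer_contrasts <- function(records, alpha = 0.05, min_n = 2,
                            p_adjust = "BH") {
  groups <- sort(unique(records$group))
  medians <- matrix(NA_real_, length(groups), length(PICO_LAYERS),
                    dimnames = list(groups, PICO_LAYERS))
  ncell <- matrix(0L, length(groups), length(PICO_LAYERS),
                  dimnames = list(groups, PICO_LAYERS))
  p_raw <- p_adj <- stats::setNames(vector("list", length(groups)), groups)
  hi <- lo <- stats::setNames(vector("list", length(groups)), groups)
  skipped <- character()
  for (g in groups) {
    rg <- records[records$group == g, ]
    by_layer <- split(rg$ratio, factor(rg$layer, levels = PICO_LAYERS))
    ncell[g, ] <- lengths(by_layer)
    medians[g, ] <- vapply(by_layer, function(v)
      if (length(v)) stats::median(v) else NA_real_, numeric(1))
    tested <- names(by_layer)[lengths(by_layer) >= min_n]
    hi[[g]] <- lo[[g]] <- character()
    if (length(tested) < 2) {
      skipped <- c(skipped, g)
      next
    }
    pm <- matrix(NA_real_, length(tested), length(tested),
                 dimnames = list(tested, tested))
    for (i in seq_along(tested)[-1]) for (j in seq_len(i - 1)) {
      p <- suppressWarnings(stats::wilcox.test(
        by_layer[[tested[i]]], by_layer[[tested[j]]],
        alternative = "two.sided"))$p.value
      pm[tested[i], tested[j]] <- pm[tested[j], tested[i]] <- p
    }
    am <- pm
    am[lower.tri(am)] <- stats::p.adjust(pm[lower.tri(pm)], method = p_adjust)
    am[upper.tri(am)] <- t(am)[upper.tri(am)]
    p_raw[[g]] <- pm
    p_adj[[g]] <- am
    med <- medians[g, tested]
    for (l in tested) {
      others <- setdiff(tested, l)
      sig_all <- all(am[l, others] <= alpha)
      if (sig_all && all(med[l] > med[others])) hi[[g]] <- c(hi[[g]], l)
      if (sig_all && all(med[l] < med[others])) lo[[g]] <- c(lo[[g]], l)
    }
  }
  if (length(skipped))
    message("layer_contrasts: skipped group(s) with <2 testable layers: ",
            paste(skipped, collapse = ", "))
  structure(list(medians = medians, n = ncell, p_raw = p_raw, p_adj = p_adj,
                 significantly_high = hi, significantly_low = lo,
                 alpha = alpha, p_adjust = p_adjust, min_n = min_n),
            class = "layer_contrasts")
}

#' @export
print.layer_contrasts <- function(x, ...) {
  cat("Layer contrasts for", nrow(x$medians), "groups (alpha =", x$alpha,
      ",", x$p_adjust, "adjusted)\n")
  for (g in rownames(x$medians)) {
    flag <- c(if (length(x$significantly_high[[g]]))
      paste0("high: ", paste(x$significantly_high[[g]], collapse = ",")),
      if (length(x$significantly_low[[g]]))
        paste0("low: ", paste(x$significantly_low[[g]], collapse = ",")))
    cat(sprintf("  %-28s %s\n", g,
                if (length(flag)) paste(flag, collapse = "; ") else "-"))
  }
  invisible(x)
}

#' Layer of maximum activity per OTU
#'
#' Considers only OTUs with at least one ratio in each of the required
#' number of layers (default all four), computes the median ratio per
#' layer, and assigns each OTU to the layer where its median activity is
#' highest. OTUs whose maximum is tied between layers are flagged
#' ambiguous and excluded from downstream layer sets.
#'
#' @param records Activity records from [activity_ratios()].
#' @param min_layers Number of layers an OTU must be observed in to be
#'   eligible (default 4).
#' @return Data frame with one row per eligible OTU: `otu_id`, `group`,
#'   one median column per layer, `max_layer` (NA when ambiguous) and
#'   `ambiguous`.
#' @export
layer_of_max_activity <- function(records, min_layers = 4) {
  by_otu <- split(records, records$otu_id)
  rows <- lapply(by_otu, function(r) {
    meds <- vapply(split(r$ratio, factor(r$layer, levels = PICO_LAYERS)),
                   function(v) if (length(v)) stats::median(v) else NA_real_,
                   numeric(1))
    if (sum(!is.na(meds)) < min_layers) return(NULL)
    mx <- max(meds, na.rm = TRUE)
    at_max <- names(meds)[!is.na(meds) & meds == mx]
    data.frame(otu_id = r$otu_id[1], group = r$group[1],
               as.list(stats::setNames(meds, paste0("median_", names(meds)))),
               max_layer = if (length(at_max) == 1) at_max else NA_character_,
               ambiguous = length(at_max) > 1)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(otu_id = character(), group = character(),
                      max_layer = character(), ambiguous = logical())
  rownames(out) <- NULL
  out
}
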