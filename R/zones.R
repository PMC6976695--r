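#' Split the mesopelagic into a zone and its complement
#'
#' Defines the oxygen minimum zone (OMZ; mesopelagic water samples with
#' oxygen below the OMZ threshold, taken from the derived `omz` flag) or
#' the deep scattering layer (DSL; acoustically located, here a metadata
#' flag), and returns the zone together with the remaining mesopelagic
#' water samples. A water sample is a station-depth unit; both templates
#' of a unit belong to the same side.
#'
#' @param meta Metadata data frame with `omz` and `dsl` columns.
#' @param zone `"OMZ"` or `"DSL"`.
#' @return Object of class `"zone_split"`: list with `zone` and
#'   `complement` (data frames of station-depth units), the per-side
#'   sample-id vectors (all templates pooled), and `zone` name.
#' @export
define_zone <- function(meta, zone = c("OMZ", "DSL")) {
  zone <- match.arg(zone)
  meso <- meta[meta$layer == "mesopelagic", ]
  if (!nrow(meso)) stop("no mesopelagic samples in metadata")
  flag_col <- if (zone == "OMZ") "omz" else "dsl"
  if (is.null(meso[[flag_col]]))
    stop("metadata lacks the '", flag_col, "' column")
  units <- meso[!duplicated(paste(meso$station, meso$depth_m)),
                c("station", "depth_m", "layer", flag_col)]
  in_zone <- as.logical(units[[flag_col]])
  if (!any(in_zone)) stop("empty zone: no ", zone, " mesopelagic samples")
  if (all(in_zone)) stop("empty complement: all mesopelagic samples are ", zone)
  key <- paste(meso$station, meso$depth_m)
  zone_keys <- paste(units$station, units$depth_m)[in_zone]
  structure(list(
    zone = units[in_zone, ], complement = units[!in_zone, ],
    zone_sample_ids = meso$sample_id[key %in% zone_keys],
    complement_sample_ids = meso$sample_id[!key %in% zone_keys],
    name = zone), class = "zone_split")
}

#' @export
print.zone_split <- function(x, ...) {
  cat(x$name, " split: ", nrow(x$zone), " zone vs ", nrow(x$complement),
      " complement mesopelagic water samples\n", sep = "")
  invisible(x)
}

zone_membership <- function(records, split) {
  key <- paste(records$station, records$depth_m)
  zk <- paste(split$zone$station, split$zone$depth_m)
  ck <- paste(split$complement$station, split$complement$depth_m)
  ifelse(key %in% zk, "zone", ifelse(key %in% ck, "complement", NA))
}

#' Group-level abundance and activity contrast between a zone and the
#' rest of the mesopelagic
#'
#' For every taxonomic group passing the mesopelagic read-share filter,
#' computes the ratio of its aggregated relative abundance in the zone
#' samples to that in the complement samples (abundance statistic: mean),
#' and the ratio of its pooled rRNA:rDNA ratios in zone pairs to those in
#' complement pairs (activity statistic: median; the ratio distribution
#' is heavy-tailed). Groups with zero abundance on one side are reported
#' as one-sided (`NA` ratio with a reason code), never as infinite.
#'
#' @param rel A [relative_abundance()] matrix (rRNA survey by default —
#'   the template whose composition the zone analysis describes).
#' @param records Activity records from [activity_ratios()].
#' @param tax Taxonomy data frame.
#' @param split A [define_zone()] result.
#' @param share_threshold Minimum fraction of total mesopelagic reads a
#'   group must hold to be reported (strict inequality; default 5e-4,
#'   i.e. 0.05%).
#' @param abundance_stat,activity_stat Aggregation statistics, `"mean"`
#'   or `"median"` (defaults mean and median respectively; the choice is
#'   configurable because either is defensible).
#' @return Data frame with one row per group: `group`,
#'   `mesopelagic_share`, `abundance_ratio`, `activity_ratio`,
#'   `included`, `reason` (`"ok"`, `"zone_absent"`,
#'   `"complement_absent"`, `"no_activity_records"`).
#' @export
zone_contrast <- function(rel, records, tax, split, share_threshold = 5e-4,
                          abundance_stat = c("mean", "median"),
                          activity_stat = c("median", "mean")) {
  abundance_stat <- get(match.arg(abundance_stat))
  activity_stat <- get(match.arg(activity_stat))
  meso_ids <- intersect(colnames(rel),
                        c(split$zone_sample_ids, split$complement_sample_ids))
  zone_ids <- intersect(colnames(rel), split$zone_sample_ids)
  comp_ids <- setdiff(meso_ids, zone_ids)
  if (!length(zone_ids) || !length(comp_ids))
    stop("relative-abundance table lacks samples on one side of the split")
  g <- aggregate_by_group(rel[, meso_ids, drop = FALSE], tax)
  share <- rowMeans(g)  # equal-depth samples: mean proportion = read share
  records$side <- zone_membership(records, split)
  records <- records[!is.na(records$side), ]
  rows <- lapply(rownames(g), function(grp) {
    zv <- g[grp, zone_ids]
    cv <- g[grp, comp_ids]
    ab_zone <- abundance_stat(zv)
    ab_comp <- abundance_stat(cv)
    reason <- if (ab_zone == 0) "zone_absent" else
      if (ab_comp == 0) "complement_absent" else "ok"
    rz <- records$ratio[records$group == grp & records$side == "zone"]
    rc <- records$ratio[records$group == grp & records$side == "complement"]
    act <- if (length(rz) && length(rc))
      activity_stat(rz) / activity_stat(rc) else NA_real_
    if (reason == "ok" && is.na(act)) reason <- "no_activity_records"
    data.frame(group = grp, mesopelagic_share = share[grp],
               abundance_ratio = if (reason %in% c("zone_absent", "complement_absent"))
                 NA_real_ else ab_zone / ab_comp,
               activity_ratio = act,
               included = share[grp] > share_threshold,
               reason = reason)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(-out$abundance_ratio, na.last = TRUE), ]
  out[out$included, , drop = FALSE]
}

#' Richness contrast between a zone and the rest of the mesopelagic
#'
#' Two-sided Wilcoxon rank-sum test of per-sample OTU richness (computed
#' on rarefied counts) between the zone and complement samples.
#'
#' @param x A rarefied [otu_table()] (one template).
#' @param split A [define_zone()] result.
#' @return List with `median_zone`, `median_complement`, `p_value`,
#'   `n_zone`, `n_complement` and the per-sample richness vectors.
#' @export
zone_richness_contrast <- function(x, split) {
  zone_ids <- intersect(colnames(x), split$zone_sample_ids)
  comp_ids <- intersect(colnames(x), split$complement_sample_ids)
  if (length(zone_ids) < 2 || length(comp_ids) < 2)
    stop("need at least two samples on each side of the split")
  rz <- richness(strip_table_class(x)[, zone_ids, drop = FALSE])
  rc <- richness(strip_table_class(x)[, comp_ids, drop = FALSE])
  p <- suppressWarnings(stats::wilcox.test(rz, rc,
                                           alternative = "two.sided"))$p.value
  if (is.nan(p)) p <- 1  # fully tied data carry no evidence
  list(median_zone = stats::median(rz), median_complement = stats::median(rc),
       p_value = p, n_zone = length(rz), n_complement = length(rc),
       richness_zone = rz, richness_complement = rc)
}
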