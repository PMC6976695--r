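#' Pipeline configuration
#'
#' Collects every input path and tunable threshold of the end-to-end
#' analysis in one validated list. Unknown arguments are rejected, and
#' every parameter is echoed into the run manifest so any output can be
#' traced back to its settings.
#'
#' @param otu_table,metadata,taxonomy,tree Input file paths (`tree`
#'   optional; the phylo stage requires it).
#' @param out_dir Output directory.
#' @param rarefaction_depth Reads per sample after rarefaction; `NULL`
#'   (default) uses the minimum column sum per template table.
#' @param seed Integer seed governing every stochastic stage.
#' @param omz_threshold Oxygen cutoff (mg O2/L) for the OMZ flag.
#' @param activity_band Length-2 `(low, high)` band for
#'   [classify_activity()].
#' @param alpha Significance level for layer contrasts.
#' @param share_threshold Mesopelagic read-share filter for
#'   [zone_contrast()].
#' @param gunifrac_alpha Generalized UniFrac alpha.
#' @param n_perm_anosim,n_perm_permanova Permutation counts.
#' @param min_reads Total-read filter for [layer_restricted_otus()].
#' @param bounds A [layer_boundaries()] list.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(otu_table, metadata, taxonomy, tree = NULL,
                            out_dir = "picodepth_out",
                            rarefaction_depth = NULL, seed = 1L,
                            omz_threshold = 2, activity_band = c(0.5, 2),
                            alpha = 0.05, share_threshold = 5e-4,
                            gunifrac_alpha = 0.5, n_perm_anosim = 1000,
                            n_perm_permanova = 999, min_reads = 5,
                            bounds = layer_boundaries()) {
  cfg <- list(otu_table = otu_table, metadata = metadata,
              taxonomy = taxonomy, tree = tree, out_dir = out_dir,
              rarefaction_depth = rarefaction_depth, seed = as.integer(seed),
              omz_threshold = omz_threshold, activity_band = activity_band,
              alpha = alpha, share_threshold = share_threshold,
              gunifrac_alpha = gunifrac_alpha,
              n_perm_anosim = n_perm_anosim,
              n_perm_permanova = n_perm_permanova, min_reads = min_reads,
              bounds = bounds)
  stopifnot(omz_threshold > 0, alpha > 0, alpha < 1,
            share_threshold >= 0, gunifrac_alpha >= 0, gunifrac_alpha <= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

write_stage_tsv <- function(df, path, cfg, extra = character()) {
  hdr <- c(paste0("# seed=", cfg$seed,
                  " omz_threshold=", cfg$omz_threshold,
                  " activity_band=", paste(cfg$activity_band, collapse = ","),
                  " alpha=", cfg$alpha),
           extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: read inputs, rarefy, split by template, alpha/beta
#' diversity (Shannon, richness, Bray-Curtis, NMDS, ANOSIM photic vs
#' aphotic, PERMANOVA on environmental terms), rRNA:rDNA activity
#' (ratios, classification, layer contrasts, layer of maximum activity),
#' horizontal structure (dissimilarity distributions, prevalence curves,
#' layer-restricted and shared OTUs), OMZ/DSL zone contrasts, and —
#' when a tree is configured — generalized UniFrac distances among
#' layer-preferential OTU sets. Each stage writes a TSV under
#' `out_dir`; a YAML manifest records every parameter, seed and stage.
#' Reruns with the same config and seed are byte-identical.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with all in-memory stage results plus
#'   `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  res <- list()
  completed <- character()

  stage("read", {
    res$table <- read_otu_table(cfg$otu_table)
    res$meta <- read_metadata(cfg$metadata, omz_threshold = cfg$omz_threshold,
                              bounds = cfg$bounds)
    res$tax <- read_taxonomy(cfg$taxonomy)
  })
  completed <- c(completed, "read")

  stage("rarefy", {
    depth <- if (is.null(cfg$rarefaction_depth)) min(colSums(res$table))
             else cfg$rarefaction_depth
    res$rarefied_all <- rarefy(res$table, depth = depth, seed = cfg$seed)
  })
  completed <- c(completed, "rarefy")

  stage("split", {
    res$rarefied <- split_by_template(res$rarefied_all, res$meta)
    res$rel <- lapply(res$rarefied, relative_abundance)
  })
  completed <- c(completed, "split")

  stage("diversity", {
    res$alpha_div <- do.call(rbind, lapply(PICO_TEMPLATES, function(t) {
      tab <- res$rarefied[[t]]
      data.frame(sample_id = colnames(tab), template = t,
                 shannon = shannon(strip_table_class(tab)),
                 richness = richness(strip_table_class(tab)))
    }))
    res$bray <- lapply(res$rel, bray_curtis)
    res$nmds <- lapply(res$bray, nmds, seed = cfg$seed)
    res$anosim_photic <- lapply(PICO_TEMPLATES, function(t) {
      m <- res$meta[match(labels(res$bray[[t]]), res$meta$sample_id), ]
      anosim_test(res$bray[[t]],
                  ifelse(m$layer %in% c("surface", "DCM"), "photic", "aphotic"),
                  n_perm = cfg$n_perm_anosim, seed = cfg$seed)
    })
    names(res$anosim_photic) <- PICO_TEMPLATES
    res$permanova <- lapply(PICO_TEMPLATES, function(t) {
      m <- res$meta[match(labels(res$bray[[t]]), res$meta$sample_id), ]
      terms <- intersect(c("light", "temperature_C", "oxygen_mg_L",
                           "ocean", "depth_m"), names(m))
      permanova(res$bray[[t]], m, terms = terms,
                n_perm = cfg$n_perm_permanova, seed = cfg$seed)
    })
    names(res$permanova) <- PICO_TEMPLATES
    write_stage_tsv(res$alpha_div,
                    file.path(cfg$out_dir, "alpha_diversity.tsv"), cfg)
    write_stage_tsv(do.call(rbind, lapply(PICO_TEMPLATES, function(t)
      cbind(template = t, res$permanova[[t]]))),
      file.path(cfg$out_dir, "permanova.tsv"), cfg)
  })
  completed <- c(completed, "diversity")

  stage("activity", {
    res$pairs <- pair_samples(res$meta)
    keep <- res$pairs$rdna_sample_id %in% colnames(res$rel$rDNA) &
      res$pairs$rrna_sample_id %in% colnames(res$rel$rRNA)
    res$records <- activity_ratios(res$rel$rDNA, res$rel$rRNA,
                                   res$pairs[keep, ], res$tax)
    res$records$class <- classify_activity(res$records$ratio,
                                           band = cfg$activity_band)
    res$contrasts <- layer_contrasts(res$records, alpha = cfg$alpha)
    res$max_activity <- layer_of_max_activity(res$records)
    write_stage_tsv(res$records[, c("otu_id", "station", "depth_m", "layer",
                                    "group", "ratio", "class")],
                    file.path(cfg$out_dir, "activity_records.tsv"), cfg)
    write_stage_tsv(res$max_activity,
                    file.path(cfg$out_dir, "layer_of_max_activity.tsv"), cfg)
  })
  completed <- c(completed, "activity")

  stage("biogeography", {
    res$layer_bray <- lapply(res$bray, layer_dissimilarity_distributions,
                             meta = res$meta)
    res$prevalence <- lapply(res$rarefied, prevalence_curves, meta = res$meta)
    res$restricted <- lapply(res$rarefied, layer_restricted_otus,
                             meta = res$meta, min_reads = cfg$min_reads)
    res$shared <- lapply(res$rarefied, shared_otu_matrix, meta = res$meta)
    restr <- do.call(rbind, lapply(PICO_TEMPLATES, function(t)
      data.frame(template = t, layer = PICO_LAYERS,
                 n_restricted = vapply(res$restricted[[t]],
                                       function(l) length(l$otus), integer(1)),
                 fraction = vapply(res$restricted[[t]],
                                   function(l) l$fraction, numeric(1)))))
    write_stage_tsv(restr,
                    file.path(cfg$out_dir, "layer_restricted_otus.tsv"), cfg,
                    extra = paste0("# min_reads=", cfg$min_reads))
  })
  completed <- c(completed, "biogeography")

  stage("zones", {
    res$zones <- lapply(c(OMZ = "OMZ", DSL = "DSL"), function(z) {
      split <- tryCatch(define_zone(res$meta, z), error = function(e) NULL)
      if (is.null(split)) return(NULL)
      list(split = split,
           contrast = zone_contrast(res$rel$rRNA, res$records, res$tax,
                                    split,
                                    share_threshold = cfg$share_threshold),
           richness = zone_richness_contrast(res$rarefied$rRNA, split))
    })
    for (z in names(res$zones))
      if (!is.null(res$zones[[z]]))
        write_stage_tsv(res$zones[[z]]$contrast,
                        file.path(cfg$out_dir,
                                  paste0("zone_contrast_", z, ".tsv")), cfg,
                        extra = paste0("# share_threshold=",
                                       cfg$share_threshold))
  })
  completed <- c(completed, "zones")

  if (!is.null(cfg$tree)) {
    stage("phylo", {
      if (!file.exists(cfg$tree))
        stop("tree file not found: ", cfg$tree)
      res$tree <- read_newick(cfg$tree)
      sets <- layer_abundance_sets(res$max_activity, res$rel$rRNA)
      res$layer_unifrac <- if (length(sets) >= 2)
        layer_phylo_distances(res$tree, sets, alpha = cfg$gunifrac_alpha)
      if (!is.null(res$layer_unifrac))
        write_stage_tsv(data.frame(layer = rownames(res$layer_unifrac),
                                   res$layer_unifrac, check.names = FALSE),
                        file.path(cfg$out_dir, "layer_unifrac.tsv"), cfg,
                        extra = paste0("# gunifrac_alpha=",
                                       cfg$gunifrac_alpha))
    })
    completed <- c(completed, "phylo")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("picodepth")),
    completed_stages = completed,
    parameters = cfg[setdiff(names(cfg), "bounds")],
    layer_boundaries = cfg$bounds)
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yml"))
  res$manifest <- manifest

  invisible(res)
}
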