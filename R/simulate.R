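#' Default depth profile for a simulated station
#'
#' Seven depths per station: surface (3 m), DCM, two mesopelagic and
#' three bathypelagic depths, matching the vertical design of a global
#' depth-stratified survey.
#'
#' @return Data frame with columns `depth_m`, `layer`, `dcm`.
#' @export
default_depths <- function() {
  data.frame(
    depth_m = c(3, 80, 300, 700, 1400, 2500, 4000),
    layer = c("surface", "DCM", "mesopelagic", "mesopelagic",
              "bathypelagic", "bathypelagic", "bathypelagic"),
    dcm = c(FALSE, TRUE, rep(FALSE, 5)))
}

#' Default simulation truth: group roster, depth archetypes and
#' multipliers
#'
#' Encodes the statistical structure the analysis is designed to detect,
#' as the generator's ground truth:
#' * a roster of named picoeukaryote groups, each following one of four
#'   depth-abundance archetypes — increasing with depth, decreasing with
#'   depth, peaking in the mesopelagic, or peaking at the DCM;
#' * per-group rDNA copy-number multipliers (`copy_factor`), with strong
#'   inflation for the MALV-like marine alveolate groups that dominate
#'   DNA surveys;
#' * per-(group, layer) RNA multipliers (`activity_factor`): heterotrophic
#'   groups peak in the mesopelagic (x3) and are depressed in the
#'   bathypelagic (x0.3); phototrophic groups peak at the DCM (x2) and
#'   are halved in the bathypelagic; mixotrophic groups stay at 1.
#'   Because ratios are compositional (both surveys renormalize to 1),
#'   the unaffected mixotrophic groups — which dominate the bathypelagic
#'   — are the reference frame that makes the heterotrophs' signal
#'   observable;
#' * layer-specific between-station compositional drift (`decay_rate`,
#'   log-normal sd), increasing with depth so horizontal dissimilarity
#'   widens in the dark ocean;
#' * OMZ enrichment multipliers for ciliate/dinoflagellate-like groups.
#'
#' All values are generator conventions chosen for testability, not
#' estimates from any survey.
#'
#' @param meso_activity,bathy_activity Activity multipliers applied to
#'   heterotrophic and mixotrophic groups in the mesopelagic and
#'   bathypelagic (defaults 3 and 0.3).
#' @param decay_rate Named numeric, layer -> log-normal drift sd.
#' @param otu_sigma Log-normal sd of OTU masses within a group (default
#'   1). Real amplicon OTU distributions are far heavier-tailed, but the
#'   rare tail biases per-OTU ratio medians toward 1 through detection
#'   conditioning (an OTU must be seen in both templates for a ratio to
#'   exist); at desk scale the default keeps most simulated OTUs
#'   quantifiable in both surveys. Raise it (e.g. to 2.5) together with
#'   a lower sequencing depth to emulate occupancy-driven structure such
#'   as declining prevalence curves.
#' @param seed Integer seed stored with the truth.
#' @return Object of class `"sim_truth"`: list with `groups` (data frame:
#'   `group`, `archetype`, `trophic_mode`, `copy_factor`,
#'   `omz_enrichment`), `activity_factor` (groups x layers matrix),
#'   `decay_rate`, `seed`.
#' @export
sim_truth <- function(meso_activity = 3, bathy_activity = 0.3,
                      decay_rate = c(surface = 0.30, DCM = 0.35,
                                     mesopelagic = 0.60, bathypelagic = 1.00),
                      otu_sigma = 1, seed = 1L) {
  groups <- data.frame(
    group = c("Chrysophyceae", "Bicosoecida", "RAD-B",
              "Dinoflagellata", "Ciliophora", "MAST-3", "MAST-4", "Picozoa",
              "Labyrinthulomycetes", "RAD-C", "MALV-IV", "MALV-I", "MALV-II",
              "Pelagophyceae", "Mamiellophyceae", "Telonema",
              "Cryptomonadales"),
    archetype = c(rep("increase_with_depth", 3),
                  rep("decrease_with_depth", 5),
                  rep("meso_peak", 5),
                  rep("dcm_peak", 4)),
    trophic_mode = c("mixotrophic", "heterotrophic", "mixotrophic",
                     "mixotrophic", "heterotrophic", "heterotrophic",
                     "heterotrophic", "heterotrophic",
                     "heterotrophic", "heterotrophic", "heterotrophic",
                     "heterotrophic", "heterotrophic",
                     "phototrophic", "phototrophic", "heterotrophic",
                     "phototrophic"),
    copy_factor = 1,
    omz_enrichment = 1)
  groups$copy_factor[groups$group == "MALV-I"] <- 10
  groups$copy_factor[groups$group == "MALV-II"] <- 8
  groups$omz_enrichment[groups$group %in%
    c("Ciliophora", "Dinoflagellata", "MALV-II")] <- 4
  act <- matrix(1, nrow(groups), length(PICO_LAYERS),
                dimnames = list(groups$group, PICO_LAYERS))
  het <- groups$trophic_mode == "heterotrophic"
  photo <- groups$trophic_mode == "phototrophic"
  act[het, "mesopelagic"] <- meso_activity
  act[het, "bathypelagic"] <- bathy_activity
  act[photo, "DCM"] <- 2
  act[photo, "bathypelagic"] <- 0.5
  stopifnot(all(act > 0), all(groups$copy_factor > 0), otu_sigma >= 0,
            all(decay_rate >= 0), setequal(names(decay_rate), PICO_LAYERS))
  structure(list(groups = groups, activity_factor = act,
                 decay_rate = decay_rate, otu_sigma = otu_sigma,
                 seed = as.integer(seed)),
            class = "sim_truth")
}

#' Neutral simulation truth
#'
#' All copy, activity and OMZ multipliers set to 1 and (optionally) zero
#' between-station drift: rDNA and rRNA expectations coincide and only
#' multinomial read noise remains. Used for null-calibration tests.
#'
#' @param drift If `FALSE` (default), set all layer drift rates to zero.
#' @inheritParams sim_truth
#' @return A `"sim_truth"` object.
#' @export
neutral_truth <- function(drift = FALSE, seed = 1L) {
  tr <- sim_truth(meso_activity = 1, bathy_activity = 1, seed = seed)
  tr$activity_factor[] <- 1
  tr$groups$copy_factor[] <- 1
  tr$groups$omz_enrichment[] <- 1
  if (!drift) tr$decay_rate[] <- 0
  tr
}

ARCHETYPE_WEIGHTS <- rbind(
  increase_with_depth = c(surface = 0.5, DCM = 0.7, mesopelagic = 2.0,
                          bathypelagic = 4.0),
  decrease_with_depth = c(4.0, 3.0, 1.0, 0.30),
  meso_peak           = c(0.7, 0.8, 3.0, 0.70),
  dcm_peak            = c(1.5, 4.0, 0.5, 0.15))

#' Build a simulated sampling design and its metadata
#'
#' Lays out `n_stations` stations across three ocean basins, each sampled
#' at the given depths with both an rDNA and an rRNA template, and
#' generates environmental covariates consistent with the layer
#' structure: light present only in the photic layers, temperature
#' decreasing and nutrients increasing with depth, low oxygen only at the
#' mesopelagic depths of the designated OMZ stations, DSL flagged at the
#' upper mesopelagic depth of the designated DSL stations, and water-mass
#' fractions shifting from central to deep masses with depth.
#'
#' @param n_stations Number of stations (default 13).
#' @param depths Data frame as [default_depths()].
#' @param oceans Ocean label per station (recycled; default spreads
#'   stations across Atlantic, Indian and Pacific).
#' @param omz_stations Station indices whose mesopelagic lies in an OMZ
#'   (default: three Pacific stations).
#' @param dsl_stations Station indices with a DSL sample (default: nine
#'   stations).
#' @param reads_per_sample Sequencing depth per sample (default 25000).
#' @param n_otus_per_group OTUs simulated per taxonomic group
#'   (default 40, i.e. a 680-OTU roster at the default group list).
#' @param seed Integer seed for the environmental noise.
#' @return Object of class `"sim_design"`: list with `meta` (one row per
#'   sample, both templates), `n_stations`, `depths`,
#'   `reads_per_sample`, `n_otus_per_group`.
#' @export
sim_design <- function(n_stations = 13, depths = default_depths(),
                       oceans = NULL, omz_stations = NULL,
                       dsl_stations = NULL, reads_per_sample = 25000,
                       n_otus_per_group = 40, seed = 1L) {
  if (n_stations < 2) stop("need at least two stations")
  if (!nrow(depths)) stop("empty depth list")
  stations <- sprintf("st%02d", seq_len(n_stations))
  if (is.null(oceans))
    oceans <- rep(c("Atlantic", "Indian", "Pacific"),
                  length.out = n_stations)
  oceans <- rep_len(oceans, n_stations)
  if (is.null(omz_stations))
    omz_stations <- utils::head(which(oceans == "Pacific"), 3)
  if (is.null(dsl_stations))
    dsl_stations <- utils::head(seq_len(n_stations), 9)
  grid <- expand.grid(depth_i = seq_len(nrow(depths)),
                      station_i = seq_len(n_stations))
  meta <- withr::with_seed(seed, {
    depth <- depths$depth_m[grid$depth_i]
    layer <- depths$layer[grid$depth_i]
    omz_here <- grid$station_i %in% omz_stations & layer == "mesopelagic"
    # DSL: shallowest mesopelagic depth of designated stations
    meso_depths <- depths$depth_m[depths$layer == "mesopelagic"]
    meso_top <- if (length(meso_depths)) min(meso_depths) else -1
    data.frame(
      station = stations[grid$station_i],
      depth_m = depth,
      layer = layer,
      ocean = oceans[grid$station_i],
      temperature_C = round(pmax(2, 27 * exp(-depth / 350) + 2) +
                              stats::rnorm(nrow(grid), 0, 0.3), 2),
      salinity = round(35 + stats::rnorm(nrow(grid), 0, 0.2), 2),
      oxygen_mg_L = round(ifelse(omz_here,
                                 stats::runif(nrow(grid), 0.3, 1.5),
                                 stats::runif(nrow(grid), 4, 7)), 2),
      no3_uM = round(pmin(40, 0.5 + depth / 120) +
                       stats::rnorm(nrow(grid), 0, 0.4), 2),
      light = layer %in% c("surface", "DCM"),
      dsl = grid$station_i %in% dsl_stations & depth == meso_top)
  })
  meta$sublayer <- assign_sublayer(meta$depth_m, meta$layer)
  # deep-water-mass mixture: central water above, deep water below
  frac_deep <- round(pmin(1, pmax(0, (meta$depth_m - 200) / 3000)), 4)
  meta$wm_central <- 1 - frac_deep
  meta$wm_deep <- frac_deep
  meta <- meta[rep(seq_len(nrow(meta)), each = 2), ]
  meta$template <- rep(PICO_TEMPLATES, length.out = nrow(meta))
  meta$sample_id <- paste(meta$station, paste0(meta$depth_m, "m"),
                          meta$template, sep = "_")
  meta$omz <- meta$oxygen_mg_L < 2
  rownames(meta) <- NULL
  meta <- meta[, c("sample_id", "station", "depth_m", "layer", "sublayer",
                   "ocean", "template", "temperature_C", "salinity",
                   "oxygen_mg_L", "no3_uM", "light", "dsl", "omz",
                   "wm_central", "wm_deep")]
  structure(list(meta = meta, n_stations = n_stations, depths = depths,
                 reads_per_sample = reads_per_sample,
                 n_otus_per_group = n_otus_per_group),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat("Simulated design: ", x$n_stations, " stations x ", nrow(x$depths),
      " depths = ", x$n_stations * nrow(x$depths),
      " water samples (", nrow(x$meta), " template samples)\n", sep = "")
  invisible(x)
}

#' Simulate paired rDNA/rRNA OTU tables under a design and truth
#'
#' Generative model, per water sample (station-depth):
#' 1. each group's expected mass in a layer comes from its archetype
#'    weight;
#' 2. OTU masses are drawn log-normally within the group once (the
#'    reference community), then perturbed per sample by log-normal
#'    between-station drift with layer-specific sd (`decay_rate`), so
#'    horizontal dissimilarity grows with depth;
#' 3. normalizing gives the "cell" proportions of the community;
#' 4. rDNA proportions are proportional to cell proportions times the
#'    group's rDNA copy factor;
#' 5. rRNA proportions are proportional to cell proportions times the
#'    group-by-layer activity factor;
#' 6. in OMZ samples, designated groups' cell proportions are multiplied
#'    by their OMZ enrichment before steps 4-5;
#' 7. reads are drawn multinomially at `reads_per_sample` per sample.
#'    Optionally, Dirichlet-multinomial overdispersion can be switched on
#'    (real amplicon data are overdispersed); it is off by default so the
#'    sampling expectations stay closed-form.
#'
#' @param design A [sim_design()].
#' @param truth A [sim_truth()].
#' @param seed Integer seed (defaults to the truth's seed).
#' @param overdispersion Dirichlet precision; `Inf` (default) means pure
#'   multinomial sampling, smaller values add overdispersion.
#' @return List with `rdna` and `rrna` ([otu_table()]s), `taxonomy`
#'   (data frame), `truth`, `design` and `cell_props` (the latent cell
#'   proportion matrix, OTUs x water samples).
#' @export
simulate_tables <- function(design, truth, seed = truth$seed,
                            overdispersion = Inf) {
  groups <- truth$groups
  n_per <- design$n_otus_per_group
  otu_ids <- sprintf("otu%04d", seq_len(nrow(groups) * n_per))
  tax <- data.frame(otu_id = otu_ids,
                    group = rep(groups$group, each = n_per),
                    trophic_mode = rep(groups$trophic_mode, each = n_per))
  wm <- design$meta[design$meta$template == "rDNA", ]  # one row per water sample
  wm_id <- paste(wm$station, wm$depth_m)
  arch <- ARCHETYPE_WEIGHTS[groups$archetype, , drop = FALSE]
  rownames(arch) <- groups$group
  withr::with_seed(seed, {
    base_mass <- stats::rlnorm(length(otu_ids), 0, truth$otu_sigma)
    cell <- matrix(0, length(otu_ids), nrow(wm),
                   dimnames = list(otu_ids, wm_id))
    rdna <- rrna <- cell
    for (s in seq_len(nrow(wm))) {
      lay <- wm$layer[s]
      w_layer <- arch[tax$group, lay]
      drift <- stats::rlnorm(length(otu_ids), 0, truth$decay_rate[[lay]])
      mass <- base_mass * w_layer * drift
      if (isTRUE(wm$omz[s]))
        mass <- mass * groups$omz_enrichment[match(tax$group, groups$group)]
      if (all(mass == 0)) stop("degenerate truth: all-zero masses")
      pi_s <- mass / sum(mass)
      cell[, s] <- pi_s
      d <- pi_s * groups$copy_factor[match(tax$group, groups$group)]
      r <- pi_s * truth$activity_factor[tax$group, lay]
      rdna[, s] <- d / sum(d)
      rrna[, s] <- r / sum(r)
    }
    draw <- function(p) {
      if (is.finite(overdispersion)) {
        g <- stats::rgamma(length(p), shape = p * overdispersion)
        p <- g / sum(g)
      }
      stats::rmultinom(1, design$reads_per_sample, p)[, 1]
    }
    counts_d <- apply(rdna, 2, draw)
    counts_r <- apply(rrna, 2, draw)
  })
  meta <- design$meta
  id_for <- function(tmpl) meta$sample_id[meta$template == tmpl][
    match(wm_id, paste(meta$station, meta$depth_m)[meta$template == tmpl])]
  colnames(counts_d) <- id_for("rDNA")
  colnames(counts_r) <- id_for("rRNA")
  rownames(counts_d) <- rownames(counts_r) <- otu_ids
  list(rdna = otu_table(counts_d), rrna = otu_table(counts_r),
       taxonomy = tax, truth = truth, design = design, cell_props = cell)
}

#' Simulate a phylogeny with monophyletic taxonomic groups
#'
#' Builds a rooted binary tree whose tips are the OTU ids: each
#' taxonomic group forms a clade (a random binary subtree), and the
#' group clades hang off a ladder backbone. All branch lengths are
#' strictly positive.
#'
#' @param tax Taxonomy data frame (`otu_id`, `group`).
#' @param seed Integer seed.
#' @param backbone_length Branch length scale of the backbone separating
#'   group clades (default 1); within-group branches are shorter, so
#'   OTUs of one group are phylogenetically close.
#' @return An [ape::phylo] object.
#' @export
simulate_tree <- function(tax, seed = 1L, backbone_length = 1) {
  if (nrow(tax) < 2) stop("need at least two OTUs")
  withr::with_seed(seed, {
    clades <- lapply(split(tax$otu_id, tax$group), function(otus) {
      if (length(otus) == 1)
        return(paste0(otus, ":", round(stats::runif(1, 0.05, 0.3), 6)))
      tr <- ape::rtree(length(otus), tip.label = sample(otus))
      tr$edge.length <- stats::runif(nrow(tr$edge), 0.02, 0.3)
      sub(";$", "", ape::write.tree(tr))
    })
    s <- clades[[1]]
    if (length(clades) > 1)
      for (i in seq_along(clades)[-1]) {
        b <- round(stats::runif(2, 0.5, 1.5) * backbone_length, 6)
        s <- paste0("(", s, ":", b[1], ",", clades[[i]], ":", b[2], ")")
      }
    else s <- paste0("(", s, ")")
  })
  ape::read.tree(text = paste0(s, ";"))
}

#' Write a complete simulated dataset to disk
#'
#' Emits the exact TSV/newick formats the readers consume: paired rDNA
#' and rRNA OTU tables, metadata, taxonomy, a phylogeny over the OTUs,
#' and a YAML truth file echoing every generator parameter for
#' parameter-recovery work.
#'
#' @param dir Output directory (created if needed).
#' @param design A [sim_design()] (default design if omitted).
#' @param truth A [sim_truth()] (default truth if omitted).
#' @param seed Integer seed.
#' @return Invisibly, the named list of file paths written.
#' @export
simulate_dataset <- function(dir, design = sim_design(seed = seed),
                             truth = sim_truth(seed = seed), seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_tables(design, truth, seed = seed)
  tree <- simulate_tree(sim$taxonomy, seed = seed + 1L)
  paths <- list(
    combined = file.path(dir, "otu_table.tsv"),
    rdna = file.path(dir, "otu_table_rdna.tsv"),
    rrna = file.path(dir, "otu_table_rrna.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    tree = file.path(dir, "tree.nwk"),
    truth = file.path(dir, "truth.yml"))
  write_otu_table(otu_table(cbind(strip_table_class(sim$rdna),
                                  strip_table_class(sim$rrna))),
                  paths$combined)
  write_otu_table(sim$rdna, paths$rdna)
  write_otu_table(sim$rrna, paths$rrna)
  write_metadata(design$meta, paths$metadata)
  write_taxonomy(sim$taxonomy, paths$taxonomy)
  write_newick(tree, paths$tree)
  write_sim_truth(truth, paths$truth)
  invisible(paths)
}

#' Read or write a simulation truth file
#'
#' The truth file is YAML: group roster with archetypes, trophic modes,
#' copy factors and OMZ enrichments; the activity-factor matrix; layer
#' drift rates; and the seed.
#'
#' @param truth A `"sim_truth"` object.
#' @param path File path.
#' @return `read_sim_truth` returns a `"sim_truth"` object.
#' @export
write_sim_truth <- function(truth, path) {
  yaml::write_yaml(list(
    seed = truth$seed,
    otu_sigma = truth$otu_sigma,
    decay_rate = as.list(truth$decay_rate),
    groups = truth$groups,
    activity_factor = list(
      layers = colnames(truth$activity_factor),
      values = stats::setNames(
        lapply(seq_len(nrow(truth$activity_factor)),
               function(i) as.numeric(truth$activity_factor[i, ])),
        rownames(truth$activity_factor)))), path)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  y <- yaml::read_yaml(path)
  act <- do.call(rbind, y$activity_factor$values)
  colnames(act) <- y$activity_factor$layers
  structure(list(groups = as.data.frame(y$groups),
                 activity_factor = act,
                 decay_rate = unlist(y$decay_rate),
                 otu_sigma = y$otu_sigma,
                 seed = as.integer(y$seed)),
            class = "sim_truth")
}
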