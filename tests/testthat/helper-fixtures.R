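# Small deterministic fixtures, built in code.

fixture_counts <- function() {
  m <- matrix(c(6L, 0L, 2L,
                2L, 2L, 0L,
                1L, 5L, 3L), nrow = 3, byrow = FALSE,
              dimnames = list(c("otuA", "otuB", "otuC"),
                              c("s1", "s2", "s3")))
  otu_table(m)
}

# Paired-template metadata for n_st stations at the given depths.
fixture_meta <- function(n_st = 2,
                         depths = c(3, 80, 300, 700, 1500),
                         oxygen = 6) {
  layers <- assign_layer(depths, dcm = depths == 80)
  grid <- expand.grid(station = sprintf("st%d", seq_len(n_st)),
                      depth_m = depths, template = c("rDNA", "rRNA"),
                      stringsAsFactors = FALSE)
  data.frame(
    sample_id = paste(grid$station, grid$depth_m, grid$template, sep = "_"),
    station = grid$station,
    depth_m = grid$depth_m,
    layer = layers[match(grid$depth_m, depths)],
    ocean = "Atlantic",
    template = grid$template,
    temperature_C = 20 - grid$depth_m / 100,
    salinity = 35,
    oxygen_mg_L = rep_len(oxygen, nrow(grid)),
    light = layers[match(grid$depth_m, depths)] %in% c("surface", "DCM"),
    dsl = FALSE,
    omz = rep_len(oxygen, nrow(grid)) < 2,
    stringsAsFactors = FALSE)
}

# Activity records data frame from vectors (for contrast tests).
fixture_records <- function(ratio, layer, group = "G", otu_id = NULL,
                            station = "st1", depth_m = 500) {
  n <- length(ratio)
  data.frame(otu_id = if (is.null(otu_id)) sprintf("o%03d", seq_len(n))
             else otu_id,
             station = rep_len(station, n), depth_m = rep_len(depth_m, n),
             layer = layer, group = rep_len(group, n), ratio = ratio)
}

# Independent generalized-UniFrac oracle: explicit recursion from the
# root collecting descendant tip sets per branch (no shared code with
# picodepth::gunifrac, which uses a flat postorder accumulation).
oracle_gunifrac <- function(tree, p_a, p_b, alpha) {
  tips_below <- function(node) {
    if (node <= length(tree$tip.label)) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  num <- den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tips_below(tree$edge[e, 2])
    pa <- sum(p_a[intersect(names(p_a), tips)])
    pb <- sum(p_b[intersect(names(p_b), tips)])
    if (pa + pb == 0) next
    w <- tree$edge.length[e] * (pa + pb)^alpha
    num <- num + w * abs(pa - pb) / (pa + pb)
    den <- den + w
  }
  num / den
}

# Clarke's ANOSIM R computed directly from the rank matrix (independent
# of vegan): (mean between-rank - mean within-rank) / (M/2), mid-ranks.
oracle_anosim_R <- function(d, grouping) {
  r <- rank(as.vector(d))
  m <- as.matrix(stats::as.dist(d))
  n <- nrow(m)
  same <- outer(grouping, grouping, "==")[lower.tri(m)]
  M <- n * (n - 1) / 2
  (mean(r[!same]) - mean(r[same])) / (M / 2)
}
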