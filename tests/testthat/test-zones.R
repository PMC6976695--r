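# Metadata reproducing the survey's mesopelagic bookkeeping: 31 water
# samples, 8 below the oxygen threshold, 9 flagged DSL.
zone_meta <- function() {
  n <- 31
  meta <- data.frame(
    sample_id = sprintf("m%02d_rRNA", 1:n),
    station = sprintf("st%02d", 1:n),
    depth_m = 500,
    layer = "mesopelagic",
    ocean = "Pacific",
    template = "rRNA",
    temperature_C = 10, salinity = 35,
    oxygen_mg_L = c(rep(1.0, 8), rep(6, n - 8)),
    light = FALSE,
    dsl = c(rep(FALSE, 8), rep(TRUE, 9), rep(FALSE, n - 17)),
    stringsAsFactors = FALSE)
  meta$omz <- meta$oxygen_mg_L < 2
  rdna <- meta
  rdna$template <- "rDNA"
  rdna$sample_id <- sub("rRNA", "rDNA", meta$sample_id)
  rbind(meta, rdna)
}

test_that("zone definition reproduces the 8/23 OMZ and 9/22 DSL splits", {
  meta <- zone_meta()
  omz <- define_zone(meta, "OMZ")
  expect_equal(nrow(omz$zone), 8)
  expect_equal(nrow(omz$complement), 23)
  # both templates of a water sample fall on the same side
  expect_length(omz$zone_sample_ids, 16)
  dsl <- define_zone(meta, "DSL")
  expect_equal(nrow(dsl$zone), 9)
  expect_equal(nrow(dsl$complement), 22)
  # empty zone and empty complement are errors
  oxic <- meta
  oxic$omz <- FALSE
  expect_error(define_zone(oxic, "OMZ"), "empty zone")
  anoxic <- meta
  anoxic$omz <- TRUE
  expect_error(define_zone(anoxic, "OMZ"), "empty complement")
  expect_error(define_zone(meta[meta$layer != "mesopelagic", ], "OMZ"),
               "no mesopelagic")
})

zone_fixture <- function(seed = 37, enrich = 1) {
  meta <- zone_meta()
  rrna <- meta[meta$template == "rRNA", ]
  set.seed(seed)
  n_otu <- 30
  tax <- data.frame(otu_id = sprintf("o%02d", 1:n_otu),
                    group = rep(c("Ciliophora", "Chrysophyceae", "MAST-4"),
                                each = 10))
  base <- rlnorm(n_otu, 0, 0.5)
  counts <- sapply(seq_len(nrow(rrna)), function(i) {
    w <- base
    if (rrna$omz[i]) w[tax$group == "Ciliophora"] <- w[tax$group == "Ciliophora"] * enrich
    rmultinom(1, 2000, w / sum(w))[, 1]
  })
  dimnames(counts) <- list(tax$otu_id, rrna$sample_id)
  list(meta = meta, rrna = rrna, tax = tax, tab = otu_table(counts))
}

test_that("zone contrast computes abundance and activity ratios with the share filter", {
  fx <- zone_fixture(enrich = 6)
  split <- define_zone(fx$meta, "OMZ")
  rel <- relative_abundance(fx$tab)
  # activity records: elevated ratios for Ciliophora inside the zone
  set.seed(11)
  recs <- do.call(rbind, lapply(seq_len(nrow(fx$rrna)), function(i)
    fixture_records(rlnorm(30, ifelse(fx$rrna$omz[i] &
                                        fx$tax$group == "Ciliophora",
                                      log(2), 0), 0.1),
                    "mesopelagic", group = fx$tax$group,
                    otu_id = fx$tax$otu_id,
                    station = fx$rrna$station[i], depth_m = 500)))
  zc <- zone_contrast(rel, recs, fx$tax, split)
  cil <- zc[zc$group == "Ciliophora", ]
  expect_gt(cil$abundance_ratio, 1)
  expect_gt(cil$activity_ratio, 1)
  expect_true(all(zc$reason == "ok"))
  # equal group abundance on both sides gives a ratio of 1
  flat <- zone_fixture(enrich = 1, seed = 41)
  relf <- relative_abundance(matrix(rep(c(10L, 30L), 31), 2,
    dimnames = list(c("a", "b"), flat$rrna$sample_id)))
  taxf <- data.frame(otu_id = c("a", "b"), group = c("G1", "G2"))
  zcf <- zone_contrast(relf, recs[0, ], taxf, split)
  expect_equal(zcf$abundance_ratio, c(1, 1))
  expect_equal(unique(zcf$reason), "no_activity_records")
})

test_that("share filter is strict and one-sided groups get reason codes", {
  meta <- zone_meta()
  split <- define_zone(meta, "OMZ")
  rrna_ids <- meta$sample_id[meta$template == "rRNA"]
  zone_ids <- intersect(split$zone_sample_ids, rrna_ids)
  m <- matrix(1L, 3, 31, dimnames = list(c("big", "rare", "zonly"), rrna_ids))
  m["big", ] <- 1000L
  m["rare", ] <- 0L
  m["rare", 1:31 %% 2 == 0] <- 1L  # ~0.04% of reads: below the 0.05% cut
  m["zonly", ] <- 0L
  m["zonly", zone_ids] <- 50L
  tax <- data.frame(otu_id = rownames(m), group = rownames(m))
  zc <- zone_contrast(relative_abundance(m), fixture_records(1, "mesopelagic")[0, ],
                      tax, split, share_threshold = 5e-4)
  expect_false("rare" %in% zc$group)
  expect_equal(zc$reason[zc$group == "zonly"], "complement_absent")
  expect_true(is.na(zc$abundance_ratio[zc$group == "zonly"]))
})

test_that("abundance ratios are reciprocal under zone/complement swap", {
  fx <- zone_fixture(enrich = 3)
  split <- define_zone(fx$meta, "OMZ")
  swapped <- split
  swapped$zone <- split$complement
  swapped$complement <- split$zone
  swapped$zone_sample_ids <- split$complement_sample_ids
  swapped$complement_sample_ids <- split$zone_sample_ids
  rel <- relative_abundance(fx$tab)
  empty <- fixture_records(1, "mesopelagic")[0, ]
  a <- zone_contrast(rel, empty, fx$tax, split)
  b <- zone_contrast(rel, empty, fx$tax, swapped)
  b <- b[match(a$group, b$group), ]
  expect_equal(a$abundance_ratio, 1 / b$abundance_ratio, tolerance = 1e-12)
})

test_that("zone richness contrast detects a larger OTU pool and is sign-symmetric", {
  meta <- zone_meta()
  split <- define_zone(meta, "OMZ")
  rrna_ids <- meta$sample_id[meta$template == "rRNA"]
  zone_ids <- intersect(split$zone_sample_ids, rrna_ids)
  set.seed(43)
  # zone samples draw from a pool twice the size
  pool_small <- 40
  pool_big <- 80
  counts <- sapply(rrna_ids, function(s) {
    k <- if (s %in% zone_ids) pool_big else pool_small
    x <- integer(pool_big)
    x[seq_len(k)] <- rmultinom(1, 500, rep(1, k))[, 1]
    x
  })
  rownames(counts) <- sprintf("o%02d", seq_len(pool_big))
  res <- zone_richness_contrast(otu_table(counts), split)
  expect_gt(res$median_zone, res$median_complement)
  expect_lt(res$p_value, 0.05)
  # swapping the sides flips the sign of the median difference
  swapped <- split
  swapped$zone_sample_ids <- split$complement_sample_ids
  swapped$complement_sample_ids <- split$zone_sample_ids
  res2 <- zone_richness_contrast(otu_table(counts), swapped)
  expect_equal(res2$median_zone - res2$median_complement,
               -(res$median_zone - res$median_complement))
  expect_equal(res2$p_value, res$p_value)
  # identical richness on both sides: no signal
  flat <- counts
  flat[] <- 5L
  resf <- suppressWarnings(zone_richness_contrast(otu_table(flat), split))
  expect_equal(resf$median_zone - resf$median_complement, 0)
  expect_gt(resf$p_value, 0.9)
})
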