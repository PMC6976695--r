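test_that("OTU table TSV round trip is the identity and errors are located", {
  tab <- fixture_counts()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tab, path)
  back <- read_otu_table(path)
  expect_identical(unclass(back), unclass(tab))
  expect_equal(dim(back), c(3L, 3L))

  # duplicate sample header is rejected by name
  writeLines(c("otu_id\ts1\ts1", "otuA\t1\t2"), path)
  expect_error(read_otu_table(path), "duplicate sample id.*s1")

  # non-integer and negative cells are rejected with coordinates
  writeLines(c("otu_id\ts1\ts2", "otuA\t1\t2.5"), path)
  expect_error(read_otu_table(path), "otuA.*s2")
  writeLines(c("otu_id\ts1\ts2", "otuA\t1\t-2"), path)
  expect_error(read_otu_table(path), "otuA.*s2")
})

test_that("otu_table enforces id uniqueness and non-empty samples", {
  m <- matrix(1L, 2, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(otu_table(m), "duplicate OTU")
  m <- matrix(c(1L, 0L, 0L, 0L), 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(otu_table(m), "zero reads.*s2")
})

test_that("metadata reader derives the OMZ flag with strict inequality", {
  meta <- fixture_meta(n_st = 1, depths = c(300, 500, 700),
                       oxygen = c(1.5, 2.0, 6.3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(meta[names(meta) != "omz"], path)
  back <- read_metadata(path)
  expect_equal(back$omz[match(c(300, 500, 700), back$depth_m)],
               c(TRUE, FALSE, FALSE))
  # threshold is configurable
  expect_true(all(read_metadata(path, omz_threshold = 7)$omz))
  # missing required column
  write_metadata(meta[!names(meta) %in% c("omz", "oxygen_mg_L")], path)
  expect_error(read_metadata(path), "oxygen_mg_L")
  # unparsable enum
  bad <- meta
  bad$layer[1] <- "abyssopelagic"
  write_metadata(bad, path)
  expect_error(read_metadata(path), "layer")
})

test_that("metadata round trip preserves content and water masses must sum to 1", {
  meta <- fixture_meta()
  meta$wm_central <- 0.25
  meta$wm_deep <- 0.75
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(meta[names(meta) != "omz"], path)
  back <- read_metadata(path)
  expect_equal(back$sample_id, meta$sample_id)
  expect_equal(back$depth_m, meta$depth_m)
  expect_equal(back$wm_deep, meta$wm_deep)
  meta$wm_deep <- 0.80
  write_metadata(meta[names(meta) != "omz"], path)
  expect_error(read_metadata(path), "water-mass")
})

test_that("layer assignment follows the depth boundaries and sublayer splits", {
  expect_equal(assign_layer(c(3, 80, 300, 1500), dcm = c(F, T, F, F)),
               c("surface", "DCM", "mesopelagic", "bathypelagic"))
  expect_equal(assign_sublayer(c(300, 700, 1500, 2500),
                               c("mesopelagic", "mesopelagic",
                                 "bathypelagic", "bathypelagic")),
               c("meso_upper", "meso_lower", "bathy_upper", "bathy_lower"))
})

test_that("rarefaction returns exact depth, drops shallow samples, is deterministic", {
  set.seed(42)
  m <- matrix(rpois(60, 40), 6, 10,
              dimnames = list(sprintf("o%d", 1:6), sprintf("s%d", 1:10)))
  m[, 1] <- c(10L, 0L, 0L, 0L, 0L, 0L)  # shallow sample
  tab <- otu_table(m)
  expect_message(r <- rarefy(tab, depth = 100, seed = 7), "dropping 1 sample")
  expect_true(all(colSums(r) == 100))
  expect_equal(attr(r, "dropped_samples"), "s1")
  r2 <- suppressMessages(rarefy(tab, depth = 100, seed = 7))
  expect_identical(r, r2)
  r3 <- suppressMessages(rarefy(tab, depth = 100, seed = 8))
  expect_false(identical(unclass(r), unclass(r3)))
  # column whose sum equals depth is returned unchanged
  one <- otu_table(matrix(c(60L, 40L), 2, 1,
                          dimnames = list(c("a", "b"), "s")))
  expect_equal(as.vector(rarefy(one, depth = 100, seed = 1)), c(60, 40))
  expect_error(rarefy(tab, depth = 0), "positive")
  expect_error(rarefy(tab, depth = 1e6), "fewer")
})

test_that("rarefaction subsampling is hypergeometric-unbiased", {
  # 5-OTU fixture; over many seeds the mean subsampled count must match
  # depth * count/total within 4 standard errors
  counts <- c(900L, 50L, 30L, 15L, 5L)
  tab <- otu_table(matrix(counts, 5, 1,
                          dimnames = list(sprintf("o%d", 1:5), "s")))
  depth <- 10
  n_rep <- 1000
  draws <- vapply(seq_len(n_rep), function(s) {
    r <- rarefy(tab, depth = depth, seed = s)
    out <- setNames(numeric(5), rownames(tab))
    out[rownames(r)] <- r[, 1]
    out
  }, numeric(5))
  N <- sum(counts)
  for (i in seq_along(counts)) {
    expected <- depth * counts[i] / N
    # multivariate hypergeometric marginal variance
    v <- depth * (counts[i] / N) * (1 - counts[i] / N) * (N - depth) / (N - 1)
    se <- sqrt(v / n_rep)
    expect_lt(abs(mean(draws[i, ]) - expected), 4 * se)
  }
})

test_that("relative abundance columns sum to one and match exact fractions", {
  tab <- fixture_counts()
  rel <- relative_abundance(tab)
  expect_equal(unname(colSums(rel)), rep(1, 3))
  expect_equal(unname(rel["otuC", "s1"]), 2 / 8)
  two <- relative_abundance(matrix(c(2, 2), 2, 1,
                                   dimnames = list(c("a", "b"), "s")))
  expect_equal(as.vector(two), c(0.5, 0.5))
  expect_equal(224 / 22379, 0.0100094, tolerance = 1e-5)
  m <- matrix(c(1, 0), 1, 2, dimnames = list("a", c("s1", "s2")))
  expect_error(relative_abundance(m), "zero reads")
})

test_that("template split partitions samples without loss", {
  meta <- fixture_meta(n_st = 2, depths = c(3, 300))
  set.seed(1)
  m <- matrix(rpois(40, 20) + 1L, 5, 8,
              dimnames = list(sprintf("o%d", 1:5), meta$sample_id))
  tab <- otu_table(m)
  halves <- split_by_template(tab, meta)
  expect_equal(ncol(halves$rDNA), 4)
  expect_equal(ncol(halves$rRNA), 4)
  expect_setequal(c(colnames(halves$rDNA), colnames(halves$rRNA)),
                  colnames(tab))
  expect_equal(sum(halves$rDNA) + sum(halves$rRNA), sum(tab))
  # single-template input gives an empty second table
  sub <- otu_table(m[, meta$template == "rDNA"])
  halves2 <- split_by_template(sub, meta)
  expect_equal(ncol(halves2$rRNA), 0)
  expect_error(split_by_template(tab, meta[-1, ]), "missing from metadata")
})

test_that("group aggregation conserves per-sample totals and pools unassigned", {
  tab <- fixture_counts()
  tax <- data.frame(otu_id = c("otuA", "otuB"), group = c("G1", "G1"),
                    trophic_mode = "unknown")
  agg <- aggregate_by_group(relative_abundance(tab), tax)
  expect_equal(unname(agg["G1", "s1"]), 6 / 8)
  expect_setequal(rownames(agg), c("G1", "IncertaeSedis Eukaryota"))
  expect_equal(unname(colSums(agg)), rep(1, 3))
  only_un <- aggregate_by_group(tab, data.frame(otu_id = "x", group = "G"))
  expect_equal(rownames(only_un), "IncertaeSedis Eukaryota")
})
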