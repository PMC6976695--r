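#' Construct and validate an OTU count table
#'
#' An OTU table is an integer matrix of read counts with OTUs as rows and
#' samples as columns. Row names are OTU ids, column names are sample ids;
#' both must be unique and non-empty. All counts must be non-negative
#' integers and every sample (column) must contain at least one read.
#'
#' @param counts Numeric matrix of non-negative integer read counts with
#'   unique row names (OTU ids) and column names (sample ids).
#' @return The validated matrix with class `"otu_table"`.
#' @export
otu_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("OTU table must have OTU ids as row names and sample ids as column names")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    stop("duplicate OTU id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer or negative count at OTU '",
         rownames(counts)[bad[1, 1]], "', sample '",
         colnames(counts)[bad[1, 2]], "'")
  empty <- colnames(counts)[colSums(counts) == 0]
  if (length(empty))
    stop("sample(s) with zero reads: ", paste(empty, collapse = ", "))
  storage.mode(counts) <- "integer"
  class(counts) <- c("otu_table", class(counts))
  counts
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table: ", nrow(x), " OTUs x ", ncol(x), " samples, ",
      sum(x), " reads\n", sep = "")
  invisible(x)
}

strip_table_class <- function(x) {
  class(x) <- setdiff(class(x), c("otu_table", "rel_abundance"))
  x
}

#' Read an OTU count table from TSV
#'
#' Expects a tab-separated file whose first column holds OTU ids (header
#' `otu_id`) and whose remaining columns hold integer read counts, one
#' column per sample. Row and column order are preserved.
#'
#' @param path Path to a TSV file.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicate sample id(s) in header of '", path, "': ",
         paste(unique(dup), collapse = ", "))
  df <- utils::read.delim(path, check.names = FALSE, colClasses = c("character", rep("numeric", length(sample_ids))))
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  colnames(counts) <- sample_ids
  otu_table(counts)
}

#' Write an OTU table to TSV
#'
#' @param x An [otu_table()] or relative-abundance matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  df <- data.frame(otu_id = rownames(x), strip_table_class(x),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rarefy an OTU table to even sequencing depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) down to a common depth, so that every retained sample
#' sums exactly to `depth`. Samples with fewer reads than `depth` are
#' dropped with a message and recorded in the `"dropped_samples"`
#' attribute. OTUs left with zero reads everywhere are removed.
#'
#' @param x An [otu_table()].
#' @param depth Target reads per sample; defaults to the minimum column
#'   sum (so no sample is dropped).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return A rarefied [otu_table()] whose columns all sum to `depth`.
#' @export
rarefy <- function(x, depth = min(colSums(x)), seed = 1L) {
  stopifnot(inherits(x, "otu_table"))
  if (length(depth) != 1L || depth <= 0 || depth != round(depth))
    stop("'depth' must be a single positive integer")
  keep <- colSums(x) >= depth
  if (!any(keep)) stop("all samples have fewer than ", depth, " reads")
  dropped <- colnames(x)[!keep]
  if (length(dropped))
    message("rarefy: dropping ", length(dropped), " sample(s) below depth ",
            depth, ": ", paste(dropped, collapse = ", "))
  counts <- strip_table_class(x)[, keep, drop = FALSE]
  # counts are validated integers; vegan's "observed counts" heuristic
  # warning is spurious here
  sub <- withr::with_seed(seed,
    suppressWarnings(vegan::rrarefy(t(counts), sample = depth)))
  out <- t(sub)
  out <- out[rowSums(out) > 0, , drop = FALSE]
  out <- otu_table(out)
  attr(out, "dropped_samples") <- dropped
  attr(out, "rarefaction_depth") <- as.integer(depth)
  out
}

#' Convert counts to per-sample relative abundances
#'
#' Divides each column by its total so every sample sums to 1. Requires
#' every column to contain at least one read.
#'
#' @param x An [otu_table()] (or any non-negative count matrix with ids).
#' @return Numeric matrix of proportions with class `"rel_abundance"`.
#' @export
relative_abundance <- function(x) {
  m <- strip_table_class(as.matrix(x))
  cs <- colSums(m)
  if (any(cs == 0))
    stop("sample(s) with zero reads: ",
         paste(colnames(m)[cs == 0], collapse = ", "))
  p <- sweep(m, 2, cs, "/")
  storage.mode(p) <- "double"
  class(p) <- c("rel_abundance", class(p))
  p
}

#' Split an OTU table by template (rDNA vs rRNA)
#'
#' Partitions the samples of a table into the DNA-derived and RNA-derived
#' surveys according to the metadata `template` column. Every sample in
#' the table must be present in the metadata; no sample is lost or
#' duplicated across the split.
#'
#' @param x An [otu_table()].
#' @param meta Metadata data frame as returned by [read_metadata()].
#' @return Named list with elements `rDNA` and `rRNA`, each an
#'   [otu_table()] (possibly with zero columns).
#' @export
split_by_template <- function(x, meta) {
  missing <- setdiff(colnames(x), meta$sample_id)
  if (length(missing))
    stop("sample(s) missing from metadata: ", paste(missing, collapse = ", "))
  tmpl <- meta$template[match(colnames(x), meta$sample_id)]
  out <- lapply(PICO_TEMPLATES, function(t) {
    m <- strip_table_class(x)[, tmpl == t, drop = FALSE]
    if (ncol(m)) otu_table(m) else m
  })
  names(out) <- PICO_TEMPLATES
  out
}

#' Aggregate an OTU table to taxonomic groups
#'
#' Sums counts (or proportions) of the OTUs belonging to each taxonomic
#' group. OTUs absent from the taxonomy are pooled into the
#' `"IncertaeSedis Eukaryota"` bin, so per-sample totals are conserved
#' exactly.
#'
#' @param x An [otu_table()] or [relative_abundance()] matrix.
#' @param tax Taxonomy data frame with columns `otu_id` and `group`.
#' @return Numeric matrix, groups x samples.
#' @export
aggregate_by_group <- function(x, tax) {
  m <- strip_table_class(as.matrix(x))
  grp <- tax$group[match(rownames(m), tax$otu_id)]
  grp[is.na(grp)] <- PICO_UNASSIGNED
  rowsum(m, group = grp)
}
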