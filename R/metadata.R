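#' Default depth boundaries for water-layer assignment
#'
#' Surface samples lie at or above `surface_max` (m); DCM membership is an
#' explicit metadata flag, not inferred from depth; mesopelagic spans
#' `(meso[1], meso[2]]` and bathypelagic `(bathy[1], bathy[2]]`.
#' `meso_split` and `bathy_split` divide each dark-ocean layer into its
#' upper and lower sublayer.
#'
#' @param surface_max,meso,bathy,meso_split,bathy_split Depth bounds in
#'   meters.
#' @return Named list of boundaries.
#' @export
layer_boundaries <- function(surface_max = 10, meso = c(200, 1000),
                             bathy = c(1000, 4000), meso_split = 500,
                             bathy_split = 2000) {
  list(surface_max = surface_max, meso = meso, bathy = bathy,
       meso_split = meso_split, bathy_split = bathy_split)
}

#' Assign a water layer from depth
#'
#' @param depth_m Depth in meters (vector).
#' @param dcm Logical vector flagging deep-chlorophyll-maximum samples
#'   (DCM depth varies by station, so membership comes from metadata).
#' @param bounds A [layer_boundaries()] list.
#' @return Character vector of layer labels.
#' @export
assign_layer <- function(depth_m, dcm = FALSE, bounds = layer_boundaries()) {
  dcm <- rep_len(dcm, length(depth_m))
  out <- rep(NA_character_, length(depth_m))
  out[depth_m <= bounds$surface_max] <- "surface"
  out[depth_m > bounds$meso[1] & depth_m <= bounds$meso[2]] <- "mesopelagic"
  out[depth_m > bounds$bathy[1] & depth_m <= bounds$bathy[2]] <- "bathypelagic"
  out[dcm] <- "DCM"
  out
}

#' @rdname assign_layer
#' @param layer Layer labels as returned by [assign_layer()].
#' @return For `assign_sublayer`, a character vector splitting the
#'   mesopelagic at `meso_split` and the bathypelagic at `bathy_split`;
#'   photic layers are returned unchanged.
#' @export
assign_sublayer <- function(depth_m, layer, bounds = layer_boundaries()) {
  out <- layer
  meso <- layer == "mesopelagic"
  out[meso] <- ifelse(depth_m[meso] <= bounds$meso_split,
                      "meso_upper", "meso_lower")
  bathy <- layer == "bathypelagic"
  out[bathy] <- ifelse(depth_m[bathy] <= bounds$bathy_split,
                       "bathy_upper", "bathy_lower")
  out
}

REQUIRED_META_COLS <- c("sample_id", "station", "depth_m", "layer", "ocean",
                        "template", "temperature_C", "salinity",
                        "oxygen_mg_L", "light", "dsl")

validate_metadata <- function(meta, bounds = layer_boundaries()) {
  missing <- setdiff(REQUIRED_META_COLS, names(meta))
  if (length(missing))
    stop("metadata missing required column(s): ",
         paste(missing, collapse = ", "))
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  for (col in c("light", "dsl"))
    meta[[col]] <- as.logical(meta[[col]])
  bad <- !meta$layer %in% PICO_LAYERS
  if (any(bad))
    stop("unparsable layer value(s): ",
         paste(unique(meta$layer[bad]), collapse = ", "))
  bad <- !meta$ocean %in% PICO_OCEANS
  if (any(bad))
    stop("unparsable ocean value(s): ",
         paste(unique(meta$ocean[bad]), collapse = ", "))
  bad <- !meta$template %in% PICO_TEMPLATES
  if (any(bad))
    stop("unparsable template value(s): ",
         paste(unique(meta$template[bad]), collapse = ", "))
  if (any(meta$oxygen_mg_L < 0, na.rm = TRUE))
    stop("negative oxygen concentration")
  expected <- assign_layer(meta$depth_m, dcm = meta$layer == "DCM", bounds)
  bad <- which(!is.na(expected) & expected != meta$layer)
  if (length(bad))
    stop("layer inconsistent with depth for sample(s): ",
         paste(meta$sample_id[bad], collapse = ", "))
  wm <- grep("^wm_", names(meta), value = TRUE)
  if (length(wm)) {
    tot <- rowSums(meta[wm], na.rm = TRUE)
    has <- rowSums(!is.na(meta[wm])) > 0
    off <- has & abs(tot - 1) > 1e-6
    if (any(off))
      stop("water-mass fractions do not sum to 1 for sample(s): ",
           paste(meta$sample_id[off], collapse = ", "))
  }
  meta
}

#' Read a sample metadata sheet from TSV
#'
#' The sheet carries one row per sequenced sample (a station-depth-template
#' combination): design fields (station, depth, layer, ocean, template),
#' environmental covariates (temperature, salinity, oxygen, optional
#' nutrient columns), a light presence/absence flag, a deep scattering
#' layer (DSL) flag, and optional water-mass proportion columns prefixed
#' `wm_`. An `omz` column is derived as `oxygen_mg_L < omz_threshold`
#' (strict inequality).
#'
#' @param path Path to a TSV file.
#' @param omz_threshold Oxygen concentration (mg O2 / L) below which a
#'   sample counts as oxygen minimum zone; default 2.
#' @param bounds A [layer_boundaries()] list used to check layer/depth
#'   consistency.
#' @return A data frame, one row per sample, with derived logical `omz`
#'   and a `sublayer` column.
#' @export
read_metadata <- function(path, omz_threshold = 2, bounds = layer_boundaries()) {
  stopifnot(omz_threshold > 0)
  meta <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  meta <- validate_metadata(meta, bounds)
  meta$omz <- meta$oxygen_mg_L < omz_threshold
  if (is.null(meta$sublayer))
    meta$sublayer <- assign_sublayer(meta$depth_m, meta$layer, bounds)
  meta
}

#' Write a metadata sheet to TSV
#'
#' @param meta Metadata data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read or write an OTU taxonomy map
#'
#' Tab-separated with columns `otu_id`, `group` and `trophic_mode`
#' (phototrophic, heterotrophic, mixotrophic or unknown).
#'
#' @param path Path to a TSV file.
#' @return Data frame with one row per OTU.
#' @export
read_taxonomy <- function(path) {
  tax <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("otu_id", "group"), names(tax))
  if (length(missing))
    stop("taxonomy missing column(s): ", paste(missing, collapse = ", "))
  dup <- tax$otu_id[duplicated(tax$otu_id)]
  if (length(dup))
    stop("multiple assignments for OTU(s): ",
         paste(unique(dup), collapse = ", "))
  if (any(!nzchar(tax$group)))
    stop("empty group name in taxonomy")
  if (is.null(tax$trophic_mode)) tax$trophic_mode <- "unknown"
  bad <- !tax$trophic_mode %in% PICO_TROPHIC
  if (any(bad))
    stop("unparsable trophic mode(s): ",
         paste(unique(tax$trophic_mode[bad]), collapse = ", "))
  tax
}

#' @rdname read_taxonomy
#' @param tax Taxonomy data frame.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(tax, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
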