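#' Read an SV count table and its sample metadata
#'
#' The count table is tab-separated with sequence-variant (SV) identifiers in
#' the first column and one column per sample; entries are nonnegative integer
#' read counts. Metadata is tab-separated with required columns `sample_id`,
#' `month`, `depth_m`, `fraction` and optional `zone`; a missing `zone` is
#' derived from `depth_m` (and `month`) via [assign_zone()].
#'
#' @param path path to the count-table TSV.
#' @param meta_path path to the sample-metadata TSV.
#' @param config a [zone_config()] used for zone assignment and month order.
#' @return a list with elements `counts` (integer matrix, SV x sample) and
#'   `meta` (data frame, one row per sample, `month` an ordered factor).
#' @export
read_sv_table <- function(path, meta_path, config = zone_config()) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("count table needs an SV id column plus >= 1 sample")
  sv_ids <- as.character(raw[[1]])
  counts <- as.matrix(raw[, -1, drop = FALSE])
  rownames(counts) <- sv_ids
  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  required <- c("sample_id", "month", "depth_m", "fraction")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  }
  orphan <- setdiff(colnames(counts), meta$sample_id)
  if (length(orphan)) {
    stop("samples in count table without metadata: ",
         paste(orphan, collapse = ", "))
  }
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (is.null(meta$zone)) {
    meta$zone <- assign_zone(meta$depth_m, meta$month, config)
  }
  lev <- if (is.null(config$month_order)) unique(meta$month) else config$month_order
  meta$month <- factor(meta$month, levels = lev, ordered = TRUE)
  list(counts = validate_sv_counts(counts), meta = meta)
}

#' Validate an SV count matrix
#'
#' Checks the container invariants: unique SV and sample identifiers and
#' nonnegative integer counts. Zero rows/columns are permitted.
#'
#' @param counts matrix with SV rownames and sample colnames.
#' @return `counts`, invisibly, coerced to integer storage.
#' @export
validate_sv_counts <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry SV rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate SV id(s): ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample id(s): ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("negative or non-integer count at SV '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  storage.mode(counts) <- "integer"
  invisible(counts)
}

#' Write an SV count table as TSV
#' @param counts SV x sample integer matrix.
#' @param path output path.
#' @export
write_sv_table <- function(counts, path) {
  df <- data.frame(sv_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' Tab-separated with columns `sv_id`, `lineage` (semicolon-delimited rank
#' strings, domain to species) and optional `trophic_flag` (one of
#' `phototroph`, `heterotroph`, `unknown`).
#'
#' @param path path to the taxonomy TSV.
#' @return data frame with columns `sv_id`, `lineage`, `trophic_flag`.
#' @export
read_taxonomy <- function(path) {
  tax <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sv_id", "lineage") %in% names(tax))) {
    stop("taxonomy file must have columns sv_id and lineage")
  }
  if (anyDuplicated(tax$sv_id)) {
    stop("duplicate sv_id in taxonomy: ",
         paste(unique(tax$sv_id[duplicated(tax$sv_id)]), collapse = ", "))
  }
  if (any(is.na(tax$lineage) | !nzchar(tax$lineage))) {
    stop("empty lineage string in taxonomy")
  }
  if (is.null(tax$trophic_flag)) tax$trophic_flag <- "unknown"
  tax
}

#' Write a taxonomy table as TSV
#' @param tax data frame as returned by [read_taxonomy()].
#' @param path output path.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sample metadata as TSV
#' @param meta data frame with at least `sample_id`, `month`, `depth_m`,
#'   `fraction`.
#' @param path output path.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write attribution results as TSV
#' @param attribution data frame from [attribute_temporal()] or
#'   [attribute_vertical()].
#' @param path output path.
#' @export
write_attribution <- function(attribution, path) {
  utils::write.table(attribution, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Select sample ids by metadata
#'
#' Convenience filter used to restrict an analysis to one layer, month or size
#' fraction before attribution.
#'
#' @param meta sample metadata data frame.
#' @param month,zone,fraction optional values to match (each `NULL` = keep all).
#' @param depth_m optional numeric vector; samples whose depth matches any
#'   value (within 0.5 m) are kept.
#' @return character vector of sample ids.
#' @export
select_samples <- function(meta, month = NULL, zone = NULL, fraction = NULL,
                           depth_m = NULL) {
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(month)) keep <- keep & as.character(meta$month) %in% month
  if (!is.null(zone)) keep <- keep & meta$zone %in% zone
  if (!is.null(fraction)) keep <- keep & meta$fraction %in% fraction
  if (!is.null(depth_m)) {
    keep <- keep & vapply(meta$depth_m,
                          function(d) any(abs(d - depth_m) <= 0.5), logical(1))
  }
  meta$sample_id[keep]
}
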