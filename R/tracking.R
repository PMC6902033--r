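#' Filter an SV table to phytoplankton
#'
#' Retains sequence variants whose lineage contains any of the targeted
#' phytoplankton group tokens, then removes variants matching an exclusion
#' token or flagged as heterotrophic. The default inclusion set targets the
#' major eukaryotic phytoplankton divisions; dinoflagellates are excluded by
#' default because the group mixes photo- and heterotrophic species that
#' amplicon data cannot separate.
#'
#' @param counts SV x sample integer matrix.
#' @param tax taxonomy data frame (`sv_id`, `lineage`, optional
#'   `trophic_flag`), covering every SV in `counts`.
#' @param include_groups lineage tokens, at least one of which must occur in a
#'   retained SV's lineage.
#' @param exclude_tokens lineage tokens whose presence removes an SV.
#' @param exclude_heterotrophs drop SVs with `trophic_flag == "heterotroph"`.
#' @return the filtered count matrix (same samples, subset of rows).
#' @export
filter_phytoplankton <- function(counts, tax,
                                 include_groups = c("Archaeplastida",
                                                    "Cryptophyta",
                                                    "Haptophyta",
                                                    "Chlorarachniophyta",
                                                    "Heterokontophyta"),
                                 exclude_tokens = c("Dinoflagellata",
                                                    "Dinophyceae",
                                                    "Syndiniales"),
                                 exclude_heterotrophs = TRUE) {
  if (!length(include_groups)) stop("include_groups must be non-empty")
  missing_tax <- setdiff(rownames(counts), tax$sv_id)
  if (length(missing_tax)) {
    stop("SV(s) without taxonomy: ", paste(missing_tax, collapse = ", "))
  }
  lineage <- tax$lineage[match(rownames(counts), tax$sv_id)]
  trophic <- if (is.null(tax$trophic_flag)) rep("unknown", nrow(counts)) else
    tax$trophic_flag[match(rownames(counts), tax$sv_id)]
  has_token <- function(tokens) {
    Reduce(`|`, lapply(tokens, function(tk) grepl(tk, lineage, fixed = TRUE)),
           accumulate = FALSE)
  }
  keep <- has_token(include_groups)
  if (length(exclude_tokens)) keep <- keep & !has_token(exclude_tokens)
  if (exclude_heterotrophs) keep <- keep & trophic != "heterotroph"
  counts[keep, , drop = FALSE]
}

#' Rarefy an SV table
#'
#' Randomly subsamples each sample's reads without replacement to a common
#' depth, so that each column of the result sums exactly to `depth` and each
#' rarefied count is a multivariate-hypergeometric draw bounded by the
#' original count.
#'
#' @param counts SV x sample integer matrix.
#' @param depth target reads per sample (positive integer).
#' @param seed integer RNG seed.
#' @param drop_below if `TRUE`, samples with fewer than `depth` reads are
#'   dropped; if `FALSE` (default) any such sample is an error.
#' @return the rarefied integer matrix.
#' @export
rarefy <- function(counts, depth, seed = 1L, drop_below = FALSE) {
  counts <- validate_sv_counts(counts)
  if (length(depth) != 1 || !is.finite(depth) || depth <= 0 ||
      depth != round(depth)) {
    stop("depth must be a positive integer")
  }
  totals <- colSums(counts)
  low <- totals < depth
  if (all(low)) stop("all samples have fewer than ", depth, " reads")
  if (any(low)) {
    if (!drop_below) {
      stop("sample(s) below rarefaction depth: ",
           paste(colnames(counts)[low], collapse = ", "))
    }
    counts <- counts[, !low, drop = FALSE]
  }
  set.seed(seed)
  # vegan warns when the smallest nonzero count exceeds 1 (a heuristic that
  # the input may not be raw counts); our inputs are validated counts.
  out <- withCallingHandlers(
    t(vegan::rrarefy(t(counts), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(counts)
  out
}

#' Earliest detection of each SV along an ordered grouping
#'
#' An SV is present in a group when its summed count over the group's samples
#' is positive; its origin is the earliest group (in `order`) where it is
#' present. SVs absent from every group are omitted.
#'
#' @param counts SV x sample matrix.
#' @param order character vector of group labels, earliest first.
#' @param selector named list mapping each label in `order` to a character
#'   vector of sample ids (disjoint groups).
#' @return named character vector: SV id -> origin label.
#' @export
first_detection <- function(counts, order, selector) {
  if (!length(order)) stop("order must be non-empty")
  if (!all(order %in% names(selector))) {
    stop("selector must name every label in order")
  }
  all_samples <- unlist(selector[order], use.names = FALSE)
  if (anyDuplicated(all_samples)) stop("selector groups must be disjoint")
  origin <- rep(NA_character_, nrow(counts))
  for (lab in rev(order)) {
    samples <- selector[[lab]]
    if (!length(samples)) next
    present <- rowSums(counts[, samples, drop = FALSE]) > 0
    origin[present] <- lab
  }
  names(origin) <- rownames(counts)
  origin[!is.na(origin)]
}

# Shared engine: partition each target group's community by origin label.
attribute_origin <- function(counts, order, selector,
                             basis = c("reads", "richness")) {
  basis <- match.arg(basis)
  origin <- first_detection(counts, order, selector)
  out <- vector("list", length(order))
  for (i in seq_along(order)) {
    target <- order[i]
    sub <- counts[, selector[[target]], drop = FALSE]
    w <- rowSums(sub)
    present <- w > 0
    if (!any(present)) {
      warning("target '", target, "' has no reads; attribution undefined")
      out[[i]] <- data.frame(target = character(), origin = character(),
                             basis = character(), fraction = numeric())
      next
    }
    weight <- if (basis == "reads") w[present] else rep(1, sum(present))
    org <- origin[rownames(counts)[present]]
    tot <- sum(weight)
    frac <- vapply(order[seq_len(i)], function(lab) {
      sum(weight[org == lab]) / tot
    }, numeric(1))
    out[[i]] <- data.frame(target = target, origin = order[seq_len(i)],
                           basis = basis, fraction = unname(frac))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Attribute each month's community to months of first detection
#'
#' For each target month, partitions the community observed that month by the
#' earliest month at which each of its SVs was detected. On the `reads` basis
#' each SV is weighted by its read count in the target month; on the
#' `richness` basis every present SV counts equally (presence/absence).
#' Samples should first be restricted to one layer and one size fraction
#' (see [select_samples()]).
#'
#' @param counts SV x sample matrix (already restricted).
#' @param months month labels in temporal order.
#' @param selector named list month -> sample ids; `NULL` builds it from
#'   `meta` by matching `month`.
#' @param meta optional metadata used when `selector` is `NULL`.
#' @param basis `"reads"` or `"richness"`.
#' @return data frame `target`, `origin`, `basis`, `fraction`. Fractions for
#'   a non-empty target sum to 1; the first month is always attributed 100%
#'   to itself.
#' @export
attribute_temporal <- function(counts, months, selector = NULL, meta = NULL,
                               basis = c("reads", "richness")) {
  if (is.null(selector)) {
    if (is.null(meta)) stop("supply selector or meta")
    selector <- lapply(months, function(m) {
      intersect(select_samples(meta, month = m), colnames(counts))
    })
    names(selector) <- months
  }
  attribute_origin(counts, months, selector, basis)
}

#' Attribute deep communities to zones of first detection
#'
#' Vertical analogue of [attribute_temporal()]: for one month and size
#' fraction, each zone is represented by one sample (a representative depth)
#' and each zone's community is partitioned by the shallowest zone at which
#' each SV occurs, ordered surface to abyssopelagic.
#'
#' @param counts SV x sample matrix (one month, one fraction).
#' @param zones zone labels, shallowest first.
#' @param selector named list zone -> representative sample id(s).
#' @param basis `"reads"` or `"richness"`.
#' @return data frame as in [attribute_temporal()].
#' @export
attribute_vertical <- function(counts, zones, selector,
                               basis = c("reads", "richness")) {
  attribute_origin(counts, zones, selector, basis)
}

#' Extract representative SVs
#'
#' SVs whose within-sample relative abundance reaches `threshold` (inclusive)
#' in at least one sample of `scope`.
#'
#' @param counts SV x sample matrix.
#' @param threshold relative-abundance cutoff in (0, 1]; default 0.05.
#' @param scope sample ids to scan (default all).
#' @return data frame `sv_id`, `max_relative_abundance`, `argmax_sample`,
#'   one row per representative SV.
#' @export
representative_svs <- function(counts, threshold = 0.05,
                               scope = colnames(counts)) {
  if (!length(scope)) stop("scope must be non-empty")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  sub <- counts[, scope, drop = FALSE]
  totals <- colSums(sub)
  rel <- sweep(sub, 2, pmax(totals, 1), "/")
  rel[, totals == 0] <- 0
  mx <- apply(rel, 1, max)
  keep <- mx >= threshold
  arg <- colnames(sub)[apply(rel[keep, , drop = FALSE], 1, which.max)]
  data.frame(sv_id = rownames(counts)[keep],
             max_relative_abundance = unname(mx[keep]),
             argmax_sample = arg)
}

#' Classify vertical occurrence patterns
#'
#' Assigns each SV present anywhere in `selector` to one of three patterns:
#' `P1_surface_to_deep` (present in the epipelagic zone, including the
#' surface layer, and reaching the bathypelagic or abyssopelagic zone),
#' `P2_epipelagic_only` (present in the epipelagic but not reaching
#' bathy-/abyssopelagic; SVs also seen in the mesopelagic fall here, and the
#' returned `zones_present` column lets users re-bin them), and
#' `P3_deep_only` (absent from the epipelagic, present at mesopelagic depth
#' or below).
#'
#' @param counts SV x sample matrix (one month and fraction).
#' @param selector named list with entries `epipelagic` (surface + epipelagic
#'   samples), `mesopelagic`, `bathypelagic`, `abyssopelagic`.
#' @return data frame `sv_id`, `pattern`, `zones_present`.
#' @export
classify_vertical_patterns <- function(counts, selector) {
  need <- c("epipelagic", "mesopelagic", "bathypelagic", "abyssopelagic")
  if (!all(need %in% names(selector))) {
    stop("selector must name zones: ", paste(need, collapse = ", "))
  }
  pres <- vapply(need, function(z) {
    s <- intersect(selector[[z]], colnames(counts))
    if (!length(s)) return(rep(FALSE, nrow(counts)))
    rowSums(counts[, s, drop = FALSE]) > 0
  }, logical(nrow(counts)))
  anywhere <- rowSums(pres) > 0
  pres <- pres[anywhere, , drop = FALSE]
  deep <- pres[, "bathypelagic"] | pres[, "abyssopelagic"]
  epi <- pres[, "epipelagic"]
  pattern <- ifelse(epi & deep, "P1_surface_to_deep",
                    ifelse(epi, "P2_epipelagic_only", "P3_deep_only"))
  zones_present <- apply(pres, 1, function(p) paste(need[p], collapse = ","))
  data.frame(sv_id = rownames(counts)[anywhere], pattern = pattern,
             zones_present = unname(zones_present))
}

#' Partition SVs into shared/unique membership classes
#'
#' Each SV present in at least one group is assigned the set of groups that
#' contain it, so class sizes sum to the number of present SVs.
#'
#' @param counts SV x sample matrix.
#' @param groups named list label -> sample ids (>= 2 groups, unique labels).
#' @return data frame `sv_id`, `class` (comma-joined sorted group labels).
#' @export
shared_unique <- function(counts, groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (is.null(names(groups)) || anyDuplicated(names(groups))) {
    stop("groups must have unique labels")
  }
  pres <- vapply(groups, function(s) {
    s <- intersect(s, colnames(counts))
    if (!length(s)) return(rep(FALSE, nrow(counts)))
    rowSums(counts[, s, drop = FALSE]) > 0
  }, logical(nrow(counts)))
  anywhere <- rowSums(pres) > 0
  cls <- apply(pres[anywhere, , drop = FALSE], 1, function(p) {
    paste(sort(names(groups)[p]), collapse = ",")
  })
  data.frame(sv_id = rownames(counts)[anywhere], class = unname(cls))
}
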