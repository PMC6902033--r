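#' Bray-Curtis dissimilarity between samples
#'
#' d(i,j) = 1 - 2 * sum_k min(x_ki, x_kj) / (sum_k x_ki + sum_k x_kj) on the
#' columns (samples) of an SV count matrix; bounded in [0, 1] on nonnegative
#' counts. A pair of all-zero samples has undefined dissimilarity and is
#' returned as `NA` with a warning.
#'
#' @param counts SV x sample matrix of nonnegative counts.
#' @return a `dist` object over samples (convert with `as.matrix()`; zero
#'   diagonal, symmetric).
#' @export
bray_curtis <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  totals <- colSums(counts)
  # empty samples are reported once below, with names; silence vegan's
  # generic empty-row/NA notes
  d <- withCallingHandlers(
    vegan::vegdist(t(counts), method = "bray"),
    warning = function(w) {
      if (grepl("empty rows|missing values", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (any(totals == 0)) {
    warning("all-zero sample(s): ",
            paste(colnames(counts)[totals == 0], collapse = ", "),
            "; dissimilarities involving two empty samples are NA")
    m <- as.matrix(d)
    zz <- which(totals == 0)
    if (length(zz) > 1) {
      for (i in zz) for (j in zz) if (i != j) m[i, j] <- NA
      d <- stats::as.dist(m)
    }
  }
  d
}

#' Write a distance matrix as square TSV
#' @param d a `dist` object or square matrix with labels.
#' @param path output path.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square TSV distance matrix
#' @param path path written by [write_distance_matrix()].
#' @return a `dist` object.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  stats::as.dist(m)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: the pseudo-F statistic is
#' formed from among/within sums of squared distances,
#' `SS_T = sum_(i<j) d_ij^2 / n`, `SS_W = sum_g sum_(i<j in g) d_ij^2 / n_g`,
#' `F = (SS_A / (a - 1)) / (SS_W / (n - a))` with `SS_A = SS_T - SS_W` and `a`
#' groups. Perfectly separated groups (`SS_W = 0`) give `F = Inf` rather than
#' a rounding artefact. The p-value uses the add-one convention
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`, so p is never 0; label
#' permutations are uniform given `seed`. With `exhaustive = TRUE` all `n!`
#' label orders are enumerated instead (small `n` only) and
#' `p = #\{F_perm >= F_obs\} / n!` (the identity is included, so `p >= 1/n!`).
#'
#' @param d a `dist` object or square distance matrix (no missing values).
#' @param grouping group label per sample, in the order of `d`'s labels.
#' @param n_perm number of label permutations (default 9999).
#' @param seed integer RNG seed for the permutations.
#' @param exhaustive enumerate all permutations (requires `n <= 9`).
#' @return list with `pseudo_F`, `p`, `n_perm`.
#' @export
permanova <- function(d, grouping, n_perm = 9999, seed = 1L,
                      exhaustive = FALSE) {
  m <- as.matrix(d)
  n <- nrow(m)
  grouping <- as.factor(grouping)
  if (length(grouping) != n) {
    stop("grouping length must match the distance matrix")
  }
  grouping <- droplevels(grouping)
  if (nlevels(grouping) < 2) stop("need at least 2 groups")
  if (!exhaustive && n_perm < 1) stop("n_perm must be >= 1")
  if (any(!is.finite(m))) stop("distance matrix has missing values")
  d2 <- m^2
  a <- nlevels(grouping)
  ss_t <- sum(d2) / (2 * n)
  pseudo_f <- function(g) {
    ssw <- 0
    for (lev in levels(g)) {
      idx <- g == lev
      ssw <- ssw + sum(d2[idx, idx]) / (2 * sum(idx))
    }
    ((ss_t - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- pseudo_f(grouping)
  if (exhaustive) {
    if (n > 9) stop("exhaustive enumeration is limited to n <= 9")
    perms <- all_permutations(n)
    f_perm <- apply(perms, 1, function(ix) pseudo_f(grouping[ix]))
    p <- sum(f_perm >= f_obs, na.rm = TRUE) / nrow(perms)
    return(list(pseudo_F = f_obs, p = p, n_perm = nrow(perms)))
  }
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    if (isTRUE(pseudo_f(grouping[sample.int(n)]) >= f_obs)) hits <- hits + 1L
  }
  list(pseudo_F = f_obs, p = (1 + hits) / (1 + n_perm), n_perm = n_perm)
}

# All permutations of 1..n as a (n!) x n matrix, deterministic order.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(k, matrix(rest[sub],
                                                         nrow(sub)))
    row <- row + nrow(sub)
  }
  out
}

#' Correlate per-sample read totals with chlorophyll a
#'
#' Pearson correlation with a two-sided t-distribution p-value, used to check
#' that sequence-read totals track the corresponding size fraction's
#' chlorophyll a concentration.
#'
#' @param reads per-sample read totals.
#' @param chla per-sample chlorophyll a (ug L^-1), paired with `reads`.
#' @return list with `r`, `p`, and `n`; `r`/`p` are `NA` when either variable
#'   has zero variance.
#' @export
correlate_reads_abundance <- function(reads, chla) {
  if (length(reads) != length(chla)) stop("reads and chla must be paired")
  ok <- is.finite(reads) & is.finite(chla)
  reads <- reads[ok]; chla <- chla[ok]
  if (length(reads) < 3) stop("need at least 3 paired finite values")
  if (stats::sd(reads) == 0 || stats::sd(chla) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(reads)))
  }
  ct <- stats::cor.test(reads, chla, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(reads))
}
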