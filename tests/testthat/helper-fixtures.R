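# Shared fixtures and independent brute-force oracles.

make_counts <- function(mat, svs = NULL, samples = NULL) {
  m <- as.matrix(mat)
  rownames(m) <- svs %||% paste0("sv", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_table <- function(n_sv = 10, n_samp = 6, lambda = 5, seed = 1,
                       zero_prob = 0.3) {
  set.seed(seed)
  m <- matrix(rpois(n_sv * n_samp, lambda), n_sv, n_samp)
  m[runif(length(m)) < zero_prob] <- 0L
  make_counts(m)
}

# Brute-force Bray-Curtis: the closed formula, pair by pair.
bc_brute <- function(counts) {
  n <- ncol(counts)
  d <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- sum(pmin(counts[, i], counts[, j]))
    den <- sum(counts[, i]) + sum(counts[, j])
    d[i, j] <- 1 - 2 * num / den
  }
  d
}

# Brute-force first detection: exhaustive scan per SV.
fd_brute <- function(counts, order, selector) {
  out <- character(0)
  for (sv in rownames(counts)) {
    for (lab in order) {
      if (sum(counts[sv, selector[[lab]], drop = FALSE]) > 0) {
        out[sv] <- lab
        break
      }
    }
  }
  out
}

# Brute-force origin attribution: set enumeration per SV, then weighting.
attr_brute <- function(counts, order, selector, basis) {
  origin <- fd_brute(counts, order, selector)
  res <- list()
  for (i in seq_along(order)) {
    target <- order[i]
    tot_w <- 0
    w_by_origin <- setNames(numeric(i), order[seq_len(i)])
    for (sv in rownames(counts)) {
      reads <- sum(counts[sv, selector[[target]], drop = FALSE])
      if (reads == 0) next
      w <- if (basis == "reads") reads else 1
      tot_w <- tot_w + w
      w_by_origin[origin[sv]] <- w_by_origin[origin[sv]] + w
    }
    if (tot_w == 0) next
    res[[target]] <- w_by_origin / tot_w
  }
  res
}

# Look up one attribution fraction from the package's long-format output.
attr_frac <- function(attribution, target, origin) {
  hit <- attribution$target == target & attribution$origin == origin
  if (!any(hit)) return(NA_real_)
  attribution$fraction[hit]
}

# Study-design constants reused across tests.
study_months <- c("2010-11", "2011-02", "2011-04", "2011-07")

month_selector <- function(meta, counts, zone = "surface",
                           fraction = "large", months = study_months) {
  sel <- lapply(months, function(m) {
    intersect(select_samples(meta, month = m, zone = zone,
                             fraction = fraction), colnames(counts))
  })
  names(sel) <- months
  sel
}

new_particles <- function(lon, lat, level = 0, t0 = 0) {
  structure(data.frame(lon = lon, lat = lat), level = level, t0 = t0,
            class = c("particle_set", "data.frame"))
}
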