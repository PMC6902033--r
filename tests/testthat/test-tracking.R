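test_that("phytoplankton filter applies inclusion and exclusion rules", {
  counts <- make_counts(diag(4) * 5, svs = paste0("sv", 1:4))
  tax <- data.frame(
    sv_id = paste0("sv", 1:4),
    lineage = c("Eukaryota;Archaeplastida;Chlorophyta;Mamiellophyceae",
                "Eukaryota;Alveolata;Dinoflagellata;Dinophyceae;Gymnodinium",
                "Eukaryota;Heterokontophyta;Chrysophyceae;Spumella",
                "Eukaryota;Haptophyta;Prymnesiophyceae;Emiliania"),
    trophic_flag = c("phototroph", "unknown", "heterotroph", "phototroph"))
  out <- filter_phytoplankton(counts, tax)
  expect_identical(rownames(out), c("sv1", "sv4"))  # dino + heterotroph gone
  expect_identical(colnames(out), colnames(counts))

  expect_error(filter_phytoplankton(counts, tax[-1, ]), "sv1")
  expect_error(filter_phytoplankton(counts, tax, include_groups = character()),
               "non-empty")
})

test_that("rarefaction hits the target depth and stays below originals", {
  counts <- make_counts(rbind(c(8000, 50), c(2000, 50)))
  expect_error(rarefy(counts, 0), "positive integer")
  expect_error(rarefy(counts, 6913), "s2")
  r <- rarefy(counts, 6913, seed = 42, drop_below = TRUE)
  expect_identical(colnames(r), "s1")
  expect_identical(sum(r), 6913L)
  expect_true(all(r <= counts[, "s1"]))

  # a sample already at depth is returned unchanged
  whole <- make_counts(matrix(c(4000L, 2913L), 2, 1))
  expect_identical(rarefy(whole, 6913, seed = 1)[, 1], whole[, 1])
})

test_that("rarefied counts follow the hypergeometric expectation", {
  counts <- make_counts(matrix(c(50L, 50L), 2, 1))
  draws <- vapply(seq_len(4000), function(s) rarefy(counts, 10, seed = s)[1, 1],
                  integer(1))
  # mean of hypergeometric(N=100, K=50, n=10) is 5 with per-draw variance
  # n*p*(1-p)*(N-n)/(N-1)
  sd_mean <- sqrt(10 * 0.5 * 0.5 * 90 / 99 / length(draws))
  expect_lt(abs(mean(draws) - 5), 3 * sd_mean)
  expect_true(all(draws >= 0 & draws <= 10))
})

test_that("first detection matches exhaustive set scan", {
  counts <- make_counts(rbind(c(2, 0, 1), c(0, 3, 0), c(4, 0, 5)),
                        samples = c("m1s", "m2s", "m3s"))
  sel <- list(`1` = "m1s", `2` = "m2s", `3` = "m3s")
  got <- first_detection(counts, c("1", "2", "3"), sel)
  expect_identical(got, c(sv1 = "1", sv2 = "2", sv3 = "1"))
  expect_error(first_detection(counts, character(), sel), "non-empty")
  expect_error(first_detection(counts, c("1", "2"),
                               list(`1` = "m1s", `2` = "m1s")), "disjoint")

  for (seed in 1:20) {
    x <- rand_table(12, 6, seed = seed)
    sel <- split(colnames(x), rep(c("a", "b", "c"), each = 2))
    expect_identical(first_detection(x, c("a", "b", "c"), sel),
                     fd_brute(x, c("a", "b", "c"), sel))
  }
})

test_that("temporal attribution matches hand enumeration on both bases", {
  # month-2 community: A has 30 reads (first seen month 1), B has 70 reads
  counts <- make_counts(rbind(c(10, 30), c(0, 70)),
                        svs = c("A", "B"), samples = c("m1", "m2"))
  sel <- list(month1 = "m1", month2 = "m2")
  reads <- attribute_temporal(counts, c("month1", "month2"), selector = sel,
                              basis = "reads")
  expect_equal(attr_frac(reads, "month1", "month1"), 1)
  expect_equal(attr_frac(reads, "month2", "month1"), 0.3)
  expect_equal(attr_frac(reads, "month2", "month2"), 0.7)
  rich <- attribute_temporal(counts, c("month1", "month2"), selector = sel,
                             basis = "richness")
  expect_equal(attr_frac(rich, "month2", "month1"), 0.5)
  expect_equal(attr_frac(rich, "month2", "month2"), 0.5)

  # subset case: everything in month 2 already seen in month 1
  sub <- make_counts(rbind(c(5, 9), c(3, 1)), samples = c("m1", "m2"))
  for (basis in c("reads", "richness")) {
    a <- attribute_temporal(sub, c("month1", "month2"), selector = sel,
                            basis = basis)
    expect_equal(attr_frac(a, "month2", "month1"), 1)
    expect_equal(attr_frac(a, "month2", "month2"), 0)
  }

  # an empty target month is emitted as empty, with a warning
  gap <- make_counts(rbind(c(5, 0), c(3, 0)), samples = c("m1", "m2"))
  expect_warning(a <- attribute_temporal(gap, c("month1", "month2"),
                                         selector = sel, basis = "reads"),
                 "no reads")
  expect_identical(nrow(a[a$target == "month2", ]), 0L)
})

test_that("vertical attribution mirrors the temporal machinery over zones", {
  zones <- c("surface", "mesopelagic", "bathypelagic", "abyssopelagic")
  sel <- list(surface = "z0", mesopelagic = "z1", bathypelagic = "z2",
              abyssopelagic = "z3")
  # abyssopelagic community: X from the surface, Y first seen at the bottom
  counts <- make_counts(rbind(c(100, 5, 2, 10), c(0, 0, 0, 10)),
                        svs = c("X", "Y"),
                        samples = c("z0", "z1", "z2", "z3"))
  a <- attribute_vertical(counts, zones, sel, basis = "reads")
  expect_equal(attr_frac(a, "surface", "surface"), 1)
  expect_equal(attr_frac(a, "abyssopelagic", "surface"), 0.5)
  expect_equal(attr_frac(a, "abyssopelagic", "abyssopelagic"), 0.5)
  # every deep SV also present at the surface -> 100% surface origin
  allsurf <- make_counts(rbind(c(10, 4, 3, 2), c(5, 1, 1, 1)),
                         samples = c("z0", "z1", "z2", "z3"))
  a2 <- attribute_vertical(allsurf, zones, sel, basis = "reads")
  for (z in zones) expect_equal(attr_frac(a2, z, "surface"), 1)
})

test_that("attribution fractions sum to 1 and match brute force on random tables", {
  order <- c("g1", "g2", "g3")
  for (seed in 1:100) {
    x <- rand_table(15, 6, seed = seed, zero_prob = 0.5)
    sel <- split(colnames(x), rep(order, each = 2))
    for (basis in c("reads", "richness")) {
      a <- suppressWarnings(attribute_temporal(x, order, selector = sel,
                                               basis = basis))
      sums <- tapply(a$fraction, a$target, sum)
      expect_true(all(abs(sums - 1) < 1e-9))
      oracle <- attr_brute(x, order, sel, basis)
      for (tg in names(oracle)) for (og in names(oracle[[tg]])) {
        expect_equal(attr_frac(a, tg, og), unname(oracle[[tg]][og]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("a single month always yields the identity attribution", {
  for (seed in 1:10) {
    x <- rand_table(8, 3, seed = seed)
    a <- attribute_temporal(x, "only", selector = list(only = colnames(x)),
                            basis = "reads")
    expect_equal(a$fraction, 1)
    expect_identical(a$origin, "only")
  }
})

test_that("adding target-month reads of an earlier SV never lowers its origin share", {
  order <- c("m1", "m2")
  for (seed in 1:50) {
    x <- rand_table(10, 4, seed = seed, zero_prob = 0.4)
    sel <- split(colnames(x), rep(order, each = 2))
    origin <- first_detection(x, order, sel)
    early <- names(origin)[origin == "m1"]
    if (!length(early)) next
    base <- suppressWarnings(attribute_temporal(x, order, selector = sel,
                                                basis = "reads"))
    f0 <- attr_frac(base, "m2", "m1")
    if (is.na(f0)) next
    y <- x
    y[early[1], sel$m2[1]] <- y[early[1], sel$m2[1]] + 25L
    f1 <- attr_frac(attribute_temporal(y, order, selector = sel,
                                       basis = "reads"), "m2", "m1")
    expect_gte(f1, f0 - 1e-12)
  }
})

test_that("representative SVs use an inclusive threshold", {
  counts <- make_counts(rbind(c(6, 0), c(5, 49), c(89, 51)),
                        svs = c("six", "five", "rest"))
  # sample 1 totals 100: six = 6%, five = exactly 5%
  rep5 <- representative_svs(counts, threshold = 0.05, scope = "s1")
  expect_setequal(rep5$sv_id, c("six", "five", "rest"))
  # 4.9% everywhere is excluded
  low <- make_counts(rbind(c(49, 49), c(951, 951)), svs = c("low", "hi"))
  expect_identical(representative_svs(low, 0.05)$sv_id, "hi")
  expect_error(representative_svs(counts, 0.05, scope = character()),
               "non-empty")
  expect_error(representative_svs(counts, 0), "threshold")
})

test_that("vertical patterns partition present SVs into disjoint classes", {
  sel <- list(epipelagic = c("e1", "e2"), mesopelagic = "m",
              bathypelagic = "b", abyssopelagic = "a")
  counts <- make_counts(rbind(
    c(5, 0, 0, 0, 3),   # epi + abysso -> P1
    c(2, 1, 0, 0, 0),   # epi only -> P2
    c(0, 0, 0, 4, 0),   # bathy only -> P3
    c(1, 0, 6, 0, 0),   # epi + meso -> P2 (convention), zones recorded
    c(0, 0, 0, 0, 0)),  # absent everywhere -> not classified
    svs = paste0("sv", 1:5), samples = c("e1", "e2", "m", "b", "a"))
  pat <- classify_vertical_patterns(counts, sel)
  expect_identical(pat$pattern[pat$sv_id == "sv1"], "P1_surface_to_deep")
  expect_identical(pat$pattern[pat$sv_id == "sv2"], "P2_epipelagic_only")
  expect_identical(pat$pattern[pat$sv_id == "sv3"], "P3_deep_only")
  expect_identical(pat$pattern[pat$sv_id == "sv4"], "P2_epipelagic_only")
  expect_identical(pat$zones_present[pat$sv_id == "sv4"],
                   "epipelagic,mesopelagic")
  expect_false("sv5" %in% pat$sv_id)
  expect_identical(sort(pat$sv_id), paste0("sv", 1:4))  # exact partition
  expect_identical(anyDuplicated(pat$sv_id), 0L)
})

test_that("shared/unique classes cover exactly the present SVs", {
  counts <- make_counts(rbind(c(1, 0), c(0, 2), c(3, 4), c(0, 0)),
                        svs = c("A", "B", "C", "D"))
  g <- list(g1 = "s1", g2 = "s2")
  cls <- shared_unique(counts, g)
  expect_identical(cls$class[cls$sv_id == "A"], "g1")
  expect_identical(cls$class[cls$sv_id == "B"], "g2")
  expect_identical(cls$class[cls$sv_id == "C"], "g1,g2")
  expect_false("D" %in% cls$sv_id)
  expect_identical(nrow(cls), 3L)
  expect_error(shared_unique(counts, g["g1"]), "2 groups")
  expect_error(shared_unique(counts, setNames(g, c("g1", "g1"))), "unique")
})
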