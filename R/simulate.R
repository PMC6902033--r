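#' Define a synthetic community scenario
#'
#' Parameters of the planted provenance structure the generator emulates:
#' a persistent "seed" flora present in the surface layer every month, an
#' "allochthonous" flora present only in the deep-mixing months with a fixed
#' expected share of surface reads, stochastic re-occurrence of surface SVs
#' in deeper zones with depth attenuation, deep-resident SVs never seen in the
#' epipelagic, and non-phytoplankton decoys (dinoflagellates and flagged
#' heterotrophs) that exercise the taxon filter.
#'
#' @param n_seed_taxa persistent taxa present in all months' surface samples.
#' @param n_allochthonous taxa present only in mixing months.
#' @param n_deep deep-resident taxa (mesopelagic and below only).
#' @param n_decoy dinoflagellate / heterotroph decoy taxa (half each).
#' @param allochthonous_read_fraction expected share `f` of mixing-month
#'   surface *phytoplankton* reads carried by allochthonous taxa.
#' @param export_prob named per-zone probability that a surface SV re-occurs
#'   in that zone (attenuating with depth).
#' @param depth_total_decay multiplicative decay of the per-sample read total
#'   per zone step downward.
#' @param reads_per_sample read total of a surface sample.
#' @param dispersion overdispersion of per-SV relative abundances: per-sample
#'   gamma multipliers with variance `dispersion` (0 = none), the mixing
#'   construction behind a negative-binomial-type count law.
#' @param decoy_read_fraction share of each sample's reads given to decoys.
#' @param mixing_months positions (indices) of the mixing months within the
#'   month order; default months 2 and 3 of a 4-month cycle.
#' @param seed integer RNG seed; the same scenario and seed give bit-identical
#'   output.
#' @return object of class `community_scenario`.
#' @export
community_scenario <- function(n_seed_taxa = 40, n_allochthonous = 20,
                               n_deep = 8, n_decoy = 6,
                               allochthonous_read_fraction = 0.5,
                               export_prob = c(epipelagic = 0.8,
                                               mesopelagic = 0.4,
                                               bathypelagic = 0.2,
                                               abyssopelagic = 0.1),
                               depth_total_decay = 0.6,
                               reads_per_sample = 10000,
                               dispersion = 0.5,
                               decoy_read_fraction = 0.05,
                               mixing_months = c(2L, 3L),
                               seed = 1L) {
  if (n_seed_taxa + n_allochthonous <= 0) {
    stop("scenario needs at least one seed or allochthonous taxon")
  }
  stopifnot(allochthonous_read_fraction >= 0, allochthonous_read_fraction <= 1,
            all(export_prob >= 0), all(export_prob <= 1),
            depth_total_decay > 0, depth_total_decay <= 1,
            reads_per_sample >= 1, dispersion >= 0,
            decoy_read_fraction >= 0, decoy_read_fraction < 1)
  structure(list(n_seed_taxa = n_seed_taxa,
                 n_allochthonous = n_allochthonous,
                 n_deep = n_deep, n_decoy = n_decoy,
                 allochthonous_read_fraction = allochthonous_read_fraction,
                 export_prob = export_prob,
                 depth_total_decay = depth_total_decay,
                 reads_per_sample = reads_per_sample,
                 dispersion = dispersion,
                 decoy_read_fraction = decoy_read_fraction,
                 mixing_months = mixing_months,
                 seed = seed),
            class = "community_scenario")
}

# Fixed lineage pools (semicolon-delimited, domain -> genus), cycled over taxa.
lineage_pools <- function() {
  list(
    seed = c(
      "Eukaryota;Archaeplastida;Chlorophyta;Mamiellophyceae;Ostreococcus",
      "Eukaryota;Archaeplastida;Chlorophyta;Mamiellophyceae;Micromonas",
      "Eukaryota;Archaeplastida;Chlorophyta;Mamiellophyceae;Bathycoccus",
      "Eukaryota;Archaeplastida;Chlorophyta;Pycnococcaceae;Pycnococcus",
      "Eukaryota;Haptophyta;Prymnesiophyceae;Emiliania",
      "Eukaryota;Heterokontophyta;Dictyochophyceae;Dictyocha",
      "Eukaryota;Heterokontophyta;Eustigmatophyceae;Nannochloropsis",
      "Eukaryota;Cryptophyta;Cryptophyceae;Teleaulax",
      "Eukaryota;Chlorarachniophyta;Chlorarachniophyceae;Bigelowiella"),
    allochthonous = c(
      "Eukaryota;Heterokontophyta;Diatomea;Mediophyceae;Chaetoceros",
      "Eukaryota;Heterokontophyta;Diatomea;Mediophyceae;Skeletonema",
      "Eukaryota;Heterokontophyta;Diatomea;Bacillariophyceae;Pseudo-nitzschia",
      "Eukaryota;Cryptophyta;Cryptophyceae;Geminigera"),
    deep = c(
      "Eukaryota;Heterokontophyta;Bolidophyceae;Bolidomonas",
      "Eukaryota;Haptophyta;Prymnesiophyceae;Phaeocystis",
      "Eukaryota;Heterokontophyta;Chrysophyceae;Chrysophyceae_Clade-C"),
    decoy_dino = c(
      "Eukaryota;Alveolata;Dinoflagellata;Dinophyceae;Gymnodinium",
      "Eukaryota;Alveolata;Dinoflagellata;Syndiniales;Amoebophrya"),
    decoy_het = c(
      "Eukaryota;Heterokontophyta;Chrysophyceae;Spumella",
      "Eukaryota;Heterokontophyta;Chrysophyceae;Paraphysomonas"))
}

#' Generate a synthetic SV community
#'
#' Draws one sample per month x zone x fraction under a
#' [community_scenario()]. Surface samples contain the seed taxa every month
#' plus, in mixing months, the allochthonous taxa with an expected
#' `allochthonous_read_fraction` of the phytoplankton reads (the group split
#' is fixed in the multinomial probabilities, so the realised allochthonous
#' read count in a surface sample is binomial). Each zone below the surface
#' contains each surface SV independently with that zone's `export_prob`,
#' plus the deep-resident taxa from the mesopelagic down; per-sample read
#' totals decay by `depth_total_decay` per zone step. Within groups,
#' per-SV relative abundances are overdispersed: fixed gamma base weights
#' per taxon times per-sample gamma noise with variance `dispersion`,
#' realised by a single multinomial draw per sample.
#'
#' @param scenario a [community_scenario()].
#' @param months month labels, in temporal order.
#' @param zones zone labels, shallowest first (must start at `"surface"`).
#' @param fractions size-fraction labels.
#' @return list with `counts` (SV x sample integer matrix), `meta` (sample
#'   metadata), `taxonomy` (`sv_id`, `lineage`, `trophic_flag`) and `truth`
#'   (planted roles and parameters, for test harnesses).
#' @export
generate_community <- function(scenario,
                               months = c("2010-11", "2011-02",
                                          "2011-04", "2011-07"),
                               zones = zone_levels(),
                               fractions = c("large", "small")) {
  stopifnot(inherits(scenario, "community_scenario"))
  if (zones[1] != "surface") stop("zones must start at 'surface'")
  set.seed(scenario$seed)
  pools <- lineage_pools()
  mk <- function(prefix, n, pool, trophic) {
    if (n == 0) return(NULL)
    data.frame(sv_id = sprintf("SV_%s_%03d", prefix, seq_len(n)),
               lineage = rep_len(pool, n),
               trophic_flag = rep_len(trophic, n),
               role = prefix)
  }
  n_dino <- ceiling(scenario$n_decoy / 2)
  n_het <- scenario$n_decoy - n_dino
  tax <- rbind(
    mk("seed", scenario$n_seed_taxa, pools$seed, "phototroph"),
    mk("alloch", scenario$n_allochthonous, pools$allochthonous, "phototroph"),
    mk("deep", scenario$n_deep, pools$deep, "phototroph"),
    mk("decoy", n_dino, pools$decoy_dino, "unknown"),
    mk("decoyhet", n_het, pools$decoy_het, "heterotroph"))
  ntax <- nrow(tax)
  role <- tax$role
  is_decoy <- role %in% c("decoy", "decoyhet")
  base_w <- stats::rgamma(ntax, shape = 2, rate = 2)

  mixing <- months[scenario$mixing_months[scenario$mixing_months <=
                                            length(months)]]
  depth_of <- c(surface = 10, epipelagic = 200, mesopelagic = 500,
                bathypelagic = 1000, abyssopelagic = 5000)
  zone_k <- seq_along(zones) - 1L
  names(zone_k) <- zones
  f <- scenario$allochthonous_read_fraction
  d <- scenario$decoy_read_fraction
  if (!any(is_decoy)) d <- 0

  samples <- expand.grid(month = months, zone = zones, fraction = fractions,
                         stringsAsFactors = FALSE)
  samples$sample_id <- with(samples, paste(month, zone, fraction, sep = "."))
  samples$depth_m <- depth_of[samples$zone]
  counts <- matrix(0L, ntax, nrow(samples),
                   dimnames = list(tax$sv_id, samples$sample_id))

  disp_noise <- function(n) {
    if (scenario$dispersion == 0) return(rep(1, n))
    sh <- 1 / scenario$dispersion
    stats::rgamma(n, shape = sh, rate = sh)
  }

  for (fr in fractions) for (m in months) {
    surf_member <- role == "seed" | (role == "alloch" & m %in% mixing)
    for (z in zones) {
      j <- which(samples$month == m & samples$zone == z &
                   samples$fraction == fr)
      if (z == "surface") {
        member <- surf_member
      } else {
        p_exp <- scenario$export_prob[[z]]
        if (is.null(p_exp) || is.na(p_exp)) p_exp <- 0
        member <- surf_member &
          stats::runif(ntax) < p_exp
        if (z != "epipelagic") member <- member | role == "deep"
      }
      member <- member | is_decoy
      w <- base_w * disp_noise(ntax)
      p <- numeric(ntax)
      # fixed group shares: decoys d; phytoplankton 1 - d, with the
      # allochthonous share f planted inside surface mixing-month samples
      grp_share <- function(sel, share) {
        sel <- sel & member
        if (any(sel) && share > 0) p[sel] <<- w[sel] / sum(w[sel]) * share
        if (any(sel)) share else 0
      }
      used_decoy <- grp_share(is_decoy, d)
      phyto_share <- 1 - used_decoy
      if (z == "surface" && m %in% mixing && any(member & role == "alloch")) {
        used_a <- grp_share(role == "alloch", f * phyto_share)
        grp_share(!is_decoy & role != "alloch", phyto_share - used_a)
      } else {
        grp_share(!is_decoy, phyto_share)
      }
      if (sum(p) <= 0) next
      p <- p / sum(p)
      total <- round(scenario$reads_per_sample *
                       scenario$depth_total_decay^zone_k[[z]])
      counts[, j] <- as.integer(stats::rmultinom(1, total, p))
    }
  }

  meta <- data.frame(sample_id = samples$sample_id, month = samples$month,
                     depth_m = unname(samples$depth_m),
                     zone = samples$zone, fraction = samples$fraction)
  meta$month <- factor(meta$month, levels = months, ordered = TRUE)
  truth <- list(roles = tax[, c("sv_id", "role")],
                mixing_months = mixing,
                allochthonous_read_fraction = f,
                decoy_read_fraction = d,
                target_totals = stats::setNames(
                  round(scenario$reads_per_sample *
                          scenario$depth_total_decay^zone_k[samples$zone]),
                  samples$sample_id),
                scenario = scenario)
  list(counts = validate_sv_counts(counts),
       meta = meta,
       taxonomy = tax[, c("sv_id", "lineage", "trophic_flag")],
       truth = truth)
}
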