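#' Configuration for the synthetic community generator
#'
#' Bundles the parameters of [simulate_community()] with validation. Defaults
#' reproduce the structure of a continental-scale paired land-use survey:
#' 156 arable and 61 extensively managed grassland sites in five country
#' blocks along a ~3000 km latitudinal gradient, sequenced to 2000 reads per
#' site.
#'
#' Abundance follows a two-part model. Occupancy decays steeply with
#' abundance rank (`exp(-occupancy_decay*q)`), while the expected local
#' relative abundance of an OTU *where it is present* decays gently (the
#' sorted lognormal profile), with site-level lognormal scatter
#' (`site_sigma`) on top. This mirrors a robust feature of soil fungal
#' surveys: regionally rare taxa are rare chiefly because they occupy few
#' sites, yet remain locally detectable (a handful of reads) where they do
#' occur, and locally dominant taxa vary from site to site.
#'
#' The homogenization effect `h` is the generator's experimental dial: in
#' arable sites the occupancy probability of an OTU at rank fraction
#' `q = (rank-1)/(n_otus-1)` is multiplied by `(1 - h*q)`, so abundant OTUs
#' (q near 0) are untouched while the rarest OTUs (q near 1) lose up to a
#' fraction `h` of their site occupancy. This acts on occupancy, not on
#' per-read abundance, so cumulative rank-abundance curves diverge only in
#' the tail — the signature of biotic homogenization.
#'
#' @param n_sites_arable,n_sites_grassland Sites per land use (defaults
#'   156/61, deliberately unbalanced).
#' @param n_otus Size of the regional OTU pool (default 2000).
#' @param n_countries Number of latitude-ordered country blocks (default 5).
#' @param lognormal_mu,lognormal_sigma Parameters of the lognormal draw
#'   that, sorted decreasing, becomes the abundance-when-present profile
#'   across ranks (mu is irrelevant after the multinomial normalization).
#' @param site_sigma Standard deviation of the per-site, per-OTU lognormal
#'   abundance scatter: how much a taxon's local share varies among the
#'   sites it occupies.
#' @param occupancy_decay Rate `d` in the baseline occupancy probability
#'   `exp(-d*q)`: abundant OTUs occur almost everywhere, the rarest at
#'   `exp(-d)` of sites (default 4, putting the rarest pool members at an
#'   expected occupancy of 1-3 sites per stratum).
#' @param geo_bandwidth Latitudinal niche breadth in degrees: each OTU is
#'   assigned a preferred latitude on the gradient and its occupancy
#'   probability is damped by a Gaussian kernel of this bandwidth around
#'   it, producing the geographic community turnover (country blocks
#'   separating in ordination space, distance decay) seen in continental
#'   surveys. `Inf` disables geographic structure, making sites fully
#'   exchangeable.
#' @param h Homogenization strength in `[0, 1]` (default 0.6, a clearly
#'   detectable rare-tail depletion; set 0 for an exchangeable null).
#' @param mgmt_effect Optional site-level coupling in `[0, 1]` between the
#'   arable management-intensity latent and additional rare-OTU occupancy
#'   depletion at that site (default 0: management covariates are drawn but
#'   do not feed back on the community, keeping `h = 0` a true null).
#' @param depth Multinomial reads per site (default 2000).
#' @param seed Single integer seed; all draws flow from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sites_arable = 156, n_sites_grassland = 61,
                       n_otus = 2000, n_countries = 5,
                       lognormal_mu = 0, lognormal_sigma = 2,
                       site_sigma = 1.5,
                       occupancy_decay = 4, geo_bandwidth = 10,
                       h = 0.6, mgmt_effect = 0,
                       depth = 2000, seed = 1) {
  if (site_sigma < 0) stop("site_sigma must be non-negative", call. = FALSE)
  if (geo_bandwidth <= 0) stop("geo_bandwidth must be positive (Inf to disable)",
                               call. = FALSE)
  if (n_otus < 2) stop("n_otus must be at least 2", call. = FALSE)
  if (n_countries < 1) stop("n_countries must be >= 1", call. = FALSE)
  if (h < 0 || h > 1) stop("h must lie in [0, 1]", call. = FALSE)
  if (mgmt_effect < 0 || mgmt_effect > 1) stop("mgmt_effect must lie in [0, 1]",
                                               call. = FALSE)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (n_sites_arable < 1 || n_sites_grassland < 1) {
    stop("both land uses need at least one site", call. = FALSE)
  }
  structure(list(
    n_sites_arable = as.integer(n_sites_arable),
    n_sites_grassland = as.integer(n_sites_grassland),
    n_otus = as.integer(n_otus), n_countries = as.integer(n_countries),
    lognormal_mu = lognormal_mu, lognormal_sigma = lognormal_sigma,
    site_sigma = site_sigma,
    occupancy_decay = occupancy_decay, geo_bandwidth = geo_bandwidth,
    h = h, mgmt_effect = mgmt_effect,
    depth = as.integer(depth), seed = as.integer(seed)
  ), class = "sim_config")
}

# Country blocks ordered south to north; latitude/longitude centers loosely
# follow a Spain-to-Sweden transect.
country_blocks <- function(n_countries) {
  lat <- seq(39.5, 59.5, length.out = n_countries)
  lon <- seq(-3.5, 16, length.out = n_countries)
  tibble::tibble(
    country = paste0("country_", seq_len(n_countries)),
    lat_center = lat, lon_center = lon
  )
}

#' Simulate an OTU table, site metadata, and a truth record
#'
#' Generates a sites-by-OTUs count table with known structure so every
#' downstream stage of the pipeline can be checked against ground truth:
#'
#' 1. The abundance-when-present profile is a sorted lognormal draw (the
#'    regional rank order of local abundances).
#' 2. Each OTU is present at a site with probability
#'    `exp(-occupancy_decay*q)`, multiplied in arable sites by `(1 - h*q)`
#'    and, when `mgmt_effect > 0`, by `(1 - mgmt_effect*z_s*q)` where `z_s`
#'    is that site's latent management intensity — rare OTUs (large rank
#'    fraction `q`) are depleted where farming is intensive.
#' 3. Reads are a single multinomial draw of size `depth` from the site's
#'    profile: the abundance-when-present of the present OTUs, each scaled
#'    by its site-level lognormal scatter `exp(N(0, site_sigma))`.
#' 4. Sites are assigned to equally sized, latitude-ordered country blocks;
#'    soil and bioclimatic covariates are linear in latitude plus noise;
#'    management variables are drawn for arable sites from the latent
#'    intensity (grassland sites carry `NA` management).
#'
#' @param config A [sim_config()].
#' @return A list with elements `counts` (OTU tibble; every row sums to
#'   `depth`), `metadata` (site tibble with role attributes for the
#'   soil/climate variable sets), and `truth` — a list holding the config,
#'   the normalized abundance-when-present profile (`rel_abundance`),
#'   per-OTU true occupancy per land use
#'   (Bernoulli presences, before read sampling), the presence matrix, and
#'   each arable site's latent intensity `z`.
#' @export
#' @examples
#' sim <- simulate_community(sim_config(n_sites_arable = 12,
#'   n_sites_grassland = 8, n_otus = 50, depth = 200, seed = 42))
#' dim(sim$counts)
simulate_community <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_community_impl(config))
}

simulate_community_impl <- function(cfg) {
  n_sites <- cfg$n_sites_arable + cfg$n_sites_grassland
  otu_ids <- sprintf("otu_%04d", seq_len(cfg$n_otus))

  # 1. rank-abundance distribution
  rel <- sort(stats::rlnorm(cfg$n_otus, cfg$lognormal_mu, cfg$lognormal_sigma),
              decreasing = TRUE)
  rel <- rel / sum(rel)
  q <- (seq_len(cfg$n_otus) - 1) / (cfg$n_otus - 1)
  p_base <- exp(-cfg$occupancy_decay * q)

  # site design: interleave land uses across country blocks
  blocks <- country_blocks(cfg$n_countries)
  land_use <- c(rep("arable", cfg$n_sites_arable),
                rep("grassland", cfg$n_sites_grassland))
  country_of <- function(n) blocks$country[((seq_len(n) - 1) %% cfg$n_countries) + 1]
  country <- c(country_of(cfg$n_sites_arable), country_of(cfg$n_sites_grassland))
  site_id <- sprintf("site_%03d", seq_len(n_sites))
  b <- match(country, blocks$country)
  latitude <- blocks$lat_center[b] + stats::rnorm(n_sites, 0, 0.8)
  longitude <- blocks$lon_center[b] + stats::rnorm(n_sites, 0, 1.0)

  # latent management intensity (arable only)
  z <- ifelse(land_use == "arable", stats::runif(n_sites), NA_real_)

  # latitudinal niche centers: occupancy damped away from an OTU's
  # preferred latitude -> community turnover along the gradient
  pref_lat <- stats::runif(cfg$n_otus, min(blocks$lat_center) - 1,
                           max(blocks$lat_center) + 1)

  # 2-3. presence draws and multinomial reads
  counts <- matrix(0L, n_sites, cfg$n_otus, dimnames = list(site_id, otu_ids))
  presence <- matrix(FALSE, n_sites, cfg$n_otus, dimnames = list(site_id, otu_ids))
  for (s in seq_len(n_sites)) {
    p <- p_base
    if (is.finite(cfg$geo_bandwidth)) {
      p <- p * exp(-(latitude[s] - pref_lat)^2 / (2 * cfg$geo_bandwidth^2))
    }
    if (land_use[s] == "arable") {
      p <- p * (1 - cfg$h * q)
      if (cfg$mgmt_effect > 0) p <- p * (1 - cfg$mgmt_effect * z[s] * q)
    }
    pres <- stats::runif(cfg$n_otus) < p
    if (!any(pres)) pres[1] <- TRUE
    presence[s, ] <- pres
    prof <- rel * pres * exp(stats::rnorm(cfg$n_otus, 0, cfg$site_sigma))
    counts[s, ] <- stats::rmultinom(1, cfg$depth, prof)[, 1]
  }

  # 4. covariates: soil and climate linear in latitude + noise
  lat_c <- latitude - mean(range(blocks$lat_center))
  soil <- tibble::tibble(
    pH = 7.5 - 0.05 * lat_c + stats::rnorm(n_sites, 0, 0.3),
    total_C = pmax(0.2, 2 + 0.06 * lat_c + stats::rnorm(n_sites, 0, 0.4)),
    total_N = pmax(0.02, 0.18 + 0.005 * lat_c + stats::rnorm(n_sites, 0, 0.03)),
    CEC = pmax(1, 18 + 0.3 * lat_c + stats::rnorm(n_sites, 0, 2))
  )
  bio_slope <- seq(-1, 1, length.out = 19)
  climate <- purrr::map(seq_len(19), function(j) {
    bio_slope[j] * lat_c + stats::rnorm(n_sites, 0, 0.6)
  })
  names(climate) <- sprintf("bio%d", seq_len(19))
  climate <- tibble::as_tibble(climate)

  mgmt <- tibble::tibble(
    n_insecticide = ifelse(is.na(z), NA_integer_, stats::rpois(n_sites, 0.5 + 2 * ifelse(is.na(z), 0, z))),
    n_herbicide = ifelse(is.na(z), NA_integer_, stats::rpois(n_sites, 1 + 3 * ifelse(is.na(z), 0, z))),
    n_fungicide = ifelse(is.na(z), NA_integer_, stats::rpois(n_sites, 0.5 + 2.5 * ifelse(is.na(z), 0, z))),
    n_tillage_events = ifelse(is.na(z), NA_integer_, 1L + stats::rpois(n_sites, 1 + 2 * ifelse(is.na(z), 0, z))),
    max_tillage_depth_cm = ifelse(is.na(z), NA_real_, 5 + 25 * z + stats::rnorm(n_sites, 0, 2)),
    mineral_N_kg_ha = ifelse(is.na(z), NA_real_, pmax(0, 160 * z + stats::rnorm(n_sites, 0, 15)))
  )

  metadata <- dplyr::bind_cols(
    tibble::tibble(site_id = site_id, country = country, land_use = land_use,
                   latitude = latitude, longitude = longitude),
    soil, climate, mgmt
  )
  var_roles(metadata) <- c(
    stats::setNames(rep("soil", ncol(soil)), names(soil)),
    stats::setNames(rep("climate", ncol(climate)), names(climate)),
    stats::setNames(rep("mgmt", ncol(mgmt)), names(mgmt))
  )

  arable <- land_use == "arable"
  truth <- list(
    config = cfg,
    rel_abundance = stats::setNames(rel, otu_ids),
    occ_arable_true = colSums(presence[arable, , drop = FALSE]),
    occ_grassland_true = colSums(presence[!arable, , drop = FALSE]),
    presence = presence,
    pref_lat = stats::setNames(pref_lat, otu_ids),
    z = stats::setNames(z, site_id)
  )

  # drop OTUs that never received a read: the count table only carries
  # detected taxa (the truth record still covers the full pool)
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  list(counts = otu_tibble(counts), metadata = metadata, truth = truth)
}

#' Write a simulated triple to disk
#'
#' Serialises the output of [simulate_community()] as a counts TSV, a
#' metadata TSV, and a truth JSON (the presence matrix is summarised as
#' per-OTU true occupancies to keep the JSON small).
#'
#' @param sim Output of [simulate_community()].
#' @param dir Output directory (created if needed).
#' @return The three file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("counts.tsv", "metadata.tsv", "truth.json"))
  write_otu_table(sim$counts, paths[1])
  readr::write_tsv(sim$metadata, paths[2], progress = FALSE)
  tr <- sim$truth
  jsonlite::write_json(list(
    config = unclass(tr$config),
    rel_abundance = tr$rel_abundance,
    occ_arable_true = tr$occ_arable_true,
    occ_grassland_true = tr$occ_grassland_true,
    z = tr$z[!is.na(tr$z)]
  ), paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
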