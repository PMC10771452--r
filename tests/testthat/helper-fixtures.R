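# Fixtures are built in code: small count tables with known properties and
# a scaled-down simulation config so tests stay fast.

make_otu_table <- function(counts, site_ids = NULL, otu_ids = NULL) {
  m <- as.matrix(counts)
  rownames(m) <- site_ids %||% sprintf("s%d", seq_len(nrow(m)))
  colnames(m) <- otu_ids %||% sprintf("otu%d", seq_len(ncol(m)))
  tibble::as_tibble(m) |> dplyr::mutate(site_id = rownames(m), .before = 1)
}

random_otu_table <- function(n_sites, n_otus, max_count = 50, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_sites * n_otus, lambda = max_count / 5), n_sites, n_otus)
  m[sample(length(m), length(m) %/% 3)] <- 0
  # guarantee validity: no empty sites/OTUs
  m[, colSums(m) == 0] <- 1
  m[rowSums(m) == 0, 1] <- 1
  make_otu_table(m)
}

small_sim <- function(seed = 1, h = 0.6, ...) {
  simulate_community(sim_config(
    n_sites_arable = 24, n_sites_grassland = 16, n_otus = 120,
    depth = 400, h = h, seed = seed, ...))
}

two_group_metadata <- function(table, n_first) {
  tibble::tibble(
    site_id = table$site_id,
    land_use = rep(c("arable", "grassland"),
                   c(n_first, nrow(table) - n_first))
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
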