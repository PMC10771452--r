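# Cumulative sqrt-rank abundance curves, occupancy-abundance commonness,
# Levins' niche breadth with a permutation null, and the rarity classifier.

# Per-site rank matrix: sqrt-transform counts, sort each site's values in
# decreasing order, zero-pad to a common number of ranks. Rank-wise means of
# this matrix are the curve; the matrix itself feeds the per-rank tests.
site_rank_matrix <- function(m, n_ranks = NULL) {
  if (is.null(n_ranks)) n_ranks <- max(rowSums(m > 0))
  out <- matrix(0, nrow(m), n_ranks, dimnames = list(rownames(m), NULL))
  for (i in seq_len(nrow(m))) {
    v <- sort(sqrt(m[i, m[i, ] > 0]), decreasing = TRUE)
    v <- v[seq_len(min(length(v), n_ranks))]
    out[i, seq_along(v)] <- v
  }
  out
}

#' Cumulative abundance curves by land use
#'
#' For each site, counts are square-root transformed and ordered by
#' decreasing abundance; all sites are zero-padded to the table's maximum
#' per-site richness so rank-wise means are defined everywhere. The curve
#' for a land use is the rank-wise mean over its sites, accumulated over
#' ranks. Under biotic homogenization the curves share a head (abundant
#' OTUs similar in both land uses) but the disturbed land use's curve
#' flattens earlier in the tail, ending at a lower cumulative endpoint.
#'
#' @param table A validated OTU table.
#' @param metadata Site metadata with `land_use`.
#' @param land_use Optional single land use; default builds curves for every
#'   land use present, on a common rank grid.
#' @return A `rank_curve` tibble: `land_use`, `rank`, `mean_sqrt_abundance`,
#'   `cumulative`, with per-land-use endpoints (the cumulative value at the
#'   final rank) as an attribute `endpoints`.
#' @export
#' @examples
#' sim <- simulate_community(sim_config(n_sites_arable = 10,
#'   n_sites_grassland = 8, n_otus = 60, depth = 400, seed = 3))
#' cc <- cumulative_curve(sim$counts, sim$metadata)
#' attr(cc, "endpoints")
cumulative_curve <- function(table, metadata, land_use = NULL) {
  m <- otu_matrix(table)
  md <- align_metadata(table, metadata)
  uses <- land_use %||% sort(unique(md$land_use))
  n_ranks <- max(rowSums(m > 0))
  out <- purrr::map_dfr(uses, function(u) {
    rows <- md$land_use == u
    if (!any(rows)) stop("no sites with land use '", u, "'", call. = FALSE)
    rk <- site_rank_matrix(m[rows, , drop = FALSE], n_ranks)
    mu <- colMeans(rk)
    tibble::tibble(land_use = u, rank = seq_len(n_ranks),
                   mean_sqrt_abundance = mu, cumulative = cumsum(mu))
  })
  ep <- out |>
    dplyr::group_by(.data$land_use) |>
    dplyr::summarise(endpoint = max(.data$cumulative), .groups = "drop")
  structure(out, class = c("rank_curve", class(out)),
            endpoints = stats::setNames(ep$endpoint, ep$land_use))
}

# Welch's unequal-variance t computed explicitly so the degenerate
# zero-variance-in-both-groups case can return t = 0, p = 1 instead of
# erroring (t.test refuses essentially constant data).
welch_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) return(c(t = 0, df = n1 + n2 - 2, p = 1))
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  c(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Per-rank Welch tests between land-use curves
#'
#' At each abundance rank, compares the site-level sqrt-transformed
#' abundances of the two land uses with Welch's unequal-variance t-test.
#' Raw p values are reported (with a Benjamini-Hochberg column as an
#' option); ranks where both groups have zero variance get `t = 0, p = 1`.
#'
#' @param table A validated OTU table.
#' @param metadata Site metadata with `land_use` (exactly two types, each
#'   with at least two sites).
#' @param adjust Add a `p_adjusted` Benjamini-Hochberg column (default
#'   `TRUE`).
#' @return A tibble: `rank`, per-land-use means, `t`, `df`, `p_value` (and
#'   `p_adjusted`).
#' @export
curve_rank_tests <- function(table, metadata, adjust = TRUE) {
  m <- otu_matrix(table)
  md <- align_metadata(table, metadata)
  uses <- sort(unique(md$land_use))
  if (length(uses) != 2) stop("expected exactly two land-use types", call. = FALSE)
  if (any(table(md$land_use) < 2)) {
    stop("each land use needs at least two sites", call. = FALSE)
  }
  n_ranks <- max(rowSums(m > 0))
  rk1 <- site_rank_matrix(m[md$land_use == uses[1], , drop = FALSE], n_ranks)
  rk2 <- site_rank_matrix(m[md$land_use == uses[2], , drop = FALSE], n_ranks)
  res <- vapply(seq_len(n_ranks),
                function(r) welch_t(rk1[, r], rk2[, r]), numeric(3))
  out <- tibble::tibble(
    rank = seq_len(n_ranks),
    mean_1 = colMeans(rk1), mean_2 = colMeans(rk2),
    t = unname(res["t", ]), df = unname(res["df", ]),
    p_value = unname(res["p", ])
  )
  names(out)[2:3] <- paste0("mean_", uses)
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Occupancy-abundance relationship
#'
#' For each OTU: occupancy (number of sites where it is detected) and the
#' transformed abundance `log10(sqrt(total reads))`; their Spearman rank
#' correlation summarises the commonness relationship (abundant OTUs tend to
#' occupy more sites).
#'
#' @param table A validated OTU table.
#' @return A tibble `otu_id`, `occupancy`, `total_reads`,
#'   `transformed_abundance`, with the Spearman test (`rho`, `p_value`)
#'   attached as attribute `spearman`.
#' @export
occupancy_abundance <- function(table) {
  m <- otu_matrix(table)
  tot <- colSums(m)
  out <- tibble::tibble(
    otu_id = colnames(m),
    occupancy = as.integer(colSums(m > 0)),
    total_reads = unname(tot),
    transformed_abundance = unname(log10(sqrt(tot)))
  )
  ct <- suppressWarnings(
    stats::cor.test(out$occupancy, out$transformed_abundance,
                    method = "spearman", exact = FALSE))
  attr(out, "spearman") <- c(rho = unname(ct$estimate), p_value = ct$p.value)
  out
}

#' Levins' niche breadth per OTU
#'
#' For an OTU with proportional occurrence `p_j` across the `R` sites,
#' `B = 1 / sum(p_j^2)` and the standardized breadth `Bn = B / R`, which is
#' 1 for an OTU spread uniformly over all sites (a generalist) and `1/R`
#' for one confined to a single site (an extreme specialist).
#'
#' @param table A validated OTU table (typically the unrarefied "original"
#'   table).
#' @param normalize Compute `p_j` from per-site relative abundances instead
#'   of raw reads (default `FALSE`: raw reads, with the permutation null
#'   accounting for uneven depths).
#' @return A tibble `otu_id`, `b`, `bn`. OTUs with zero total count are an
#'   error (validate first).
#' @export
levins_bn <- function(table, normalize = FALSE) {
  m <- otu_matrix(table)
  if (nrow(m) < 2) stop("need at least two sites", call. = FALSE)
  if (normalize) m <- m / rowSums(m)
  tot <- colSums(m)
  if (any(tot == 0)) stop("OTU with zero total count; validate the table first",
                          call. = FALSE)
  p <- sweep(m, 2, tot, "/")
  b <- unname(1 / colSums(p^2))
  tibble::tibble(otu_id = colnames(m), b = b, bn = b / nrow(m))
}

#' Permutation null test for niche specialists
#'
#' Tests each OTU's standardized Levins' breadth against a null in which the
#' OTU's total reads are redistributed across sites as a multinomial with
#' probabilities proportional to site read totals — an abundance-conserving,
#' depth-aware null. The test is one-sided in the low tail (specialists have
#' narrow breadth): `p = (1 + #(Bn_null <= Bn_obs)) / (1 + n_perm)`.
#'
#' @param table A validated OTU table with at least two sites.
#' @param n_perm Number of null draws per OTU (default 999).
#' @param seed Integer seed.
#' @param alpha Significance level for the specialist flag (default 0.05).
#' @param normalize Passed to [levins_bn()] for the observed breadths; the
#'   null draws are evaluated the same way.
#' @return A tibble `otu_id`, `b`, `bn`, `null_quantile_05` (5th percentile
#'   of the null), `p_null`, `specialist`.
#' @export
bn_null_test <- function(table, n_perm = 999, seed = 1, alpha = 0.05,
                         normalize = FALSE) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  m <- otu_matrix(table)
  if (nrow(m) < 2) stop("need at least two sites", call. = FALSE)
  obs <- levins_bn(table, normalize = normalize)
  depths <- rowSums(m)
  probs <- depths / sum(depths)
  R <- nrow(m)
  with_seed(seed, {
    res <- purrr::map_dfr(seq_len(ncol(m)), function(j) {
      null_counts <- stats::rmultinom(n_perm, colSums(m)[j], probs)
      if (normalize) null_counts <- null_counts / depths
      ptab <- sweep(null_counts, 2, colSums(null_counts), "/")
      bn_null <- 1 / colSums(ptab^2) / R
      tibble::tibble(
        null_quantile_05 = unname(stats::quantile(bn_null, 0.05)),
        p_null = (1 + sum(bn_null <= obs$bn[j])) / (1 + n_perm)
      )
    })
    dplyr::bind_cols(obs, res) |>
      dplyr::mutate(specialist = .data$p_null <= alpha)
  })
}

#' Classify rare OTUs by occupancy and niche breadth
#'
#' An OTU is rare within a land use when it is present at no more than
#' `occupancy_cutoff` sites of that land use (but at least one) and its
#' standardized Levins' niche breadth — computed across all sites jointly —
#' is below `bn_cutoff`. Also emits the shared / arable-only /
#' grassland-only partition over all detected OTUs.
#'
#' @param table A validated OTU table; niche breadth should be computed on
#'   the unrarefied ("original") table.
#' @param metadata Site metadata with `land_use` (exactly two types).
#' @param bn Optional precomputed breadths ([levins_bn()] or
#'   [bn_null_test()] output); computed from `table` if missing.
#' @param occupancy_cutoff Maximum within-land-use occupancy for rarity
#'   (default 2 sites).
#' @param bn_cutoff Niche-breadth threshold (default 0.55).
#' @return A `rarity_classification` tibble: `otu_id`, per-land-use
#'   occupancies, `bn`, `rare_in_<land use>` flags, and `partition`
#'   (`"shared"`, `"<land use>_only"`).
#' @export
classify_rarity <- function(table, metadata, bn = NULL,
                            occupancy_cutoff = 2, bn_cutoff = 0.55) {
  if (occupancy_cutoff < 1) stop("occupancy_cutoff must be >= 1", call. = FALSE)
  if (bn_cutoff <= 0 || bn_cutoff > 1) stop("bn_cutoff must lie in (0, 1]",
                                            call. = FALSE)
  m <- otu_matrix(table)
  md <- align_metadata(table, metadata)
  uses <- sort(unique(md$land_use))
  if (length(uses) != 2) stop("expected exactly two land-use types", call. = FALSE)
  if (is.null(bn)) bn <- levins_bn(table)
  bn_vec <- bn$bn[match(colnames(m), bn$otu_id)]
  if (anyNA(bn_vec)) stop("bn records do not cover all OTUs", call. = FALSE)
  occ <- vapply(uses, function(u) {
    colSums(m[md$land_use == u, , drop = FALSE] > 0)
  }, numeric(ncol(m)))
  rare <- occ >= 1 & occ <= occupancy_cutoff & bn_vec < bn_cutoff
  partition <- dplyr::case_when(
    occ[, 1] > 0 & occ[, 2] > 0 ~ "shared",
    occ[, 1] > 0 ~ paste0(uses[1], "_only"),
    occ[, 2] > 0 ~ paste0(uses[2], "_only"),
    TRUE ~ "absent"
  )
  out <- tibble::tibble(
    otu_id = colnames(m),
    occupancy_1 = as.integer(occ[, 1]),
    occupancy_2 = as.integer(occ[, 2]),
    bn = bn_vec,
    rare_1 = rare[, 1],
    rare_2 = rare[, 2],
    partition = partition
  )
  names(out)[c(2, 3)] <- paste0("occupancy_", uses)
  names(out)[c(5, 6)] <- paste0("rare_in_", uses)
  structure(out, class = c("rarity_classification", class(out)),
            land_uses = uses,
            cutoffs = c(occupancy = occupancy_cutoff, bn = bn_cutoff))
}

#' Summarise a rarity classification
#'
#' @param classification Output of [classify_rarity()].
#' @return A one-row tibble: rare-OTU totals per land use and the
#'   shared/land-use-specific partition as percentages of detected OTUs.
#' @export
summarise_rarity <- function(classification) {
  uses <- attr(classification, "land_uses")
  detected <- classification$partition != "absent"
  n <- sum(detected)
  out <- tibble::tibble(
    n_otus = n,
    rare_total_1 = sum(classification[[paste0("rare_in_", uses[1])]]),
    rare_total_2 = sum(classification[[paste0("rare_in_", uses[2])]]),
    pct_shared = 100 * sum(classification$partition == "shared") / n,
    pct_only_1 = 100 * sum(classification$partition == paste0(uses[1], "_only")) / n,
    pct_only_2 = 100 * sum(classification$partition == paste0(uses[2], "_only")) / n
  )
  names(out)[2:3] <- paste0("rare_total_", uses)
  names(out)[5:6] <- paste0("pct_only_", uses)
  out
}

#' Per-country proportion of rare taxa
#'
#' For each country, the number of rare OTUs (flagged rare in either land
#' use) detected in that country divided by the total number of OTUs
#' detected there.
#'
#' @param table A validated OTU table.
#' @param metadata Site metadata with `country`.
#' @param classification Output of [classify_rarity()].
#' @return A tibble `country`, `n_otus`, `n_rare`, `proportion_rare`.
#' @export
rare_proportion_by_country <- function(table, metadata, classification) {
  m <- otu_matrix(table)
  md <- align_metadata(table, metadata)
  uses <- attr(classification, "land_uses")
  rare_any <- classification[[paste0("rare_in_", uses[1])]] |
    classification[[paste0("rare_in_", uses[2])]]
  rare_ids <- classification$otu_id[rare_any]
  purrr::map_dfr(sort(unique(md$country)), function(co) {
    present <- colSums(m[md$country == co, , drop = FALSE] > 0) > 0
    ids <- colnames(m)[present]
    tibble::tibble(country = co, n_otus = length(ids),
                   n_rare = sum(ids %in% rare_ids),
                   proportion_rare = sum(ids %in% rare_ids) / length(ids))
  })
}

#' How many prevalent OTUs make up a read fraction
#'
#' The smallest number k of most-abundant OTUs (by total reads within the
#' land-use stratum) whose summed reads reach at least `fraction` of the
#' stratum's reads — a concentration measure: dominated communities reach
#' 75% of reads with very few OTUs.
#'
#' @param table A validated OTU table.
#' @param metadata Site metadata with `land_use`.
#' @param land_use Stratum to evaluate.
#' @param fraction Target read fraction in `(0, 1]` (default 0.75).
#' @return Integer k.
#' @export
prevalent_concentration <- function(table, metadata, land_use, fraction = 0.75) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]",
                                          call. = FALSE)
  m <- otu_matrix(table)
  md <- align_metadata(table, metadata)
  rows <- md$land_use == land_use
  if (!any(rows)) stop("no sites with land use '", land_use, "'", call. = FALSE)
  tot <- sort(colSums(m[rows, , drop = FALSE]), decreasing = TRUE)
  share <- cumsum(tot) / sum(tot)
  as.integer(which(share >= fraction)[1])
}

#' Recall of planted rare OTUs against the generator truth
#'
#' Compares a rarity classification with the truth record of
#' [simulate_community()]. A planted rare OTU (for a land use) is one whose
#' true Bernoulli presence occurred at 1..`occupancy_cutoff` sites of that
#' land use — the classifier's occupancy gate evaluated on the true
#' presences instead of the observed counts. Recall is computed conditional
#' on detection: truly present tail OTUs routinely draw zero reads under
#' multinomial sampling at finite depth, so only planted rares detected at
#' >= 1 site of their land use enter the denominator.
#'
#' @param classification Output of [classify_rarity()].
#' @param truth Truth record from [simulate_community()].
#' @param table The OTU table the classification was computed on.
#' @param metadata Its site metadata.
#' @param occupancy_cutoff Cutoff used in the classification (default 2).
#' @return A tibble per land use: `n_planted_detected`, `n_recovered`,
#'   `recall`.
#' @export
rarity_recall <- function(classification, truth, table, metadata,
                          occupancy_cutoff = 2) {
  m <- otu_matrix(table)
  md <- align_metadata(table, metadata)
  uses <- attr(classification, "land_uses")
  occ_true <- list(arable = truth$occ_arable_true,
                   grassland = truth$occ_grassland_true)
  purrr::map_dfr(uses, function(u) {
    planted <- names(occ_true[[u]])[
      occ_true[[u]] >= 1 & occ_true[[u]] <= occupancy_cutoff]
    det <- colSums(m[md$land_use == u, , drop = FALSE] > 0)
    planted_det <- intersect(planted, colnames(m)[det >= 1])
    flagged <- classification$otu_id[classification[[paste0("rare_in_", u)]]]
    tibble::tibble(
      land_use = u,
      n_planted_detected = length(planted_det),
      n_recovered = length(intersect(planted_det, flagged)),
      recall = if (length(planted_det) == 0) NA_real_ else
        length(intersect(planted_det, flagged)) / length(planted_det)
    )
  })
}
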