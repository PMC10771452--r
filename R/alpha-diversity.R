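#' Shannon-Wiener index of one site
#'
#' `H = -sum(p_i * log(p_i))` over OTUs with positive counts, natural log
#' (the phyloseq convention).
#'
#' @param counts Non-negative count vector for one site.
#' @return The Shannon index, a scalar.
#' @export
shannon_index <- function(counts) {
  if (all(counts == 0)) stop("all-zero count vector", call. = FALSE)
  as.numeric(vegan::diversity(counts, index = "shannon"))
}

#' ACE richness estimator of one site
#'
#' Abundance-based Coverage Estimator (Chao & Lee): with rare OTUs those of
#' count `<= rare_cutoff`, sample coverage `C = 1 - F1/N_rare`, and
#' `gamma^2` the squared coefficient of variation of the rare counts,
#' `ACE = S_abund + S_rare/C + (F1/C) * gamma^2`. When every rare read is a
#' singleton the coverage estimate is zero and the estimator is undefined;
#' the function then falls back to bias-corrected Chao1 with a warning.
#'
#' @param counts Non-negative count vector for one site.
#' @param rare_cutoff Count at or below which an OTU is "rare" (default 10,
#'   the standard choice).
#' @return The ACE estimate (equals observed richness when no OTU is rare).
#' @export
ace_index <- function(counts, rare_cutoff = 10) {
  x <- counts[counts > 0]
  if (length(x) == 0) stop("all-zero count vector", call. = FALSE)
  rare <- x[x <= rare_cutoff]
  s_abund <- sum(x > rare_cutoff)
  s_rare <- length(rare)
  if (s_rare == 0) return(as.numeric(length(x)))
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    warning("all rare reads are singletons; falling back to Chao1", call. = FALSE)
    f2 <- sum(x == 2)
    return(length(x) + f1 * (f1 - 1) / (2 * (f2 + 1)))
  }
  fi <- tabulate(rare, nbins = rare_cutoff)
  i <- seq_len(rare_cutoff)
  gamma2 <- max(
    (s_rare / c_ace) * sum(i * (i - 1) * fi) / (n_rare * (n_rare - 1)) - 1,
    0
  )
  s_abund + s_rare / c_ace + (f1 / c_ace) * gamma2
}

#' Per-site alpha diversity
#'
#' Computes richness (observed OTUs), the natural-log Shannon-Wiener index,
#' and the ACE estimator for every site of an OTU table.
#'
#' @param table A validated OTU table.
#' @param rare_cutoff Passed to [ace_index()].
#' @return A tibble with `site_id`, `richness`, `shannon`, `ace`.
#' @export
#' @examples
#' sim <- simulate_community(sim_config(n_sites_arable = 6,
#'   n_sites_grassland = 4, n_otus = 80, depth = 300, seed = 7))
#' alpha_diversity(sim$counts)
alpha_diversity <- function(table, rare_cutoff = 10) {
  m <- otu_matrix(table)
  tibble::tibble(
    site_id = rownames(m),
    richness = as.integer(rowSums(m > 0)),
    shannon = apply(m, 1, shannon_index),
    ace = apply(m, 1, ace_index, rare_cutoff = rare_cutoff)
  )
}

#' Kruskal-Wallis rank-sum test on a data frame
#'
#' Nonparametric k-group comparison with tie correction; the degenerate
#' all-ties case returns `statistic = 0, p_value = 1` rather than `NaN` so
#' pipelines stay stable.
#'
#' @param data A data frame.
#' @param value Column of values (unquoted).
#' @param group Column of group labels (unquoted); every group must be
#'   nonempty and there must be at least two groups.
#' @return A one-row tibble: `statistic` (chi-squared approximation), `df`,
#'   `p_value`, `n_groups`, and a list-column `n_per_group`.
#' @export
kruskal_wallis <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) stop("need at least two nonempty groups", call. = FALSE)
  n_per <- table(g)
  if (any(n_per == 0)) stop("a group has zero observations", call. = FALSE)
  if (length(unique(v)) == 1) {
    kw <- list(statistic = 0, parameter = nlevels(g) - 1, p.value = 1)
  } else {
    kw <- stats::kruskal.test(v, g)
  }
  tibble::tibble(
    statistic = unname(as.numeric(kw$statistic)),
    df = as.integer(kw$parameter),
    p_value = unname(as.numeric(kw$p.value)),
    n_groups = nlevels(g),
    n_per_group = list(stats::setNames(as.integer(n_per), names(n_per)))
  )
}

#' Subsample the larger land-use stratum to a balanced design
#'
#' The survey design is unbalanced (many more arable than grassland sites);
#' as a robustness check, group comparisons can be re-run after randomly
#' subsampling the larger stratum down to the size of the smaller one.
#'
#' @param metadata Site metadata with a `land_use` column.
#' @param seed Integer seed for the random subsample.
#' @return The metadata restricted to a balanced site set (all sites of the
#'   smaller stratum, a random equal-size subset of the larger).
#' @export
balanced_site_subsample <- function(metadata, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  tab <- table(metadata$land_use)
  if (length(tab) != 2) stop("expected exactly two land-use types", call. = FALSE)
  small <- names(tab)[which.min(tab)]
  big <- setdiff(names(tab), small)
  n <- min(tab)
  big_ids <- metadata$site_id[metadata$land_use == big]
  keep_big <- with_seed(seed, sample(big_ids, n))
  out <- metadata[metadata$land_use == small | metadata$site_id %in% keep_big, ,
                  drop = FALSE]
  var_roles(out) <- var_roles(metadata)
  out
}
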