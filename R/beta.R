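#' Bray-Curtis dissimilarity between sites
#'
#' `d(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)`: 0 for identical count
#' vectors, 1 for disjoint supports.
#'
#' @param table A validated OTU table.
#' @return A `dist` object labelled by site id, entries in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  m <- otu_matrix(table)
  if (nrow(m) < 2) stop("need at least two sites", call. = FALSE)
  if (sum(rowSums(m) == 0) >= 2) {
    stop("Bray-Curtis is undefined between two all-zero sites", call. = FALSE)
  }
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: Gower double-centering of the squared distance
#' matrix, eigendecomposition, coordinates scaled by the square root of the
#' positive eigenvalues. Negative eigenvalues (possible for non-Euclidean
#' dissimilarities such as Bray-Curtis) are reported, not corrected.
#'
#' @param d A `dist` object.
#' @param k Number of axes to return (default: all with positive eigenvalue).
#' @return An object of class `pcoa_ord`: `coordinates` (tibble with
#'   `site_id` and `Axis1`, `Axis2`, ...), `eigenvalues` (full vector,
#'   including any negative ones), and `prop_explained` (relative to the sum
#'   of positive eigenvalues).
#' @export
pcoa_ordination <- function(d, k = NULL) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig), 1))
  if (is.null(k)) k <- max(pos, 1)
  k <- min(k, ncol(fit$points))
  pts <- fit$points[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_len(k))
  coords <- tibble::as_tibble(pts) |>
    dplyr::mutate(site_id = labels(d) %||% as.character(seq_len(n)), .before = 1)
  structure(list(
    coordinates = coords,
    eigenvalues = eig,
    prop_explained = pmax(eig, 0) / sum(pmax(eig, 0))
  ), class = "pcoa_ord")
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat("Principal coordinate analysis:", nrow(x$coordinates), "sites,",
      ncol(x$coordinates) - 1, "axes\n")
  pe <- round(100 * x$prop_explained[1:min(3, length(x$prop_explained))], 1)
  cat("Axis variance explained (%):", paste(pe, collapse = ", "), "\n")
  invisible(x)
}

#' PERMANOVA with sequential sums of squares
#'
#' Permutational multivariate analysis of variance on a dissimilarity matrix
#' (vegan's `adonis2` with `by = "terms"`): sequential (Type-I) sums of
#' squares, so term order matters and R-squared values over all terms plus
#' the residual sum to 1. Significance is by free permutation of site labels,
#' `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`.
#'
#' @param d A `dist` of between-site dissimilarities.
#' @param metadata Site metadata covering all sites of `d`.
#' @param terms Ordered character vector of model terms, e.g.
#'   `c("country", "land_use", "country:land_use")`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return A `permanova_fit`: tibble with one row per term plus `Residual`
#'   and `Total` (`df`, `sum_sq`, `r_squared`, `f`, `p_value`), with the
#'   permutation count as an attribute.
#' @export
permanova <- function(d, metadata, terms, n_perm = 999, seed = 1) {
  stopifnot(inherits(d, "dist"))
  ids <- labels(d)
  md <- metadata[match(ids, metadata$site_id), , drop = FALSE]
  if (anyNA(match(ids, metadata$site_id))) {
    stop("metadata does not cover all sites in the distance matrix", call. = FALSE)
  }
  main <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  for (v in main) {
    if (!v %in% names(md)) stop("term variable not in metadata: ", v, call. = FALSE)
    if (length(unique(md[[v]])) < 2) {
      stop("term '", v, "' has a single level", call. = FALSE)
    }
  }
  md <- dplyr::mutate(md, dplyr::across(dplyr::all_of(main), as.factor))
  f <- stats::as.formula(paste("d ~", paste(terms, collapse = " + ")))
  environment(f) <- environment()
  res <- with_seed(seed,
    vegan::adonis2(f, data = as.data.frame(md), permutations = n_perm,
                   by = "terms"))
  out <- tibble::tibble(
    term = rownames(res),
    df = res$Df,
    sum_sq = res$SumOfSqs,
    r_squared = res$R2,
    f = res$F,
    p_value = res$`Pr(>F)`
  )
  structure(out, class = c("permanova_fit", class(out)), n_perm = n_perm)
}

# Off-diagonal vectorization used by the Mantel statistics.
check_dist_pair <- function(a, b, what = c("a", "b")) {
  stopifnot(inherits(a, "dist"), inherits(b, "dist"))
  la <- labels(a); lb <- labels(b)
  if (!is.null(la) && !is.null(lb)) {
    if (!setequal(la, lb)) stop("distance matrices have different site sets",
                                call. = FALSE)
    if (!identical(la, lb)) {
      b <- stats::as.dist(as.matrix(b)[la, la])
    }
  } else if (attr(a, "Size") != attr(b, "Size")) {
    stop("distance matrices have different sizes", call. = FALSE)
  }
  for (x in list(a, b)) {
    if (stats::sd(as.vector(x)) == 0) {
      stop("constant off-diagonal entries: Mantel r undefined", call. = FALSE)
    }
  }
  list(a = a, b = b)
}

#' Simple and partial Mantel tests
#'
#' `mantel_test()` correlates the off-diagonal entries of two distance
#' matrices (Pearson r); `partial_mantel_test()` computes the first-order
#' partial correlation `r_ab.c = (r_ab - r_ac*r_bc) /
#' sqrt((1-r_ac^2)(1-r_bc^2))` controlling a third matrix. Significance is by
#' jointly permuting rows and columns of the first (community) matrix while
#' holding the others fixed, vegan's convention.
#'
#' @param a Community dissimilarity (`dist`); this is the matrix permuted.
#' @param b Second `dist` (e.g. geographic or environmental distance).
#' @param c_ Conditioning `dist` for the partial test.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A `mantel_result` one-row tibble: `r`, `p_value`, `n_perm`,
#'   `conditioning` (`NA` for the simple test).
#' @export
mantel_test <- function(a, b, n_perm = 999, seed = 1) {
  ab <- check_dist_pair(a, b)
  res <- with_seed(seed, vegan::mantel(ab$a, ab$b, permutations = n_perm))
  out <- tibble::tibble(r = unname(res$statistic),
                        p_value = res$signif,
                        n_perm = n_perm,
                        conditioning = NA_character_)
  structure(out, class = c("mantel_result", class(out)))
}

#' @rdname mantel_test
#' @export
partial_mantel_test <- function(a, b, c_, n_perm = 999, seed = 1) {
  ab <- check_dist_pair(a, b)
  ac <- check_dist_pair(ab$a, c_)
  res <- with_seed(seed,
    vegan::mantel.partial(ac$a, ab$b, ac$b, permutations = n_perm))
  out <- tibble::tibble(r = unname(res$statistic),
                        p_value = res$signif,
                        n_perm = n_perm,
                        conditioning = "third_matrix")
  structure(out, class = c("mantel_result", class(out)))
}

#' Great-circle geographic distance between sites
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param metadata Site metadata with `site_id`, `latitude`, `longitude`.
#' @return A `dist` of distances in kilometres, labelled by site id.
#' @export
geo_distance <- function(metadata) {
  stopifnot(all(c("site_id", "latitude", "longitude") %in% names(metadata)))
  xy <- cbind(metadata$longitude, metadata$latitude)
  m <- geosphere::distm(xy, fun = function(p1, p2) {
    geosphere::distHaversine(p1, p2, r = 6371000)
  }) / 1000
  dimnames(m) <- list(metadata$site_id, metadata$site_id)
  stats::as.dist(m)
}

#' Environmental distance between sites
#'
#' Euclidean distance on z-standardized covariates (centred, scaled by the
#' population standard deviation, so two sites with a single covariate sit
#' at z = -1 and +1 exactly). The variable set is
#' resolved from the metadata's role attribute (`"all_env"` = soil + climate,
#' `"climate"`, `"soil"`) or given explicitly via `vars`. Sites with missing
#' values in the selected variables are dropped with a warning.
#'
#' @param metadata Site metadata.
#' @param variable_set One of `"all_env"`, `"climate"`, `"soil"`.
#' @param vars Optional explicit character vector of covariate columns,
#'   overriding `variable_set`.
#' @return A `dist` labelled by site id.
#' @export
env_distance <- function(metadata, variable_set = "all_env", vars = NULL) {
  if (is.null(vars)) vars <- resolve_variable_set(metadata, variable_set)
  x <- as.matrix(metadata[vars])
  ok <- stats::complete.cases(x)
  if (any(!ok)) {
    warning(sum(!ok), " site(s) with missing covariates dropped", call. = FALSE)
    x <- x[ok, , drop = FALSE]
  }
  if (nrow(x) < 2) stop("fewer than two complete sites", call. = FALSE)
  n <- nrow(x)
  z <- scale(x) * sqrt(n / (n - 1)) # population-SD z-scores
  z <- z[, !is.nan(colSums(z)), drop = FALSE] # constant columns scale to NaN
  rownames(z) <- metadata$site_id[ok]
  stats::dist(z)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
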