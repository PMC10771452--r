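# Geographic/environmental driver analysis: polynomial gradient models with
# AICc selection, covariate PCA with collinearity pruning, PC1 regressions,
# and the PCA-based management-intensity index.

#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2k(k+1)/(n-k-1)` with k the number of estimated parameters
#' (coefficients plus the error variance).
#'
#' @param model A fitted `lm`.
#' @return The AICc value (finite only when `n - k - 1 > 0`).
#' @export
aicc <- function(model) {
  ll <- stats::logLik(model)
  k <- attr(ll, "df")
  n <- stats::nobs(model)
  if (n - k - 1 <= 0) stop("AICc undefined: n <= k + 1", call. = FALSE)
  stats::AIC(model) + 2 * k * (k + 1) / (n - k - 1)
}

#' Polynomial gradient models with AICc selection
#'
#' Fits first- and second-order polynomial OLS models of a response (e.g.
#' fungal richness) against a geographic predictor (latitude or longitude)
#' and keeps the order with the lower AICc. Optionally stratified by land
#' use.
#'
#' @param data A data frame holding response and predictor columns (join
#'   alpha diversity onto metadata first).
#' @param response,predictor Unquoted column names.
#' @param by_land_use Fit separately per `land_use` stratum.
#' @return A `latlon_fit`: tibble with one row per (stratum x) order —
#'   `order`, `aicc`, `adj_r_squared`, `n`, `best` flag — carrying the
#'   fitted `lm` objects as an attribute `models`.
#' @export
fit_latlon_models <- function(data, response, predictor, by_land_use = FALSE) {
  y_name <- rlang::as_name(rlang::enquo(response))
  x_name <- rlang::as_name(rlang::enquo(predictor))
  strata <- if (by_land_use) split(data, data$land_use) else list(all = data)
  models <- list()
  rows <- purrr::imap_dfr(strata, function(d, stratum) {
    d <- d[stats::complete.cases(d[c(y_name, x_name)]), , drop = FALSE]
    if (nrow(d) < 5) stop("need at least 5 sites per stratum", call. = FALSE)
    fits <- purrr::map(1:2, function(ord) {
      stats::lm(stats::reformulate(sprintf("poly(%s, %d, raw = TRUE)", x_name, ord),
                                   response = y_name), data = d)
    })
    models[[stratum]] <<- fits
    tibble::tibble(
      stratum = stratum,
      order = 1:2,
      aicc = vapply(fits, aicc, 0),
      adj_r_squared = vapply(fits, function(f) summary(f)$adj.r.squared, 0),
      n = nrow(d)
    ) |>
      dplyr::mutate(best = .data$aicc == min(.data$aicc))
  })
  structure(rows, class = c("latlon_fit", class(rows)),
            models = models, response = y_name, predictor = x_name)
}

#' Coefficients of the AICc-best polynomial model
#'
#' @param fit A [fit_latlon_models()] result.
#' @param stratum Stratum name (default `"all"`).
#' @return Named numeric coefficient vector of the winning model.
#' @export
best_latlon_coef <- function(fit, stratum = "all") {
  rows <- fit[fit$stratum == stratum, ]
  if (nrow(rows) == 0) stop("unknown stratum '", stratum, "'", call. = FALSE)
  best_order <- rows$order[rows$best][1]
  stats::coef(attr(fit, "models")[[stratum]][[best_order]])
}

# Greedy collinearity pruning: walk columns in order, drop any later column
# whose |Spearman rho| with a kept column exceeds the threshold.
prune_collinear <- function(x, prune_r = 0.95) {
  keep <- character()
  for (v in colnames(x)) {
    rho <- if (length(keep) == 0) 0 else
      suppressWarnings(abs(stats::cor(x[, v], x[, keep, drop = FALSE],
                                      method = "spearman")))
    if (all(rho <= prune_r)) keep <- c(keep, v)
  }
  keep
}

#' PCA of environmental covariates with collinearity pruning
#'
#' Z-standardizes the selected covariates, greedily drops the later member
#' of every pair with `|Spearman rho| > prune_r` (keeping the first in
#' column order), and runs PCA on the correlation matrix. PC1's sign is
#' oriented so it correlates positively with the first retained variable.
#' Constant variables are dropped with a warning; sites with missing values
#' are dropped with a warning.
#'
#' @param metadata Site metadata (variable roles resolve `variable_set`).
#' @param variable_set `"all_env"`, `"climate"`, or `"soil"`.
#' @param vars Optional explicit covariate columns.
#' @param prune_r Collinearity threshold (default 0.95).
#' @return A `covariate_pca`: `scores` (tibble `site_id`, `PC1`, ...),
#'   `loadings` matrix, `var_explained`, `retained` and `pruned` variable
#'   names.
#' @export
covariate_pca <- function(metadata, variable_set = "climate", vars = NULL,
                          prune_r = 0.95) {
  if (is.null(vars)) vars <- resolve_variable_set(metadata, variable_set)
  x <- as.matrix(metadata[vars])
  ok <- stats::complete.cases(x)
  if (any(!ok)) warning(sum(!ok), " site(s) with missing covariates dropped",
                        call. = FALSE)
  x <- x[ok, , drop = FALSE]
  constant <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(constant)) {
    warning("constant variable(s) dropped: ",
            paste(colnames(x)[constant], collapse = ", "), call. = FALSE)
    x <- x[, !constant, drop = FALSE]
  }
  retained <- prune_collinear(x, prune_r)
  pruned <- setdiff(colnames(x), retained)
  if (length(retained) < 2) stop("fewer than 2 variables after pruning",
                                 call. = FALSE)
  x <- x[, retained, drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- stats::cor(pc$x[, 1], x[, 1]) < 0
  if (isTRUE(flip)) {
    pc$x[, 1] <- -pc$x[, 1]
    pc$rotation[, 1] <- -pc$rotation[, 1]
  }
  scores <- tibble::as_tibble(pc$x) |>
    dplyr::mutate(site_id = metadata$site_id[ok], .before = 1)
  structure(list(
    scores = scores,
    loadings = pc$rotation,
    var_explained = pc$sdev^2 / sum(pc$sdev^2),
    retained = retained, pruned = pruned
  ), class = "covariate_pca")
}

#' @export
print.covariate_pca <- function(x, ...) {
  cat("Covariate PCA:", length(x$retained), "variables retained",
      if (length(x$pruned)) paste0("(", length(x$pruned), " pruned)") else "", "\n")
  cat("PC1 variance explained:", round(100 * x$var_explained[1], 1), "%\n")
  invisible(x)
}

#' Linear regression of a response on PC1
#'
#' OLS of a diversity response on the first principal component of the
#' covariate PCA, optionally per land-use stratum.
#'
#' @param data Data frame holding the response, a `pc1` column (join
#'   `covariate_pca()$scores` first, renaming `PC1` as needed), and
#'   `land_use` if stratified.
#' @param response Unquoted response column.
#' @param pc1 Unquoted predictor column (default `PC1`).
#' @param by_land_use Fit per stratum.
#' @return A tibble per stratum: `slope`, `intercept`, `adj_r_squared`,
#'   `p_value` (two-sided, for the slope), `n`.
#' @export
pc1_regression <- function(data, response, pc1 = PC1, by_land_use = FALSE) {
  y_name <- rlang::as_name(rlang::enquo(response))
  x_name <- rlang::as_name(rlang::enquo(pc1))
  strata <- if (by_land_use) split(data, data$land_use) else list(all = data)
  purrr::imap_dfr(strata, function(d, stratum) {
    d <- d[stats::complete.cases(d[c(y_name, x_name)]), , drop = FALSE]
    if (nrow(d) < 3) stop("need at least 3 complete sites", call. = FALSE)
    if (stats::sd(d[[x_name]]) == 0) stop("zero-variance predictor", call. = FALSE)
    fit <- stats::lm(stats::reformulate(x_name, response = y_name), data = d)
    sm <- summary(fit)
    tibble::tibble(
      stratum = stratum,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      adj_r_squared = sm$adj.r.squared,
      p_value = sm$coefficients[2, 4],
      n = nrow(d)
    )
  })
}

#' Agricultural management-intensity index
#'
#' Collapses the six management variables (insecticide, herbicide and
#' fungicide application counts, tillage events, maximum tillage depth,
#' mineral nitrogen applied) into a single index: z-standardize, PCA, take
#' PC1, orient its sign so the mean loading is positive (higher = more
#' intensive), and min-max scale to `[0, 1]` — 0 the least intensively
#' managed site, 1 the most. Defined for arable sites; sites missing any
#' management variable are dropped with a warning.
#'
#' @param metadata Site metadata containing the management columns
#'   (`n_insecticide`, `n_herbicide`, `n_fungicide`, `n_tillage_events`,
#'   `max_tillage_depth_cm`, `mineral_N_kg_ha`) and optionally a
#'   `crop_diversity` column, included when present.
#' @param mgmt_vars Management columns (default the six above plus
#'   `crop_diversity` if present).
#' @return An `intensity_index` tibble: `site_id`, `intensity` in `[0, 1]`,
#'   with PC1 `loadings` and the variance explained as attributes.
#' @export
intensity_index <- function(metadata, mgmt_vars = NULL) {
  if (is.null(mgmt_vars)) {
    mgmt_vars <- c(MGMT_VARS, intersect("crop_diversity", names(metadata)))
  }
  missing_cols <- setdiff(mgmt_vars, names(metadata))
  if (length(missing_cols) > 0) {
    stop("management variables missing from metadata: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  md <- metadata
  if ("land_use" %in% names(md)) md <- md[md$land_use == "arable", , drop = FALSE]
  x <- as.matrix(md[mgmt_vars])
  ok <- stats::complete.cases(x)
  if (any(!ok)) warning(sum(!ok), " site(s) with incomplete management data dropped",
                        call. = FALSE)
  x <- x[ok, , drop = FALSE]
  if (nrow(x) < 3) stop("need at least 3 complete arable sites", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  sgn <- if (mean(pc$rotation[, 1]) < 0) -1 else 1
  pc1 <- sgn * pc$x[, 1]
  rng <- range(pc1)
  intensity <- if (diff(rng) == 0) rep(0, length(pc1)) else
    (pc1 - rng[1]) / diff(rng)
  out <- tibble::tibble(site_id = md$site_id[ok], intensity = intensity)
  structure(out, class = c("intensity_index", class(out)),
            loadings = sgn * pc$rotation[, 1],
            var_explained = pc$sdev[1]^2 / sum(pc$sdev^2),
            orientation_sign = sgn)
}

#' Spearman correlations of the intensity index with diversity responses
#'
#' @param data Data frame with an `intensity` column and the response
#'   columns (join [intensity_index()] onto per-site diversity first).
#' @param ... Unquoted response columns (e.g. `richness`, `rare_richness`).
#' @return A tibble per response: `rho`, `p_value` (two-sided), `n`.
#' @export
intensity_correlations <- function(data, ...) {
  responses <- sapply(rlang::enquos(...), rlang::as_name)
  if (length(responses) == 0) stop("supply at least one response column",
                                   call. = FALSE)
  purrr::map_dfr(responses, function(v) {
    d <- data[stats::complete.cases(data[c("intensity", v)]), , drop = FALSE]
    if (nrow(d) < 5) stop("need at least 5 complete sites", call. = FALSE)
    if (stats::sd(d[[v]]) == 0 || stats::sd(d$intensity) == 0) {
      stop("constant input for '", v, "'", call. = FALSE)
    }
    ct <- suppressWarnings(
      stats::cor.test(d$intensity, d[[v]], method = "spearman", exact = FALSE))
    tibble::tibble(response = v, rho = unname(ct$estimate),
                   p_value = ct$p.value, n = nrow(d))
  })
}
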