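# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PERMANOVA fit
#'
#' @param x A `permanova_fit`.
#' @param ... Unused.
#' @return A tibble with one row per term (plus residual and total).
#' @method tidy permanova_fit
#' @export
tidy.permanova_fit <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.permanova_fit
#' @method glance permanova_fit
#' @export
glance.permanova_fit <- function(x, ...) {
  terms <- x[!x$term %in% c("Residual", "Total"), ]
  tibble::tibble(
    r_squared_model = sum(terms$r_squared),
    df_model = sum(terms$df),
    n_terms = nrow(terms),
    n_perm = attr(x, "n_perm")
  )
}

#' Tidy a Mantel test result
#'
#' @param x A `mantel_result`.
#' @param ... Unused.
#' @return A one-row tibble: `r`, `p_value`, `n_perm`, `conditioning`.
#' @method tidy mantel_result
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Tidy a polynomial gradient-model comparison
#'
#' @param x A `latlon_fit`.
#' @param ... Unused.
#' @return The per-order comparison table as a plain tibble.
#' @method tidy latlon_fit
#' @export
tidy.latlon_fit <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.latlon_fit
#' @method glance latlon_fit
#' @export
glance.latlon_fit <- function(x, ...) {
  x |>
    tibble::as_tibble() |>
    dplyr::filter(.data$best) |>
    dplyr::select("stratum", best_order = "order", "aicc", "adj_r_squared", "n")
}

#' Tidy a covariate PCA
#'
#' @param x A `covariate_pca`.
#' @param ... Unused.
#' @return Loadings in long form: `variable`, `component`, `loading`.
#' @method tidy covariate_pca
#' @export
tidy.covariate_pca <- function(x, ...) {
  l <- x$loadings
  tibble::as_tibble(l, rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "component",
                        values_to = "loading")
}

#' @rdname tidy.covariate_pca
#' @method glance covariate_pca
#' @export
glance.covariate_pca <- function(x, ...) {
  tibble::tibble(
    n_retained = length(x$retained),
    n_pruned = length(x$pruned),
    pc1_var_explained = x$var_explained[1],
    pc2_var_explained = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_
  )
}
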