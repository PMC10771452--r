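# Internal helpers shared across modules.

#' Extract the count matrix from an OTU tibble
#'
#' @param table An OTU table as returned by [read_otu_table()]: a data frame
#'   whose first column is `site_id` and whose remaining columns are OTU
#'   counts.
#' @return A numeric matrix, sites in rows (named by `site_id`), OTUs in
#'   columns.
#' @keywords internal
otu_matrix <- function(table) {
  stopifnot(is.data.frame(table), "site_id" %in% names(table))
  m <- as.matrix(table[setdiff(names(table), "site_id")])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(table$site_id)
  m
}

#' Rebuild an OTU tibble from a count matrix
#' @keywords internal
otu_tibble <- function(m) {
  tibble::as_tibble(m, .name_repair = "minimal") |>
    dplyr::mutate(site_id = rownames(m), .before = 1)
}

# Align metadata rows to the site order of an OTU table; errors on missing
# sites (the metadata must cover every site used in a joined operation).
align_metadata <- function(table, metadata) {
  stopifnot("site_id" %in% names(metadata))
  missing <- setdiff(table$site_id, metadata$site_id)
  if (length(missing) > 0) {
    stop("metadata is missing sites: ", paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ..." else "", call. = FALSE)
  }
  metadata[match(table$site_id, metadata$site_id), , drop = FALSE]
}

# Variable-role bookkeeping: a named character vector column -> role.
# Roles used downstream: "soil", "climate", "mgmt"; anything else is ignored
# by the variable-set selectors.
var_roles <- function(metadata) {
  attr(metadata, "var_roles")
}

`var_roles<-` <- function(metadata, value) {
  attr(metadata, "var_roles") <- value
  metadata
}

# Resolve a variable set ("all_env", "climate", "soil") into column names,
# from the metadata's role attribute.
resolve_variable_set <- function(metadata, variable_set) {
  roles <- var_roles(metadata)
  if (is.null(roles)) {
    stop("metadata carries no variable roles; pass `vars` explicitly or use ",
         "`read_site_metadata()`/`simulate_community()` output", call. = FALSE)
  }
  variable_set <- match.arg(variable_set, c("all_env", "climate", "soil"))
  keep <- switch(variable_set,
    all_env = names(roles)[roles %in% c("climate", "soil")],
    climate = names(roles)[roles == "climate"],
    soil    = names(roles)[roles == "soil"]
  )
  if (length(keep) == 0) stop("no variables with role(s) for set '", variable_set, "'",
                              call. = FALSE)
  keep
}

MGMT_VARS <- c("n_insecticide", "n_herbicide", "n_fungicide",
               "n_tillage_events", "max_tillage_depth_cm", "mineral_N_kg_ha")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
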