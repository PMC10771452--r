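#' Read an OTU-by-site count table
#'
#' Reads a tab- or comma-separated count table with one header row and one id
#' column, validates it, and returns it in the package's internal layout:
#' one row per site (`site_id` column) and one numeric column per OTU.
#'
#' @param path Path to a TSV/CSV file. The delimiter is taken from the file
#'   extension (`.csv` means comma, anything else tab) unless `delim` is given.
#' @param otus_as_rows Orientation of the file on disk. `FALSE` (default)
#'   means sites are rows; `TRUE` means OTUs are rows and the table is
#'   transposed on read so the internal layout is always sites x OTUs.
#' @param delim Optional explicit field delimiter.
#' @param drop_empty_otus Drop OTUs whose total count is zero (default `TRUE`,
#'   with a warning listing how many were dropped).
#' @return A tibble with `site_id` and one integer-valued column per OTU.
#'   Counts are validated: any negative or non-integer cell is a hard error
#'   naming the offending site and OTU; duplicate site or OTU ids are errors;
#'   all-zero sites are dropped with a warning so every retained row total is
#'   positive.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("site_id\totu1\totu2", "s1\t5\t0", "s2\t1\t2"), tf)
#' read_otu_table(tf)
read_otu_table <- function(path, otus_as_rows = FALSE, delim = NULL,
                           drop_empty_otus = TRUE) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 2) stop("expected an id column plus at least one count column",
                          call. = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[-1])
  if (!is.numeric(m)) stop("count columns must be numeric", call. = FALSE)
  rownames(m) <- ids
  if (otus_as_rows) m <- t(m)
  validate_otu_table(otu_tibble(m), drop_empty_otus = drop_empty_otus)
}

#' Validate an OTU table
#'
#' Enforces the count-table invariants: non-negative integer counts, unique
#' site and OTU ids, positive row totals. Zero-total OTUs are dropped (with a
#' warning) when `drop_empty_otus = TRUE`; zero-total sites are always dropped
#' with a warning.
#'
#' @param table A data frame with a `site_id` column and numeric OTU columns.
#' @param drop_empty_otus Drop all-zero OTU columns.
#' @return The validated table as a tibble.
#' @export
validate_otu_table <- function(table, drop_empty_otus = TRUE) {
  m <- otu_matrix(table)
  if (anyNA(m)) stop("OTU table contains missing values", call. = FALSE)
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid count %s at site '%s', OTU '%s' (must be a non-negative integer)",
                 format(m[bad[1, , drop = FALSE]]),
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate site id: ", rownames(m)[duplicated(rownames(m))][1], call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate OTU id: ", colnames(m)[duplicated(colnames(m))][1], call. = FALSE)
  }
  empty_otu <- colSums(m) == 0
  if (drop_empty_otus && any(empty_otu)) {
    warning(sum(empty_otu), " OTU(s) with zero total count dropped", call. = FALSE)
    m <- m[, !empty_otu, drop = FALSE]
  }
  empty_site <- rowSums(m) == 0
  if (any(empty_site)) {
    warning(sum(empty_site), " site(s) with zero total count dropped: ",
            paste(utils::head(rownames(m)[empty_site], 5), collapse = ", "),
            call. = FALSE)
    m <- m[!empty_site, , drop = FALSE]
  }
  if (nrow(m) == 0) stop("no sites left after validation", call. = FALSE)
  otu_tibble(m)
}

#' Write an OTU table to disk
#'
#' @inheritParams read_otu_table
#' @param table A validated OTU table.
#' @param path Output path; `.csv` extension writes comma-separated, anything
#'   else tab-separated.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, otus_as_rows = FALSE, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  m <- otu_matrix(table)
  if (otus_as_rows) {
    m <- t(m)
    out <- tibble::as_tibble(m, .name_repair = "minimal") |>
      dplyr::mutate(otu_id = rownames(m), .before = 1)
  } else {
    out <- otu_tibble(m)
  }
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Read site metadata with declared column roles
#'
#' Metadata arrives as a TSV/CSV with one row per site. Column roles (which
#' columns are soil chemistry, which are bioclimatic, which are management)
#' are declared either as a named character vector or as a small `key = value`
#' config file, one `column = role` pair per line. Recognised roles:
#' `site_id`, `country`, `land_use`, `latitude`, `longitude`, `soil`,
#' `climate`, `mgmt`; unrecognised roles are kept but ignored by the
#' variable-set selectors.
#'
#' @param path Path to the metadata table.
#' @param roles Named character vector (`c(pH = "soil", bio1 = "climate")`) or
#'   path to a config file of `column = role` lines. Columns named exactly
#'   `site_id`, `country`, `land_use`, `latitude`, `longitude` are recognised
#'   without declaration.
#' @param delim Optional explicit delimiter.
#' @return A tibble of site metadata carrying the role map as an attribute;
#'   latitude/longitude are range-checked.
#' @export
read_site_metadata <- function(path, roles = NULL, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  md <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          show_col_types = FALSE, progress = FALSE)
  if (is.character(roles) && length(roles) == 1 && is.null(names(roles)) &&
      file.exists(roles)) {
    lines <- readLines(roles)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    kv <- strsplit(lines, "=", fixed = TRUE)
    roles <- stats::setNames(trimws(vapply(kv, `[`, "", 2)),
                             trimws(vapply(kv, `[`, "", 1)))
  }
  # rename core columns declared via roles
  core <- c("site_id", "country", "land_use", "latitude", "longitude")
  if (!is.null(roles)) {
    for (col in names(roles)[roles %in% core]) {
      names(md)[names(md) == col] <- roles[[col]]
    }
    roles <- roles[!roles %in% core]
  }
  if (!"site_id" %in% names(md)) stop("metadata must have a site_id column",
                                      call. = FALSE)
  md$site_id <- as.character(md$site_id)
  if (anyDuplicated(md$site_id)) stop("duplicate site_id in metadata", call. = FALSE)
  if ("latitude" %in% names(md) &&
      any(md$latitude < -90 | md$latitude > 90, na.rm = TRUE)) {
    stop("latitude outside [-90, 90]", call. = FALSE)
  }
  if ("longitude" %in% names(md) &&
      any(md$longitude < -180 | md$longitude > 180, na.rm = TRUE)) {
    stop("longitude outside [-180, 180]", call. = FALSE)
  }
  var_roles(md) <- roles
  md
}

#' Read a taxonomy table
#'
#' @param path TSV/CSV with an `otu_id` column and rank columns
#'   kingdom..genus; missing assignments may be the string "unclassified".
#' @param delim Optional explicit delimiter.
#' @return A tibble with unique `otu_id` and the rank columns in canonical
#'   order (of those present).
#' @export
read_taxonomy_table <- function(path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  tx <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          show_col_types = FALSE, progress = FALSE)
  if (!"otu_id" %in% names(tx)) stop("taxonomy must have an otu_id column",
                                     call. = FALSE)
  if (anyDuplicated(tx$otu_id)) stop("duplicate otu_id in taxonomy", call. = FALSE)
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  present <- intersect(ranks, names(tx))
  dplyr::select(tx, "otu_id", dplyr::all_of(present),
                dplyr::everything())
}

#' Rarefy an OTU table to a fixed depth
#'
#' Subsamples each site's reads without replacement to a common depth, the
#' standard correction for uneven sequencing effort. Sites with fewer reads
#' than `depth` are dropped with a warning. A single draw is taken per site;
#' the seed is a required argument so the draw is reproducible.
#'
#' @param table A validated OTU table.
#' @param depth Target reads per site (must be >= 1).
#' @param seed Integer seed for the subsampling draw.
#' @param drop_empty_otus Drop OTUs that become all-zero after rarefaction
#'   (default `FALSE`: they are retained so OTU ids stay aligned with the
#'   unrarefied table).
#' @return A rarefied OTU tibble; every retained site row sums to exactly
#'   `depth`.
#' @export
rarefy <- function(table, depth, seed, drop_empty_otus = FALSE) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (!is.numeric(depth) || length(depth) != 1 || depth < 1) {
    stop("`depth` must be a positive integer", call. = FALSE)
  }
  depth <- as.integer(depth)
  m <- otu_matrix(table)
  totals <- rowSums(m)
  keep <- totals >= depth
  if (!any(keep)) stop("all sites have fewer than ", depth, " reads", call. = FALSE)
  if (any(!keep)) {
    warning(sum(!keep), " site(s) below depth ", depth, " dropped: ",
            paste(utils::head(rownames(m)[!keep], 5), collapse = ", "),
            call. = FALSE)
    m <- m[keep, , drop = FALSE]
  }
  r <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(m, depth),
    # vegan advises when counts look unusual; not actionable here
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  out <- otu_tibble(r)
  if (drop_empty_otus) {
    tot <- colSums(otu_matrix(out))
    if (any(tot == 0)) out <- out[, c(TRUE, tot > 0)]
  }
  out
}

#' Per-site OTU richness
#'
#' @param table A validated OTU table.
#' @return A tibble with `site_id` and `richness`, the number of OTUs with a
#'   positive count at that site.
#' @export
richness_per_site <- function(table) {
  m <- otu_matrix(table)
  tibble::tibble(site_id = rownames(m), richness = as.integer(rowSums(m > 0)))
}

#' Drop low-abundance OTUs
#'
#' Optional pre-filter removing OTUs whose overall relative abundance falls
#' below a threshold (and, optionally, singletons).
#'
#' @param table A validated OTU table.
#' @param threshold Overall relative-abundance cutoff (default 0.005, i.e.
#'   0.5%); OTUs strictly below it are removed. The comparison uses the OTU's
#'   total reads over the table's total reads.
#' @param drop_singletons Also remove OTUs with exactly one read in total.
#' @return The filtered tibble.
#' @export
filter_low_abundance <- function(table, threshold = 0.005, drop_singletons = TRUE) {
  m <- otu_matrix(table)
  tot <- colSums(m)
  keep <- tot / sum(tot) >= threshold
  if (drop_singletons) keep <- keep & tot > 1
  if (!any(keep)) stop("no OTUs pass the abundance filter", call. = FALSE)
  validate_otu_table(otu_tibble(m[, keep, drop = FALSE]), drop_empty_otus = FALSE)
}
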