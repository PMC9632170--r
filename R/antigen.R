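# Matching clustered T clonotypes against an antigen-annotated CDR3beta
# database and per-cluster fold enrichment.

#' Load an antigen-annotated CDR3beta table
#'
#' Reads a TSV of (CDR3beta amino-acid sequence, antigen category) pairs in
#' the style of McPAS-TCR or VDJdb slim exports, with configurable column
#' names. Rows with invalid residues are dropped with a warning and
#' (cdr3, category) pairs are deduplicated; a clonotype may carry several
#' categories.
#'
#' @param path TSV path.
#' @param cdr3_col,category_col column names (defaults `"cdr3"` and
#'   `"category"`; McPAS uses `CDR3.beta.aa`/`Pathology`, VDJdb uses
#'   `cdr3`/`antigen.species`).
#' @param categories optional whitelist of categories to retain.
#' @return tibble of class `"antigen_db"` with columns `cdr3b_aa`,
#'   `antigen_category`.
#' @export
load_antigen_table <- function(path, cdr3_col = "cdr3",
                               category_col = "category",
                               categories = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c(cdr3_col, category_col) %in% names(raw))) {
    abort(sprintf("antigen table must contain columns '%s' and '%s'",
                  cdr3_col, category_col), class = "crossrep_format_error")
  }
  db <- tibble(cdr3b_aa = as.character(raw[[cdr3_col]]),
               antigen_category = as.character(raw[[category_col]]))
  bad <- !is_valid_junction(db$cdr3b_aa)
  if (any(bad)) {
    warn(sprintf("dropped %d antigen rows with invalid residues", sum(bad)))
    db <- db[!bad, , drop = FALSE]
  }
  if (!is.null(categories)) db <- filter(db, .data$antigen_category %in% categories)
  db <- distinct(db)
  if (nrow(db) == 0) abort("no antigen records retained")
  structure(db, class = c("antigen_db", class(tibble())))
}

#' Per-category antigen enrichment of a T clonotype cluster
#'
#' For each antigen category, the fraction of cluster members exactly
#' matching a database CDR3beta of that category is compared to the same
#' fraction over the background pool of public T clonotypes:
#' `enrichment = f_cluster / f_background` (NA when the category never
#' matches the background; 0 when it matches the background but not the
#' cluster).
#'
#' @param cluster_t character vector of cluster T clonotypes (subset of
#'   `background`).
#' @param background character vector of all public T clonotypes.
#' @param db an [load_antigen_table()] result (or tibble with `cdr3b_aa`,
#'   `antigen_category`).
#' @return tibble with one row per category present in the database:
#'   `antigen_category`, `n_cluster_match`, `f_cluster`, `n_background_match`,
#'   `f_background`, `enrichment`.
#' @export
cluster_antigen_enrichment <- function(cluster_t, background, db) {
  cluster_t <- as_clonotype_set(cluster_t)
  background <- as_clonotype_set(background)
  if (length(cluster_t) == 0) abort("empty cluster")
  if (!all(cluster_t %in% background)) abort("cluster must be a subset of the background pool")
  db %>%
    as_tibble() %>%
    group_by(.data$antigen_category) %>%
    summarise(
      n_cluster_match = sum(cluster_t %in% .data$cdr3b_aa),
      n_background_match = sum(background %in% .data$cdr3b_aa),
      .groups = "drop"
    ) %>%
    mutate(
      f_cluster = .data$n_cluster_match / length(cluster_t),
      f_background = .data$n_background_match / length(background),
      enrichment = ifelse(.data$f_background == 0, NA_real_,
                          .data$f_cluster / .data$f_background)
    ) %>%
    select(all_of(c("antigen_category", "n_cluster_match", "f_cluster",
                    "n_background_match", "f_background", "enrichment")))
}
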