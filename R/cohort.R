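# The cohort container: a tibble of repertoires keyed by
# (study_id, individual_id, locus), with pairing bookkeeping.

#' Construct a cohort from a tibble of repertoires
#'
#' @param data a tibble with columns `study_id`, `individual_id`,
#'   `condition`, `locus`, optionally `q30_fraction`, and a `repertoire`
#'   list-column of [repertoire()] objects.
#' @return the tibble with class `"cohort"` and a `paired` logical column
#'   (TRUE when the individual has both an IGH and a TRB repertoire).
#' @export
as_cohort <- function(data) {
  required <- c("study_id", "individual_id", "condition", "locus", "repertoire")
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    abort(sprintf("Cohort data is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (!"q30_fraction" %in% names(data)) data$q30_fraction <- NA_real_
  data <- data %>%
    group_by(.data$study_id, .data$individual_id) %>%
    mutate(paired = all(LOCI %in% .data$locus)) %>%
    ungroup() %>%
    arrange(.data$study_id, .data$individual_id, .data$locus)
  structure(data, class = c("cohort", class(tibble())))
}

#' Build a cohort directly from a list of repertoires
#'
#' Provenance attributes (`study_id`, `individual_id`, `condition`) must be
#' set on each repertoire.
#'
#' @param reps list of [repertoire()] objects.
#' @param q30_fraction optional numeric vector aligned with `reps`.
#' @return a `cohort`.
#' @export
cohort_from_repertoires <- function(reps, q30_fraction = NULL) {
  tbl <- tibble(
    study_id = map_chr(reps, ~ attr(.x, "study_id")),
    individual_id = map_chr(reps, ~ attr(.x, "individual_id")),
    condition = map_chr(reps, ~ attr(.x, "condition")),
    locus = map_chr(reps, ~ attr(.x, "locus")),
    q30_fraction = q30_fraction %||% NA_real_,
    repertoire = reps
  )
  as_cohort(tbl)
}

#' @export
print.cohort <- function(x, ...) {
  n_ind <- nrow(distinct(as_tibble(x), .data$study_id, .data$individual_id))
  cat(sprintf(
    "<cohort> %d repertoires | %d individuals | %d studies | %d unpaired\n",
    nrow(x), n_ind, length(unique(x$study_id)),
    nrow(distinct(filter(as_tibble(x), !.data$paired), .data$study_id, .data$individual_id))
  ))
  NextMethod()
}

#' Extract one repertoire from a cohort
#'
#' @param cohort a `cohort`.
#' @param study_id,individual_id,locus key of the repertoire.
#' @return a [repertoire()] or an error if absent.
#' @export
get_repertoire <- function(cohort, study_id, individual_id, locus) {
  hit <- cohort$study_id == study_id & cohort$individual_id == individual_id &
    cohort$locus == locus
  if (!any(hit)) abort("No such repertoire in cohort")
  cohort$repertoire[[which(hit)[1]]]
}

#' Paired individuals of a cohort
#'
#' @param cohort a `cohort`.
#' @return tibble of (study_id, individual_id, condition) for individuals
#'   with both chains present.
#' @export
paired_individuals <- function(cohort) {
  cohort %>%
    as_tibble() %>%
    filter(.data$paired) %>%
    distinct(.data$study_id, .data$individual_id, .data$condition)
}

#' Write a cohort to disk as AIRR TSVs plus a manifest
#'
#' Writes one AIRR-style TSV per repertoire under `dir` and a TSV manifest
#' that [load_cohort()] can read back.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    fn <- sprintf("%s_%s_%s.tsv", cohort$study_id[i], cohort$individual_id[i],
                  cohort$locus[i])
    write_airr_repertoire(cohort$repertoire[[i]], file.path(dir, fn))
    files[i] <- fn
  }
  manifest <- cohort %>%
    as_tibble() %>%
    select(all_of(c("study_id", "individual_id", "condition", "locus", "q30_fraction"))) %>%
    mutate(path = files)
  mpath <- file.path(dir, "manifest.tsv")
  readr::write_tsv(manifest, mpath, progress = FALSE)
  invisible(mpath)
}

#' Pool all clonotype rows of a cohort into one long tibble
#'
#' One row per (repertoire, clonotype), carrying provenance columns. This is
#' the flat form most downstream public-clonotype operations work from.
#'
#' @param cohort a `cohort`.
#' @param locus optional filter, `"IGH"` or `"TRB"`.
#' @param condition optional filter, `"healthy"` or `"disease"`.
#' @param paired_only drop unpaired individuals (default FALSE).
#' @return a long tibble with columns `study_id`, `individual_id`,
#'   `condition`, `locus`, `junction_aa`, `duplicate_count`, `proportion`
#'   and, when present, `cell_subset`.
#' @export
cohort_clonotypes <- function(cohort, locus = NULL, condition = NULL,
                              paired_only = FALSE) {
  tbl <- as_tibble(cohort)
  if (!is.null(locus)) tbl <- filter(tbl, .data$locus == !!locus)
  if (!is.null(condition)) tbl <- filter(tbl, .data$condition == !!condition)
  if (paired_only) tbl <- filter(tbl, .data$paired)
  if (nrow(tbl) == 0) {
    return(tibble(
      study_id = character(), individual_id = character(),
      condition = character(), locus = character(),
      junction_aa = character(), duplicate_count = numeric(),
      proportion = numeric()
    ))
  }
  tbl %>%
    mutate(repertoire = map(.data$repertoire, as_tibble)) %>%
    select(all_of(c("study_id", "individual_id", "condition", "locus", "repertoire"))) %>%
    tidyr::unnest("repertoire")
}
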