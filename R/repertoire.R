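# The repertoire container: one individual x one chain, as a tibble of unique
# clonotypes with counts and normalized proportions.

#' Build a clonotype repertoire
#'
#' A repertoire is a tibble with one row per unique CDR3 amino-acid clonotype
#' of one chain (IGH or TRB) in one individual, holding the read/cell count
#' (`duplicate_count`) and the clonal proportion (count over total count).
#' Rows with the same `junction_aa` are merged by summing counts;
#' nonproductive or malformed junctions (anything outside the 20-letter
#' alphabet, e.g. containing `*` or `_`) are dropped with a message. Missing
#' or zero counts default to 1 (single-cell convention). Rows are stored in a
#' canonical order (decreasing count, then alphabetical junction) so that
#' construction is invariant to input row order.
#'
#' @param junction_aa character vector of CDR3 amino-acid sequences.
#' @param duplicate_count integer vector of counts (recycled if length 1);
#'   `NULL`, `NA` or 0 entries become 1.
#' @param locus `"IGH"` or `"TRB"`.
#' @param cell_subset optional character vector of cell subsets (see
#'   [CELL_SUBSETS]); must be consistent with `locus`.
#' @param v_call,j_call optional gene-call annotations.
#' @param individual_id,study_id,condition optional provenance attributes.
#' @param quiet suppress the dropped-row message.
#'
#' @return A tibble of class `"repertoire"` with columns `junction_aa`,
#'   `duplicate_count`, `proportion` (and any optional annotation columns),
#'   plus attributes `locus`, `individual_id`, `study_id`, `condition` and
#'   `n_dropped` (number of rows removed by the productivity filter).
#' @export
#' @examples
#' rep <- repertoire(c("CASSF", "CARGW", "CASSF"), c(2, 5, 3), "TRB")
#' rep$duplicate_count # merged: 5, 5
repertoire <- function(junction_aa, duplicate_count = NULL, locus,
                       cell_subset = NULL, v_call = NULL, j_call = NULL,
                       individual_id = NA_character_, study_id = NA_character_,
                       condition = NA_character_, quiet = FALSE) {
  check_locus(locus)
  junction_aa <- as.character(junction_aa)
  n <- length(junction_aa)
  duplicate_count <- duplicate_count %||% rep(1L, n)
  if (length(duplicate_count) == 1L) duplicate_count <- rep(duplicate_count, n)
  duplicate_count <- as.numeric(duplicate_count)
  duplicate_count[is.na(duplicate_count) | duplicate_count < 1] <- 1

  df <- tibble(junction_aa = junction_aa, duplicate_count = duplicate_count)
  if (!is.null(cell_subset)) {
    bad <- !is.na(cell_subset) & !cell_subset %in% CELL_SUBSETS[[locus]]
    if (any(bad)) {
      abort(sprintf(
        "cell_subset values %s are not valid for locus %s",
        paste(unique(cell_subset[bad]), collapse = ", "), locus
      ))
    }
    df$cell_subset <- as.character(cell_subset)
  }
  if (!is.null(v_call)) df$v_call <- as.character(v_call)
  if (!is.null(j_call)) df$j_call <- as.character(j_call)

  keep_row <- is_valid_junction(df$junction_aa)
  n_dropped <- sum(!keep_row)
  if (n_dropped > 0 && !quiet) {
    inform(sprintf("Dropped %d nonproductive/malformed junction row(s)", n_dropped))
  }
  df <- df[keep_row, , drop = FALSE]
  if (nrow(df) == 0) {
    abort("No valid clonotype rows remain after filtering", class = "crossrep_empty_repertoire")
  }

  # merge duplicated junctions; annotations taken from the most abundant row
  agg <- df %>%
    arrange(desc(.data$duplicate_count)) %>%
    group_by(.data$junction_aa) %>%
    summarise(
      across(any_of(c("cell_subset", "v_call", "j_call")), first),
      duplicate_count = sum(.data$duplicate_count),
      .groups = "drop"
    ) %>%
    arrange(desc(.data$duplicate_count), .data$junction_aa) %>%
    mutate(proportion = .data$duplicate_count / sum(.data$duplicate_count)) %>%
    relocate("junction_aa", "duplicate_count", "proportion")

  new_repertoire(agg, locus, individual_id, study_id, condition, n_dropped)
}

new_repertoire <- function(data, locus, individual_id = NA_character_,
                           study_id = NA_character_, condition = NA_character_,
                           n_dropped = 0L) {
  structure(
    as_tibble(data),
    locus = locus,
    individual_id = individual_id,
    study_id = study_id,
    condition = condition,
    n_dropped = n_dropped,
    class = c("repertoire", class(tibble()))
  )
}

#' Validate repertoire invariants
#'
#' Checks junction uniqueness and alphabet, count positivity, proportion
#' normalization (sum to 1 within 1e-9), and subset/locus consistency.
#'
#' @param rep a [repertoire()].
#' @return `rep`, invisibly; aborts on violation.
#' @export
validate_repertoire <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  locus <- attr(rep, "locus")
  check_locus(locus)
  if (anyDuplicated(rep$junction_aa)) abort("duplicate junction_aa in repertoire")
  if (!all(is_valid_junction(rep$junction_aa))) abort("invalid junction_aa in repertoire")
  if (any(rep$duplicate_count < 1)) abort("duplicate_count must be >= 1")
  if (abs(sum(rep$proportion) - 1) > 1e-9) abort("proportions do not sum to 1")
  if ("cell_subset" %in% names(rep)) {
    ok <- is.na(rep$cell_subset) | rep$cell_subset %in% CELL_SUBSETS[[locus]]
    if (!all(ok)) abort("cell_subset inconsistent with locus")
  }
  invisible(rep)
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf(
    "<repertoire> %s | %s/%s (%s) | %d clonotypes, %s reads\n",
    attr(x, "locus"), attr(x, "study_id"), attr(x, "individual_id"),
    attr(x, "condition"), nrow(x), format(sum(x$duplicate_count))
  ))
  NextMethod()
}

rep_locus <- function(rep) attr(rep, "locus")
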