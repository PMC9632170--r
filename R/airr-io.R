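# AIRR Rearrangement TSV input/output and cohort manifest loading.

#' Default column alias map for clonotype tables
#'
#' Maps the package's canonical column names onto the AIRR Rearrangement
#' schema names plus the MiXCR-style export dialect, so mixed processing
#' pipelines (MiXCR, pRESTO, CellRanger) can be read with one call.
#'
#' @return named list of accepted column names per canonical field.
#' @export
airr_aliases <- function() {
  list(
    junction_aa = c("junction_aa", "aaSeqCDR3", "cdr3aa", "cdr3_aa", "CDR3.aa"),
    duplicate_count = c("duplicate_count", "cloneCount", "clone_count", "count", "clones"),
    locus = c("locus", "chain"),
    cell_subset = c("cell_subset", "subset", "cell_type"),
    v_call = c("v_call", "allVHitsWithScore", "v_gene"),
    j_call = c("j_call", "allJHitsWithScore", "j_gene")
  )
}

pick_alias <- function(cols, aliases) {
  hit <- aliases[aliases %in% cols]
  if (length(hit)) hit[[1]] else NA_character_
}

#' Read one AIRR-style clonotype table as a repertoire
#'
#' Reads a tab-separated clonotype table (AIRR Rearrangement subset or a
#' MiXCR-style export, see [airr_aliases()]), drops nonproductive junctions,
#' merges duplicate junctions, and normalizes proportions.
#'
#' @param path path to a TSV file with at least a junction column.
#' @param locus `"IGH"` or `"TRB"`.
#' @param aliases column alias map, see [airr_aliases()].
#' @inheritParams repertoire
#' @return a [repertoire()].
#' @export
read_airr_repertoire <- function(path, locus, aliases = airr_aliases(),
                                 individual_id = NA_character_,
                                 study_id = NA_character_,
                                 condition = NA_character_, quiet = FALSE) {
  check_locus(locus)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  jcol <- pick_alias(names(raw), aliases$junction_aa)
  if (is.na(jcol)) {
    abort(sprintf("No junction column found in %s (looked for: %s)",
                  path, paste(aliases$junction_aa, collapse = ", ")),
          class = "crossrep_format_error")
  }
  ccol <- pick_alias(names(raw), aliases$duplicate_count)
  scol <- pick_alias(names(raw), aliases$cell_subset)
  vcol <- pick_alias(names(raw), aliases$v_call)
  jcallcol <- pick_alias(names(raw), aliases$j_call)
  counts <- if (is.na(ccol)) NULL else raw[[ccol]]
  repertoire(
    junction_aa = raw[[jcol]],
    duplicate_count = counts,
    locus = locus,
    cell_subset = if (is.na(scol)) NULL else raw[[scol]],
    v_call = if (is.na(vcol)) NULL else raw[[vcol]],
    j_call = if (is.na(jcallcol)) NULL else raw[[jcallcol]],
    individual_id = individual_id, study_id = study_id,
    condition = condition, quiet = quiet
  )
}

#' Write a repertoire as an AIRR-style TSV
#'
#' The written file round-trips: reading it back with
#' [read_airr_repertoire()] reproduces the clonotype set, counts and
#' proportions exactly.
#'
#' @param rep a [repertoire()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_airr_repertoire <- function(rep, path) {
  stopifnot(inherits(rep, "repertoire"))
  out <- as_tibble(rep)
  out$locus <- attr(rep, "locus")
  out <- out[, c("junction_aa", "duplicate_count", "locus",
                 intersect(c("cell_subset", "v_call", "j_call"), names(out)))]
  if (nrow(out) == 0) warn("Writing an empty repertoire (header-only file)")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Load a cohort of paired repertoires from a manifest
#'
#' The manifest (TSV or YAML) lists one row/record per repertoire file with
#' fields `study_id`, `individual_id`, `condition` (`healthy` or `disease`),
#' `locus`, `path`, and optionally `q30_fraction` (per-individual fraction of
#' reads above Q30, in \[0, 1\]). Individuals present for only one locus are
#' retained but flagged unpaired; they are excluded from cross-receptor
#' correlation downstream.
#'
#' @param manifest path to the manifest file (`.tsv`, `.yaml` or `.yml`).
#' @param base_dir directory against which relative repertoire paths are
#'   resolved; defaults to the manifest's directory.
#' @param quiet suppress the per-study summary message.
#' @return a `cohort` tibble: one row per (study, individual, locus) with a
#'   `repertoire` list-column and a `paired` flag.
#' @export
load_cohort <- function(manifest, base_dir = dirname(manifest), quiet = FALSE) {
  ext <- tolower(tools::file_ext(manifest))
  man <- if (ext %in% c("yaml", "yml")) {
    recs <- yaml::read_yaml(manifest)
    bind_rows(lapply(recs, as_tibble))
  } else {
    readr::read_tsv(manifest, show_col_types = FALSE, progress = FALSE)
  }
  required <- c("study_id", "individual_id", "condition", "locus", "path")
  missing <- setdiff(required, names(man))
  if (length(missing)) {
    abort(sprintf("Manifest is missing column(s): %s", paste(missing, collapse = ", ")),
          class = "crossrep_manifest_error")
  }
  if (!"q30_fraction" %in% names(man)) man$q30_fraction <- NA_real_
  bad_q30 <- !is.na(man$q30_fraction) & (man$q30_fraction < 0 | man$q30_fraction > 1)
  if (any(bad_q30)) {
    abort("q30_fraction must lie in [0, 1]", class = "crossrep_manifest_error")
  }
  key <- paste(man$study_id, man$individual_id, man$locus)
  if (anyDuplicated(key)) {
    abort("Duplicate (study, individual, locus) entries in manifest",
          class = "crossrep_manifest_error")
  }
  if (!all(man$locus %in% LOCI)) {
    abort("Manifest locus values must be IGH or TRB", class = "crossrep_manifest_error")
  }

  reps <- pmap(man, function(study_id, individual_id, condition, locus, path,
                             q30_fraction, ...) {
    full <- if (file.exists(path)) path else file.path(base_dir, path)
    read_airr_repertoire(full, locus,
      individual_id = individual_id, study_id = study_id,
      condition = condition, quiet = TRUE
    )
  })
  out <- man %>%
    select(all_of(c("study_id", "individual_id", "condition", "locus", "q30_fraction"))) %>%
    mutate(repertoire = reps)
  out <- as_cohort(out)
  if (!quiet) {
    summ <- out %>%
      distinct(.data$study_id, .data$individual_id, .data$condition) %>%
      count(.data$study_id, .data$condition)
    inform(paste(
      c("Loaded cohort:", sprintf(
        "  %s / %s: %d individual(s)", summ$study_id, summ$condition, summ$n
      )),
      collapse = "\n"
    ))
  }
  out
}
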