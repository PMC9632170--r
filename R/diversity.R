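# Clonality and diversity summary statistics, plus repertoire downsampling.

#' Clone-fraction bin thresholds
#'
#' Thresholds for the clonal-space proportion bins: the top-N most frequent
#' clonotypes, hyperexpanded clonotypes (proportion above
#' `hyperexpanded_min`), small clonotypes (proportion below `small_max`) and
#' rare clonotypes (absolute count at most `rare_count_max`, i.e. fewer than
#' three reads at the default).
#'
#' @param top_n number of top clonotypes summed (default 100).
#' @param hyperexpanded_min proportion threshold for hyperexpanded clones
#'   (default 0.01).
#' @param small_max proportion threshold for small clones (default 1e-5).
#' @param rare_count_max maximum count of a rare clone (default 2).
#' @return a list of class `"bin_thresholds"`.
#' @export
bin_thresholds <- function(top_n = 100, hyperexpanded_min = 0.01,
                           small_max = 1e-5, rare_count_max = 2) {
  if (!(small_max > 0 && small_max < hyperexpanded_min && hyperexpanded_min <= 1)) {
    abort("need 0 < small_max < hyperexpanded_min <= 1")
  }
  if (top_n < 1) abort("top_n must be >= 1")
  structure(
    list(top_n = top_n, hyperexpanded_min = hyperexpanded_min,
         small_max = small_max, rare_count_max = rare_count_max),
    class = "bin_thresholds"
  )
}

#' Clonal volume: number of unique clonotypes
#' @param rep a [repertoire()].
#' @return integer count of unique junctions.
#' @export
clonal_volume <- function(rep) nrow(rep)

#' Clonal-space proportions of top / hyperexpanded / small / rare clones
#'
#' `top_prop` sums the proportions of the `top_n` most frequent clonotypes
#' (boundary ties broken alphabetically for determinism); `hyper_prop` sums
#' clonotypes whose proportion exceeds `hyperexpanded_min`; `small_prop`
#' those below `small_max`; `rare_prop` those with counts at most
#' `rare_count_max`.
#'
#' @param rep a [repertoire()].
#' @param th a [bin_thresholds()].
#' @return one-row tibble with `top_prop`, `hyper_prop`, `small_prop`,
#'   `rare_prop`.
#' @export
clone_fraction_bins <- function(rep, th = bin_thresholds()) {
  ord <- order(-rep$duplicate_count, rep$junction_aa)
  p <- rep$proportion[ord]
  tibble(
    top_prop = sum(p[seq_len(min(th$top_n, length(p)))]),
    hyper_prop = sum(p[p > th$hyperexpanded_min]),
    small_prop = sum(p[p < th$small_max]),
    rare_prop = sum(rep$proportion[rep$duplicate_count <= th$rare_count_max])
  )
}

#' Chao1 richness estimator
#'
#' With `S` observed clonotypes, `F1` singletons and `F2` doubletons:
#' classic form `S + F1^2 / (2 F2)`; bias-corrected form (the default)
#' `S + F1 (F1 - 1) / (2 (F2 + 1))`. The classic form with no doubletons
#' falls back to the bias-corrected form with a message.
#'
#' @param rep a [repertoire()].
#' @param bias_corrected use the bias-corrected form (default TRUE).
#' @return the estimate (>= clonal volume).
#' @export
chao1 <- function(rep, bias_corrected = TRUE) {
  s <- nrow(rep)
  f1 <- sum(rep$duplicate_count == 1)
  f2 <- sum(rep$duplicate_count == 2)
  if (!bias_corrected && f2 == 0) {
    inform("Chao1: no doubletons; using the bias-corrected form")
    bias_corrected <- TRUE
  }
  if (bias_corrected) s + f1 * (f1 - 1) / (2 * (f2 + 1)) else s + f1^2 / (2 * f2)
}

#' Hill diversity number of order q
#'
#' `q = 1` gives the exponential of Shannon entropy (natural log); `q = 2`
#' gives inverse Simpson concentration, `1 / sum(p^2)`.
#'
#' @param rep a [repertoire()].
#' @param q order, 1 or 2.
#' @return effective number of clonotypes, in `[1, clonal_volume]`.
#' @export
hill_number <- function(rep, q) {
  if (nrow(rep) == 0) abort("Hill number undefined for an empty repertoire")
  p <- rep$proportion
  if (q == 1) {
    exp(-sum(p * log(p)))
  } else if (q == 2) {
    1 / sum(p^2)
  } else {
    abort("q must be 1 or 2")
  }
}

#' Gini-Simpson diversity index
#'
#' `1 - sum(p^2)`: the probability that two random reads come from
#' different clonotypes.
#'
#' @param rep a [repertoire()].
#' @return value in `[0, 1)`.
#' @export
gini_simpson <- function(rep) 1 - sum(rep$proportion^2)

#' Gini inequality coefficient of clonotype counts
#'
#' Mean absolute difference between clonotype counts divided by twice the
#' mean count (computed with the sorted O(n log n) identity; equals the
#' O(n^2) double sum).
#'
#' @param rep a [repertoire()].
#' @return value in `[0, 1)`; 0 iff all counts are equal.
#' @export
gini_coefficient <- function(rep) {
  x <- sort(rep$duplicate_count)
  n <- length(x)
  if (n == 0) abort("Gini undefined for an empty repertoire")
  2 * sum(seq_len(n) * x) / (n * sum(x)) - (n + 1) / n
}

#' Downsample a repertoire
#'
#' `mode = "clonotypes"` draws a uniform sample of unique clonotypes without
#' replacement and discards frequency information (all counts set to 1), the
#' form used before network construction. `mode = "reads"` draws reads
#' without replacement (multivariate hypergeometric), the form used for
#' clonality/diversity sensitivity analyses; clonotypes losing all reads are
#' dropped.
#'
#' @param rep a [repertoire()].
#' @param size target number of clonotypes (mode `"clonotypes"`) or reads
#'   (mode `"reads"`).
#' @param mode `"reads"` or `"clonotypes"`.
#' @param seed optional integer seed for reproducibility.
#' @return a downsampled [repertoire()], or `NULL` with a warning when the
#'   repertoire is smaller than `size` (the individual is skipped at that
#'   size).
#' @export
downsample <- function(rep, size, mode = c("reads", "clonotypes"), seed = NULL) {
  mode <- match.arg(mode)
  run <- function() {
    if (mode == "clonotypes") {
      if (size > nrow(rep)) {
        warn(sprintf("downsample: size %d exceeds clonal volume %d; skipped", size, nrow(rep)))
        return(NULL)
      }
      idx <- sample.int(nrow(rep), size)
      repertoire(rep$junction_aa[idx], rep(1L, size), rep_locus(rep),
        individual_id = attr(rep, "individual_id"),
        study_id = attr(rep, "study_id"),
        condition = attr(rep, "condition"), quiet = TRUE
      )
    } else {
      total <- sum(rep$duplicate_count)
      if (size > total) {
        warn(sprintf("downsample: size %d exceeds total reads %d; skipped", size, total))
        return(NULL)
      }
      # hypergeometric draw of `size` reads without replacement
      reads <- sample.int(total, size)
      breaks <- cumsum(rep$duplicate_count)
      clone_of <- findInterval(reads - 1, c(0, breaks), rightmost.closed = FALSE)
      counts <- tabulate(clone_of, nbins = nrow(rep))
      keep <- counts > 0
      repertoire(rep$junction_aa[keep], counts[keep], rep_locus(rep),
        individual_id = attr(rep, "individual_id"),
        study_id = attr(rep, "study_id"),
        condition = attr(rep, "condition"), quiet = TRUE
      )
    }
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' All clonality and diversity statistics of one repertoire
#'
#' @param rep a [repertoire()].
#' @param th a [bin_thresholds()].
#' @return one-row tibble with `clonal_volume`, the four bin proportions,
#'   `chao1`, `hill_q1`, `hill_q2`, `gini_simpson`, `gini`.
#' @export
summarize_repertoire <- function(rep, th = bin_thresholds()) {
  bind_cols(
    tibble(clonal_volume = clonal_volume(rep)),
    clone_fraction_bins(rep, th),
    tibble(
      chao1 = chao1(rep),
      hill_q1 = hill_number(rep, 1),
      hill_q2 = hill_number(rep, 2),
      gini_simpson = gini_simpson(rep),
      gini = gini_coefficient(rep)
    )
  )
}

#' Summary statistics for every repertoire of a cohort
#'
#' Computes the ten clonality/diversity statistics for each repertoire at
#' full size and, optionally, at each downsampled size. Repertoires smaller
#' than a requested size are flagged as skipped rather than aborting the
#' cohort run.
#'
#' @param cohort a `cohort`.
#' @param th a [bin_thresholds()].
#' @param sizes integer vector of downsampling sizes (may be empty).
#' @param mode downsampling mode, see [downsample()].
#' @param seed integer seed; each (repertoire, size) draw gets its own
#'   derived stream so results do not depend on iteration order.
#' @return tibble with one row per (study, individual, locus, size), where
#'   `size` is `"full"` or the numeric size; skipped rows carry NA metrics
#'   and `skipped = TRUE`.
#' @export
summarize_cohort <- function(cohort, th = bin_thresholds(), sizes = NULL,
                             mode = "reads", seed = 1L) {
  rows <- pmap(
    list(cohort$study_id, cohort$individual_id, cohort$condition,
         cohort$locus, cohort$repertoire, cohort$q30_fraction),
    function(study_id, individual_id, condition, locus, rep, q30) {
      base <- tibble(
        study_id = study_id, individual_id = individual_id,
        condition = condition, locus = locus, q30_fraction = q30
      )
      out <- list(bind_cols(base, tibble(size = "full", skipped = FALSE),
                            summarize_repertoire(rep, th)))
      for (s in sizes) {
        ds <- withCallingHandlers(
          downsample(rep, s, mode = mode,
                     seed = derive_seed(seed, study_id, individual_id, locus, s)),
          warning = function(w) invokeRestart("muffleWarning")
        )
        out[[length(out) + 1]] <- if (is.null(ds)) {
          bind_cols(base, tibble(size = as.character(s), skipped = TRUE))
        } else {
          bind_cols(base, tibble(size = as.character(s), skipped = FALSE),
                    summarize_repertoire(ds, th))
        }
      }
      bind_rows(out)
    }
  )
  bind_rows(rows)
}
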