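# Per-study correlation of paired B/T statistics and Fisher-z fixed-effect
# meta-analysis with Benjamini-Hochberg false discovery control.

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (average ranks on ties); the p-value
#' uses the t approximation with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (>= 4, no missing values).
#' @param exact use the exact permutation distribution for the p-value
#'   (only honoured for n <= 10 without ties, where it is tractable and the
#'   t approximation is weakest; default FALSE).
#' @return one-row tibble with `r`, `n`, `p`; `r` is NA (with
#'   `constant = TRUE`) when either vector is constant.
#' @export
spearman_rp <- function(x, y, exact = FALSE) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) abort("spearman_rp needs n >= 4")
  if (anyNA(x) || anyNA(y)) abort("missing values must be filtered upstream")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(r = NA_real_, n = n, p = NA_real_, constant = TRUE))
  }
  r <- cor(rank(x), rank(y))
  no_ties <- !anyDuplicated(x) && !anyDuplicated(y)
  p <- if (exact && n <= 10 && no_ties) {
    suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  } else if (abs(r) >= 1) {
    0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  tibble(r = r, n = n, p = p, constant = FALSE)
}

#' Fixed-effect Fisher-z meta-analysis of correlations
#'
#' Each study correlation is Fisher-z transformed (`atanh`) with sampling
#' variance 1/(n - 3) and pooled by inverse-variance weighting under a
#' common-effect model; the pooled estimate is back-transformed with `tanh`.
#' Correlations at |r| = 1 are clipped to +/-0.999999 with a warning.
#'
#' @param r_list per-study correlation coefficients.
#' @param n_list per-study sample sizes (each >= 4).
#' @return object of class `"meta_cor"`: list with per-study tibble
#'   (`studies`), pooled `z`, `se_z`, `r`, `conf_low`, `conf_high`, `p`,
#'   `n_studies`, `n_total`.
#' @export
fisher_z_meta <- function(r_list, n_list) {
  keep <- !is.na(r_list) & !is.na(n_list)
  r_list <- r_list[keep]; n_list <- n_list[keep]
  if (length(r_list) == 0) abort("no studies to pool")
  if (any(n_list < 4)) abort("each pooled study needs n >= 4")
  r_list <- clip_correlation(r_list)
  z <- atanh(r_list)
  w <- n_list - 3
  zp <- sum(w * z) / sum(w)
  se <- 1 / sqrt(sum(w))
  structure(
    list(
      studies = tibble(r = r_list, n = n_list, z = z, weight = w),
      z = zp, se_z = se, r = tanh(zp),
      conf_low = tanh(zp - 1.96 * se), conf_high = tanh(zp + 1.96 * se),
      p = 2 * pnorm(-abs(zp / se)),
      n_studies = length(r_list), n_total = sum(n_list)
    ),
    class = "meta_cor"
  )
}

#' @export
print.meta_cor <- function(x, ...) {
  cat(sprintf(
    "<meta_cor> pooled r = %.4f [%.4f, %.4f], p = %.3g (%d studies, N = %d)\n",
    x$r, x$conf_low, x$conf_high, x$p, x$n_studies, x$n_total
  ))
  invisible(x)
}

#' @describeIn fisher_z_meta per-study tibble (broom-style).
#' @param x a `meta_cor`.
#' @param ... unused.
#' @export
tidy.meta_cor <- function(x, ...) x$studies

#' @describeIn fisher_z_meta one-row pooled summary (broom-style).
#' @export
glance.meta_cor <- function(x, ...) {
  tibble(
    r = x$r, conf_low = x$conf_low, conf_high = x$conf_high,
    z = x$z, se_z = x$se_z, p = x$p,
    n_studies = x$n_studies, n_total = x$n_total
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, `q_(i) = min_{j >= i} m p_(j)/j`,
#' returned in input order.
#'
#' @param p_list numeric vector of p-values in \[0, 1\].
#' @return vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_list) p.adjust(p_list, method = "BH")

#' Cross-receptor correlation of summary statistics with meta-analysis
#'
#' For each metric and condition group: within each study, the Spearman
#' correlation between an individual's IGH value and TRB value is computed
#' over paired individuals; studies with fewer than `min_n` paired
#' individuals (or a constant metric) are dropped with a warning; the
#' surviving per-study correlations are pooled by [fisher_z_meta()]; and
#' p-values are BH-adjusted within each condition's metric family.
#'
#' @param stats a statistics table from [summarize_cohort()] (or any tibble
#'   with `study_id`, `individual_id`, `condition`, `locus` and metric
#'   columns). Rows flagged `skipped` are removed; when a `size` column is
#'   present, one metric family per size is analysed.
#' @param metrics character vector of metric column names.
#' @param min_n minimum paired individuals per study (default 4).
#' @return tibble with one row per (condition, size, metric): `n_studies`,
#'   `studies` (list-column of per-study r/n/p), pooled `r`, `conf_low`,
#'   `conf_high`, `z`, `se_z`, `p`, `q`.
#' @export
correlate_paired_metrics <- function(stats,
                                     metrics = c("clonal_volume", "top_prop",
                                                 "hyper_prop", "small_prop",
                                                 "rare_prop", "chao1", "hill_q1",
                                                 "hill_q2", "gini_simpson", "gini"),
                                     min_n = 4) {
  stats <- as_tibble(stats)
  if ("skipped" %in% names(stats)) stats <- filter(stats, !.data$skipped)
  if (!"size" %in% names(stats)) stats$size <- "full"
  metrics <- intersect(metrics, names(stats))

  long <- stats %>%
    select(all_of(c("study_id", "individual_id", "condition", "locus", "size", metrics))) %>%
    tidyr::pivot_longer(all_of(metrics), names_to = "metric", values_to = "value") %>%
    tidyr::pivot_wider(names_from = "locus", values_from = "value") %>%
    filter(!is.na(.data$IGH), !is.na(.data$TRB))

  per_study <- long %>%
    group_by(.data$condition, .data$size, .data$metric, .data$study_id) %>%
    summarise(
      n = n(),
      res = list(if (n() >= min_n) spearman_rp(.data$IGH, .data$TRB) else NULL),
      .groups = "drop"
    )
  dropped <- per_study %>% filter(.data$n < min_n)
  if (nrow(dropped)) {
    warn(sprintf("%d study/metric combinations dropped (fewer than %d paired individuals)",
                 nrow(dropped), min_n))
  }
  per_study <- per_study %>% filter(.data$n >= min_n)
  if (nrow(per_study) == 0) {
    return(tibble(
      condition = character(), size = character(), metric = character(),
      studies = list(), r = numeric(), conf_low = numeric(),
      conf_high = numeric(), z = numeric(), se_z = numeric(),
      p = numeric(), n_studies = integer(), n_total = integer(),
      q = numeric()
    ))
  }
  per_study <- per_study %>%
    tidyr::unnest("res", names_sep = "_") %>%
    filter(!is.na(.data$res_r))

  pooled <- per_study %>%
    group_by(.data$condition, .data$size, .data$metric) %>%
    summarise(
      # bare names: .data would be re-masked by the inner tibble()
      studies = list(tibble(study_id = study_id, r = res_r, n = res_n, p = res_p)),
      meta = list(fisher_z_meta(.data$res_r, .data$res_n)),
      .groups = "drop"
    ) %>%
    mutate(glance = map(.data$meta, glance)) %>%
    select(-"meta") %>%
    tidyr::unnest("glance") %>%
    group_by(.data$condition, .data$size) %>%
    mutate(q = bh_fdr(.data$p)) %>%
    ungroup()
  pooled
}

#' Covariate-adjusted association by ordinary least squares
#'
#' Fits `y ~ 1 + x + cov` and reports the slope on `x` with its standard
#' error and two-sided t-test p-value; used to check that cross-receptor
#' associations survive adjustment for sequencing quality (the per-individual
#' fraction of reads above Q30).
#'
#' @param y,x,cov numeric vectors of equal length (>= 5).
#' @return one-row tibble with `slope`, `se`, `p`; NA with
#'   `collinear = TRUE` when `x` and `cov` are collinear.
#' @export
covariate_adjusted_association <- function(y, x, cov) {
  n <- length(y)
  stopifnot(length(x) == n, length(cov) == n)
  if (n < 5) abort("need at least 5 observations")
  fit <- lm(y ~ x + cov)
  cf <- summary(fit)$coefficients
  if (anyNA(coef(fit)) || !"x" %in% rownames(cf)) {
    return(tibble(slope = NA_real_, se = NA_real_, p = NA_real_, collinear = TRUE))
  }
  tibble(slope = cf["x", 1], se = cf["x", 2], p = cf["x", 4], collinear = FALSE)
}
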