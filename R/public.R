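# Public clonotypes, proportion matrices, subset top-50 correlation counts,
# pairwise B x T correlations and correlation-based cluster extraction.

#' Find public clonotypes of a cohort
#'
#' A public clonotype is a CDR3 amino-acid sequence found in at least
#' `min_individuals` individuals of the pooled condition group (pooled
#' across studies) for one locus.
#'
#' @param cohort a `cohort`.
#' @param locus `"IGH"` or `"TRB"`.
#' @param condition optional condition filter (`"healthy"`/`"disease"`).
#' @param min_individuals publicity threshold (default 2).
#' @return tibble with `junction_aa`, `n_individuals`, `pooled_count`,
#'   sorted by decreasing occurrence then alphabetically.
#' @export
find_public_clonotypes <- function(cohort, locus, condition = NULL,
                                   min_individuals = 2) {
  cohort_clonotypes(cohort, locus = locus, condition = condition) %>%
    group_by(.data$junction_aa) %>%
    summarise(
      n_individuals = n_distinct(paste(.data$study_id, .data$individual_id)),
      pooled_count = sum(.data$duplicate_count),
      .groups = "drop"
    ) %>%
    filter(.data$n_individuals >= min_individuals) %>%
    arrange(desc(.data$n_individuals), desc(.data$pooled_count), .data$junction_aa)
}

as_clonotype_set <- function(clonotypes) {
  if (is.data.frame(clonotypes)) clonotypes$junction_aa else as.character(clonotypes)
}

#' Per-individual proportion matrix of selected clonotypes
#'
#' Rows are individuals (of one locus and, optionally, one condition),
#' columns are clonotypes; entries are the clonotype's proportion of the
#' individual's whole clonal space for that locus (exact 0 when absent).
#' With `subset`, proportions are taken relative to the individual's clonal
#' space of that cell subset only.
#'
#' @param cohort a `cohort`.
#' @param clonotypes character vector or a [find_public_clonotypes()] tibble.
#' @param locus `"IGH"` or `"TRB"`.
#' @param condition optional condition filter.
#' @param subset optional cell-subset filter (requires `cell_subset`
#'   annotations).
#' @return numeric matrix (individuals x clonotypes) with rownames
#'   `"study:individual"` and attributes `study`, `condition`, `locus`.
#' @export
proportion_matrix <- function(cohort, clonotypes, locus, condition = NULL,
                              subset = NULL) {
  clon <- as_clonotype_set(clonotypes)
  long <- cohort_clonotypes(cohort, locus = locus, condition = condition)
  if (!is.null(subset)) {
    if (!"cell_subset" %in% names(long)) abort("cohort has no cell_subset annotations")
    long <- long %>%
      filter(.data$cell_subset == !!subset) %>%
      group_by(.data$study_id, .data$individual_id) %>%
      mutate(proportion = .data$duplicate_count / sum(.data$duplicate_count)) %>%
      ungroup()
  }
  inds <- long %>% distinct(.data$study_id, .data$individual_id)
  if (nrow(inds) == 0) abort("no individuals selected")
  rid <- paste(inds$study_id, inds$individual_id, sep = ":")
  mat <- matrix(0, nrow = nrow(inds), ncol = length(clon),
                dimnames = list(rid, clon))
  hits <- long %>% filter(.data$junction_aa %in% clon)
  if (nrow(hits)) {
    mat[cbind(
      match(paste(hits$study_id, hits$individual_id, sep = ":"), rid),
      match(hits$junction_aa, clon)
    )] <- hits$proportion
  }
  structure(mat, study = inds$study_id, condition = condition, locus = locus)
}

#' Top-k public clonotypes of one cell subset
#'
#' Pools all clonotypes of the subset across individuals and ranks public
#' ones by pooled frequency; ties broken alphabetically for determinism.
#'
#' @param cohort a `cohort` with `cell_subset` annotations.
#' @param subset a cell subset name (see [CELL_SUBSETS]).
#' @param k number of clonotypes to keep (default 50); when fewer public
#'   clonotypes exist, the full list is returned with a warning.
#' @param min_individuals publicity threshold (default 2).
#' @return character vector of up to `k` clonotypes, most frequent first.
#' @export
top_public_by_subset <- function(cohort, subset, k = 50, min_individuals = 2) {
  locus <- if (subset %in% CELL_SUBSETS$IGH) "IGH" else "TRB"
  long <- cohort_clonotypes(cohort, locus = locus)
  if (!"cell_subset" %in% names(long)) abort("cohort has no cell_subset annotations")
  long <- filter(long, .data$cell_subset == !!subset)
  if (nrow(long) == 0) abort(sprintf("subset %s absent from cohort", subset))
  ranked <- long %>%
    group_by(.data$junction_aa) %>%
    summarise(
      n_individuals = n_distinct(paste(.data$study_id, .data$individual_id)),
      pooled_count = sum(.data$duplicate_count), .groups = "drop"
    ) %>%
    filter(.data$n_individuals >= min_individuals) %>%
    arrange(desc(.data$pooled_count), .data$junction_aa)
  if (nrow(ranked) < k) {
    warn(sprintf("only %d public clonotypes in subset %s (k = %d requested)",
                 nrow(ranked), subset, k))
  }
  head(ranked$junction_aa, k)
}

#' Pearson correlation and p-value between the columns of two matrices
#'
#' @param a,b numeric matrices with the same number of rows.
#' @return list of matrices `r`, `p`, and scalar `n`; columns with zero
#'   variance give NA.
#' @keywords internal
pearson_rp_matrix <- function(a, b) {
  n <- nrow(a)
  stopifnot(nrow(b) == n)
  sda <- apply(a, 2, sd); sdb <- apply(b, 2, sd)
  r <- suppressWarnings(cor(a, b))
  r[sda == 0, ] <- NA
  r[, sdb == 0] <- NA
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[!is.na(r) & abs(r) >= 1] <- 0
  list(r = r, p = p, n = n)
}

#' Count highly correlated clonotype pairs by category
#'
#' Given a long tibble of clonotype-pair correlations labelled by category
#' (e.g. the cell-subset pair), counts pairs with `r > r_thresh` and
#' `p < p_thresh` per category, and compares a focal category's fraction
#' against all remaining pairs with a 2x2 Fisher exact test.
#'
#' @param pairs tibble with columns `category`, `r`, `p`.
#' @param r_thresh correlation threshold; required explicitly (the analysis
#'   is sensitive to it; 0.7 and 0.8 are the conventional choices).
#' @param p_thresh p-value threshold (default 0.05).
#' @param focal optional focal category for the Fisher comparison; defaults
#'   to each category in turn.
#' @param alternative passed to [stats::fisher.test()] (default
#'   `"two.sided"`).
#' @return list with `counts` (per-category n, n_high, fraction) and
#'   `fisher` (per focal category: odds ratio and p against the complement).
#' @export
count_high_correlations <- function(pairs, r_thresh, p_thresh = 0.05,
                                    focal = NULL, alternative = "two.sided") {
  pairs <- pairs %>%
    filter(!is.na(.data$r)) %>%
    mutate(high = .data$r > r_thresh & .data$p < p_thresh)
  counts <- pairs %>%
    group_by(.data$category) %>%
    summarise(n = n(), n_high = sum(.data$high), .groups = "drop") %>%
    mutate(fraction = ifelse(.data$n > 0, .data$n_high / .data$n, NA_real_))
  cats <- focal %||% counts$category
  fisher <- map(cats, function(cat) {
    inc <- counts %>% filter(.data$category == cat)
    outc <- counts %>% filter(.data$category != cat)
    if (nrow(inc) == 0 || sum(outc$n) == 0) {
      return(tibble(category = cat, odds_ratio = NA_real_, p = NA_real_))
    }
    tab <- matrix(c(inc$n_high, inc$n - inc$n_high,
                    sum(outc$n_high), sum(outc$n) - sum(outc$n_high)),
                  nrow = 2, byrow = TRUE)
    ft <- fisher.test(tab, alternative = alternative)
    tibble(category = cat, odds_ratio = unname(ft$estimate), p = ft$p.value)
  }) %>% bind_rows()
  list(counts = counts, fisher = fisher)
}

#' Subset-pair correlations of top public clonotypes
#'
#' Selects the top-k public clonotypes of each cell subset, computes their
#' per-individual within-subset proportions, and correlates every pair of
#' selected clonotypes (Pearson) across individuals, labelling each pair by
#' its subset-pair category.
#'
#' @param cohort a `cohort` with `cell_subset` annotations (one study).
#' @param subsets subsets to analyse (default all six).
#' @param k top clonotypes per subset (default 50).
#' @return tibble with columns `subset_a`, `subset_b`, `clonotype_a`,
#'   `clonotype_b`, `category`, `r`, `p`.
#' @export
subset_pair_correlations <- function(cohort, subsets = unlist(CELL_SUBSETS),
                                     k = 50) {
  sel <- map(setNames(subsets, subsets), function(s) {
    tryCatch(suppressWarnings(top_public_by_subset(cohort, s, k = k)),
             error = function(e) character(0))
  })
  sel <- keep(sel, ~ length(.x) >= 2)
  mats <- imap(sel, function(clon, subset) {
    locus <- if (subset %in% CELL_SUBSETS$IGH) "IGH" else "TRB"
    proportion_matrix(cohort, clon, locus, subset = subset)
  })
  subs <- names(mats)
  out <- list()
  for (i in seq_along(subs)) {
    for (j in i:length(subs)) {
      a <- mats[[i]]; b <- mats[[j]]
      common <- intersect(rownames(a), rownames(b))
      if (length(common) < 4) next
      rp <- pearson_rp_matrix(a[common, , drop = FALSE], b[common, , drop = FALSE])
      long <- as_tibble(as.data.frame.table(rp$r, responseName = "r")) %>%
        mutate(p = as.vector(rp$p))
      names(long)[1:2] <- c("clonotype_a", "clonotype_b")
      if (i == j) {
        # within-subset: keep unordered distinct pairs only
        ia <- match(long$clonotype_a, colnames(a))
        ib <- match(long$clonotype_b, colnames(b))
        long <- long[ia < ib, , drop = FALSE]
      }
      out[[length(out) + 1]] <- long %>%
        mutate(
          subset_a = subs[i], subset_b = subs[j],
          category = paste(sort(c(subs[i], subs[j])), collapse = "|"),
          clonotype_a = as.character(.data$clonotype_a),
          clonotype_b = as.character(.data$clonotype_b)
        )
    }
  }
  bind_rows(out)
}

#' Pairwise B x T clonotype proportion correlations with meta-analysis
#'
#' For every (B clonotype, T clonotype) pair, the Pearson correlation of
#' their per-individual proportions is computed within each study (absent
#' clonotypes count as proportion 0) and the per-study correlations are
#' pooled with the Fisher-z fixed-effect model. A study contributes to a
#' pair only if both columns vary within that study and it has at least
#' `min_n` individuals. Pairs with no contributing study are NA.
#'
#' @param bmat,tmat proportion matrices from [proportion_matrix()] sharing
#'   individual rows (IGH and TRB respectively).
#' @param min_n minimum individuals per contributing study (default 4).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return object of class `"bt_cor"`: list of matrices `r` (pooled), `p`,
#'   `n_studies`, plus `b_clonotypes`, `t_clonotypes`.
#' @export
pairwise_bt_correlations <- function(bmat, tmat, min_n = 4,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  common <- intersect(rownames(bmat), rownames(tmat))
  bmat <- bmat[common, , drop = FALSE]
  study <- sub(":.*", "", common)
  tmat <- tmat[common, , drop = FALSE]
  nb <- ncol(bmat); nt <- ncol(tmat)
  zw_sum <- matrix(0, nb, nt); w_sum <- matrix(0, nb, nt)
  k_used <- matrix(0L, nb, nt)
  for (s in unique(study)) {
    rows <- which(study == s)
    n_s <- length(rows)
    if (n_s < min_n) next
    a <- bmat[rows, , drop = FALSE]; b <- tmat[rows, , drop = FALSE]
    if (method == "spearman") {
      a <- apply(a, 2, rank); b <- apply(b, 2, rank)
    }
    r_s <- suppressWarnings(cor(a, b))
    ok <- !is.na(r_s)
    r_s[ok] <- pmin(pmax(r_s[ok], -0.999999), 0.999999)
    w <- n_s - 3
    zw_sum[ok] <- zw_sum[ok] + w * atanh(r_s[ok])
    w_sum[ok] <- w_sum[ok] + w
    k_used[ok] <- k_used[ok] + 1L
  }
  z <- ifelse(w_sum > 0, zw_sum / w_sum, NA_real_)
  se <- ifelse(w_sum > 0, 1 / sqrt(w_sum), NA_real_)
  r <- tanh(z)
  p <- 2 * pnorm(-abs(z / se))
  dimnames(r) <- dimnames(p) <- dimnames(k_used) <-
    list(colnames(bmat), colnames(tmat))
  structure(
    list(r = r, p = p, n_studies = k_used,
         b_clonotypes = colnames(bmat), t_clonotypes = colnames(tmat)),
    class = "bt_cor"
  )
}

#' @export
print.bt_cor <- function(x, ...) {
  cat(sprintf(
    "<bt_cor> %d B x %d T clonotype pairs; %.1f%% estimable\n",
    length(x$b_clonotypes), length(x$t_clonotypes),
    100 * mean(!is.na(x$r))
  ))
  invisible(x)
}

#' Long tibble of B x T pair correlations
#' @param x a `bt_cor`.
#' @param ... unused.
#' @return tibble with `b_clonotype`, `t_clonotype`, `r`, `p`, `n_studies`.
#' @export
tidy.bt_cor <- function(x, ...) {
  tibble(
    b_clonotype = rep(x$b_clonotypes, times = length(x$t_clonotypes)),
    t_clonotype = rep(x$t_clonotypes, each = length(x$b_clonotypes)),
    r = as.vector(x$r), p = as.vector(x$p),
    n_studies = as.vector(x$n_studies)
  )
}

#' Extract paired B-T clonotype clusters from the correlation matrix
#'
#' B clonotypes are hierarchically clustered on the Euclidean distance
#' between their correlation-profile rows (NA imputed as 0), T clonotypes
#' likewise on columns; both trees are cut at `k_b`/`k_t` groups (or at
#' height `h_b`/`h_t`). Every B-group x T-group block is scored by the mean
#' |pooled r| of its entries; blocks with score at least `min_score` and at
#' least `min_size` members on both sides are accepted greedily in
#' decreasing score order, so each B and T group joins at most one cluster
#' pair (best block wins).
#'
#' @param btcor a [pairwise_bt_correlations()] result.
#' @param k_b,k_t number of tree-cut groups per side (default 8 each),
#'   capped at the number of clonotypes.
#' @param h_b,h_t optional cut heights (override `k_b`/`k_t`).
#' @param min_score minimum block mean |r| (default 0.5).
#' @param min_size minimum members per side (default 2).
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"complete"`).
#' @return tibble of class `"bt_clusters"`: one row per cluster pair with
#'   `cluster_id`, `b_members`/`t_members` (list-columns), `n_b`, `n_t`,
#'   `mean_abs_r`; zero rows when no block passes.
#' @export
cluster_correlation_matrix <- function(btcor, k_b = 8, k_t = 8,
                                       h_b = NULL, h_t = NULL,
                                       min_score = 0.5, min_size = 2,
                                       linkage = "complete") {
  r <- btcor$r
  if (nrow(r) < 2 || ncol(r) < 2) abort("correlation matrix is degenerate (< 2 rows or columns)")
  rimp <- r
  rimp[is.na(rimp)] <- 0
  hb <- hclust(dist(rimp), method = linkage)
  ht <- hclust(dist(t(rimp)), method = linkage)
  gb <- if (is.null(h_b)) cutree(hb, k = min(k_b, nrow(rimp))) else cutree(hb, h = h_b)
  gt <- if (is.null(h_t)) cutree(ht, k = min(k_t, ncol(rimp))) else cutree(ht, h = h_t)

  blocks <- tidyr::expand_grid(bg = unique(gb), tg = unique(gt)) %>%
    mutate(
      score = map2_dbl(.data$bg, .data$tg, function(i, j) {
        mean(abs(rimp[gb == i, gt == j, drop = FALSE]))
      }),
      n_b = map_int(.data$bg, ~ sum(gb == .x)),
      n_t = map_int(.data$tg, ~ sum(gt == .x))
    ) %>%
    filter(.data$score >= min_score, .data$n_b >= min_size, .data$n_t >= min_size) %>%
    arrange(desc(.data$score))

  used_b <- integer(); used_t <- integer()
  rows <- list()
  for (i in seq_len(nrow(blocks))) {
    bg <- blocks$bg[i]; tg <- blocks$tg[i]
    if (bg %in% used_b || tg %in% used_t) next
    used_b <- c(used_b, bg); used_t <- c(used_t, tg)
    rows[[length(rows) + 1]] <- tibble(
      cluster_id = length(rows) + 1L,
      b_members = list(sort(rownames(rimp)[gb == bg])),
      t_members = list(sort(colnames(rimp)[gt == tg])),
      n_b = blocks$n_b[i], n_t = blocks$n_t[i],
      mean_abs_r = blocks$score[i]
    )
  }
  out <- if (length(rows)) bind_rows(rows) else {
    tibble(cluster_id = integer(), b_members = list(), t_members = list(),
           n_b = integer(), n_t = integer(), mean_abs_r = numeric())
  }
  structure(out, class = c("bt_clusters", class(tibble())))
}

#' Random groups of public clonotypes
#'
#' Uniform without-replacement samples from a pool, used to build null
#' distributions of group-level sequence features.
#'
#' @param pool character vector of clonotypes.
#' @param size group size (must not exceed the pool).
#' @param n_iter number of groups (default 10000).
#' @param seed integer seed.
#' @return list of `n_iter` character vectors of length `size`.
#' @export
sample_random_groups <- function(pool, size, n_iter = 10000, seed = 1L) {
  pool <- as_clonotype_set(pool)
  if (size > length(pool)) abort("group size exceeds pool size")
  withr::with_seed(seed, {
    lapply(seq_len(n_iter), function(i) pool[sample.int(length(pool), size)])
  })
}

#' Adjusted Rand index between two labelings
#'
#' Hubert-Arabie adjusted Rand index; 1 for identical partitions, ~0 for
#' independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return the index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}
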