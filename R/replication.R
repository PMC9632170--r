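# Replication analysis: cluster-match fractions per individual, the
# regression Fr_T ~ Fr_B + C, and the random-cluster permutation null.

#' Fraction of cluster members carried by a repertoire
#'
#' A member counts as carried when the repertoire contains at least one
#' clonotype within `ld_tol` Levenshtein distance of it (0 = exact match);
#' each member counts at most once. With a 10-member cluster of which the
#' repertoire carries 3, the fraction is 0.3.
#'
#' @param rep a [repertoire()] or a character vector of sequences.
#' @param members cluster member sequences (non-empty).
#' @param ld_tol edit-distance tolerance (default 0).
#' @return fraction in \[0, 1\].
#' @export
cluster_match_fraction <- function(rep, members, ld_tol = 0) {
  if (length(members) == 0) abort("empty member set")
  seqs <- if (inherits(rep, "repertoire") || is.data.frame(rep)) rep$junction_aa else as.character(rep)
  mean(members_carried(seqs, members, ld_tol))
}

# logical vector: which members have a repertoire sequence within ld_tol
members_carried <- function(seqs, members, ld_tol) {
  if (ld_tol == 0) return(members %in% seqs)
  carried <- members %in% seqs
  todo <- which(!carried)
  if (length(todo) == 0 || length(seqs) == 0) return(carried)
  mlen <- nchar(members)
  slen <- nchar(seqs)
  for (i in todo) {
    near <- which(abs(slen - mlen[i]) <= ld_tol)
    if (length(near) && any(adist(members[i], seqs[near]) <= ld_tol)) {
      carried[i] <- TRUE
    }
  }
  carried
}

# individuals x pool presence matrix for one locus, reused by the observed
# regression and every permutation iteration
match_presence_matrix <- function(cohort, pool, locus, ld_tol) {
  tbl <- cohort %>% as_tibble() %>% filter(.data$locus == !!locus, .data$paired)
  rid <- paste(tbl$study_id, tbl$individual_id, sep = ":")
  mat <- matrix(FALSE, nrow = nrow(tbl), ncol = length(pool),
                dimnames = list(rid, pool))
  for (i in seq_len(nrow(tbl))) {
    mat[i, ] <- members_carried(tbl$repertoire[[i]]$junction_aa, pool, ld_tol)
  }
  mat
}

#' Per-individual cluster-match fraction table
#'
#' One record per (paired individual, cluster pair) with `fr_b` and `fr_t`
#' — the fractions of the cluster's B and T members carried by the
#' individual (B members matched within `ld_tol_b`, T members within
#' `ld_tol_t`) — and `c_total`, the individual's total number of unique B
#' plus T clonotypes.
#'
#' @param cohort a `cohort` (the replication cohort).
#' @param clusters a `bt_clusters` tibble.
#' @param ld_tol_b edit tolerance for B members (default 2).
#' @param ld_tol_t edit tolerance for T members (default 0, exact).
#' @return tibble with `study_id`, `individual_id`, `cluster_id`, `fr_b`,
#'   `fr_t`, `c_total`.
#' @export
build_fraction_table <- function(cohort, clusters, ld_tol_b = 2, ld_tol_t = 0) {
  b_pool <- unique(unlist(clusters$b_members))
  t_pool <- unique(unlist(clusters$t_members))
  bp <- match_presence_matrix(cohort, b_pool, "IGH", ld_tol_b)
  tp <- match_presence_matrix(cohort, t_pool, "TRB", ld_tol_t)
  common <- intersect(rownames(bp), rownames(tp))
  vols <- cohort %>%
    as_tibble() %>%
    filter(.data$paired) %>%
    mutate(rid = paste(.data$study_id, .data$individual_id, sep = ":"),
           volume = map_int(.data$repertoire, nrow)) %>%
    group_by(.data$rid) %>%
    summarise(c_total = sum(.data$volume), .groups = "drop")
  rows <- list()
  for (m in seq_len(nrow(clusters))) {
    bm <- match(clusters$b_members[[m]], b_pool)
    tm <- match(clusters$t_members[[m]], t_pool)
    rows[[m]] <- tibble(
      rid = common,
      cluster_id = clusters$cluster_id[m],
      fr_b = rowMeans(bp[common, bm, drop = FALSE]),
      fr_t = rowMeans(tp[common, tm, drop = FALSE])
    )
  }
  bind_rows(rows) %>%
    left_join(vols, by = "rid") %>%
    tidyr::separate("rid", into = c("study_id", "individual_id"), sep = ":") %>%
    relocate("study_id", "individual_id", "cluster_id")
}

#' Regression of T-cluster match fractions on B-cluster match fractions
#'
#' Ordinary least squares `fr_t ~ fr_b + c_total`, pooled over all
#' (individual, cluster) records; the slope on `fr_b` tests whether
#' individuals carrying many of a cluster's B members also carry many of
#' its paired T members, adjusting for repertoire size.
#'
#' @param table a [build_fraction_table()] tibble (>= 10 records).
#' @return object of class `"replication_fit"` with `slope`, `se`, `p`,
#'   the `lm` fit, and `n_records`; NA slope with a flag when `fr_b` is
#'   constant.
#' @export
fit_fraction_regression <- function(table) {
  if (nrow(table) < 10) abort("need at least 10 records")
  if (sd(table$fr_b) == 0) {
    return(structure(list(slope = NA_real_, se = NA_real_, p = NA_real_,
                          fit = NULL, n_records = nrow(table), constant = TRUE),
                     class = "replication_fit"))
  }
  fit <- lm(fr_t ~ fr_b + c_total, data = table)
  cf <- summary(fit)$coefficients
  structure(
    list(slope = cf["fr_b", 1], se = cf["fr_b", 2], p = cf["fr_b", 4],
         fit = fit, n_records = nrow(table), constant = FALSE),
    class = "replication_fit"
  )
}

#' @export
print.replication_fit <- function(x, ...) {
  cat(sprintf("<replication_fit> slope = %.4f (se %.4f), p = %.3g, n = %d\n",
              x$slope, x$se, x$p, x$n_records))
  if (!is.null(x$null_slopes)) {
    cat(sprintf("  permutation null: %d iterations, empirical p = %.4f\n",
                length(x$null_slopes), x$empirical_p))
  }
  invisible(x)
}

#' @describeIn fit_fraction_regression coefficient-level tibble.
#' @param x a `replication_fit`.
#' @param ... unused.
#' @export
tidy.replication_fit <- function(x, ...) {
  if (is.null(x$fit)) return(tibble(term = character(), estimate = numeric(),
                                    std_error = numeric(), p_value = numeric()))
  cf <- summary(x$fit)$coefficients
  tibble(term = rownames(cf), estimate = cf[, 1], std_error = cf[, 2],
         statistic = cf[, 3], p_value = cf[, 4])
}

#' @describeIn fit_fraction_regression one-row model summary.
#' @export
glance.replication_fit <- function(x, ...) {
  tibble(
    slope = x$slope, se = x$se, p = x$p, n_records = x$n_records,
    n_null = length(x$null_slopes %||% numeric(0)),
    empirical_p = x$empirical_p %||% NA_real_
  )
}

#' Replication test with random-cluster permutation null
#'
#' Fits the observed regression, then refits it `n_iter` times with random
#' B and T clonotype clusters of the same sizes drawn from the public
#' pools. The empirical p-value uses the add-one rule,
#' `(1 + #{|slope_null| >= |slope_obs|}) / (n_iter + 1)`, so an observed
#' slope outside the whole null gives 1/(n_iter + 1).
#'
#' @param cohort the replication `cohort`.
#' @param clusters a `bt_clusters` tibble from the discovery cohort.
#' @param b_pool,t_pool public clonotype pools to draw random clusters from
#'   (character vectors or [find_public_clonotypes()] tibbles).
#' @param n_iter null iterations (default 100).
#' @param ld_tol_b,ld_tol_t match tolerances as in
#'   [build_fraction_table()].
#' @param seed integer seed.
#' @return a `"replication_fit"` carrying `null_slopes` and `empirical_p`
#'   in addition to the observed fit.
#' @export
replication_test <- function(cohort, clusters, b_pool, t_pool, n_iter = 100,
                             ld_tol_b = 2, ld_tol_t = 0, seed = 1L) {
  b_pool <- unique(c(as_clonotype_set(b_pool), unlist(clusters$b_members)))
  t_pool <- unique(c(as_clonotype_set(t_pool), unlist(clusters$t_members)))
  if (max(clusters$n_b) > length(b_pool) || max(clusters$n_t) > length(t_pool)) {
    abort("public pool smaller than a cluster")
  }
  bp <- match_presence_matrix(cohort, b_pool, "IGH", ld_tol_b)
  tp <- match_presence_matrix(cohort, t_pool, "TRB", ld_tol_t)
  common <- intersect(rownames(bp), rownames(tp))
  bp <- bp[common, , drop = FALSE]
  tp <- tp[common, , drop = FALSE]
  vols <- cohort %>%
    as_tibble() %>%
    filter(.data$paired) %>%
    mutate(rid = paste(.data$study_id, .data$individual_id, sep = ":"),
           volume = map_int(.data$repertoire, nrow)) %>%
    group_by(.data$rid) %>%
    summarise(c_total = sum(.data$volume), .groups = "drop")
  c_total <- vols$c_total[match(common, vols$rid)]

  slope_for <- function(b_member_idx, t_member_idx) {
    tab <- bind_rows(map2(b_member_idx, t_member_idx, function(bi, ti) {
      tibble(fr_b = rowMeans(bp[, bi, drop = FALSE]),
             fr_t = rowMeans(tp[, ti, drop = FALSE]),
             c_total = c_total)
    }))
    if (sd(tab$fr_b) == 0) return(NA_real_)
    coef(lm(fr_t ~ fr_b + c_total, data = tab))["fr_b"]
  }

  obs_tab <- build_fraction_table(cohort, clusters, ld_tol_b, ld_tol_t)
  obs <- fit_fraction_regression(obs_tab)

  null_slopes <- withr::with_seed(seed, {
    vapply(seq_len(n_iter), function(it) {
      bidx <- map(clusters$n_b, ~ sample.int(length(b_pool), .x))
      tidx <- map(clusters$n_t, ~ sample.int(length(t_pool), .x))
      slope_for(bidx, tidx)
    }, numeric(1))
  })
  obs$null_slopes <- unname(null_slopes)
  obs$empirical_p <- (1 + sum(abs(null_slopes) >= abs(obs$slope), na.rm = TRUE)) /
    (n_iter + 1)
  obs
}
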