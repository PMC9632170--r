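# Sequence-feature characterization of clusters: pairwise Levenshtein
# distances, physicochemical averages against random-group nulls, KS
# comparisons, and discrete motif enrichment.

#' Mean pairwise Levenshtein distance within a group
#'
#' @param group character vector of at least two sequences.
#' @return mean edit distance over all unordered pairs.
#' @export
mean_pairwise_ld <- function(group) {
  if (length(group) < 2) abort("mean pairwise LD undefined for groups of < 2 sequences")
  d <- adist(group)
  mean(d[upper.tri(d)])
}

#' Per-cluster sequence-feature averages
#'
#' For each cluster pair and each side (B and T): the mean pairwise LD of
#' the member sequences and the unweighted group mean of each requested
#' physicochemical property.
#'
#' @param clusters a `bt_clusters` tibble ([cluster_correlation_matrix()]).
#' @param properties property names (default all, see
#'   [aa_property_names()]).
#' @return tibble with one row per (cluster, locus) and one column per
#'   feature (`mean_pairwise_ld` plus properties).
#' @export
cluster_feature_stats <- function(clusters, properties = aa_property_names()) {
  tab <- aa_property_table()
  rows <- list()
  for (i in seq_len(nrow(clusters))) {
    for (side in c("IGH", "TRB")) {
      members <- if (side == "IGH") clusters$b_members[[i]] else clusters$t_members[[i]]
      feats <- c(
        list(mean_pairwise_ld = mean_pairwise_ld(members)),
        setNames(
          lapply(properties, function(pr) group_property_mean(members, pr, tab)),
          properties
        )
      )
      rows[[length(rows) + 1]] <- bind_cols(
        tibble(cluster_id = clusters$cluster_id[i], locus = side,
               n_members = length(members)),
        as_tibble(feats)
      )
    }
  }
  bind_rows(rows)
}

#' Null distribution of group-level sequence features
#'
#' Draws `n_iter` random groups of `size` clonotypes from the public pool
#' and computes each feature's group average, giving the reference
#' distribution the cluster averages are compared against. Pairwise LDs and
#' per-sequence property values are precomputed once over the pool, so the
#' 10,000 default iterations are cheap.
#'
#' @param pool character vector of public clonotypes.
#' @param size group size (matched to the cluster being tested).
#' @param n_iter number of random groups (default 10000).
#' @param features feature names: `"mean_pairwise_ld"` and/or property
#'   names (default all).
#' @param seed integer seed.
#' @return tibble of class `"null_dist"` with `n_iter` rows, one column per
#'   feature; attributes `size` and `pool_size`.
#' @export
null_feature_distribution <- function(pool, size, n_iter = 10000,
                                      features = c("mean_pairwise_ld",
                                                   aa_property_names()),
                                      seed = 1L) {
  pool <- as_clonotype_set(pool)
  if (size > length(pool)) abort("group size exceeds pool size")
  want_ld <- "mean_pairwise_ld" %in% features
  props <- setdiff(features, "mean_pairwise_ld")
  dmat <- if (want_ld) adist(pool) else NULL
  tab <- aa_property_table()
  pvals <- vapply(props, function(pr) {
    vapply(pool, sequence_property_mean, numeric(1), property = pr,
           table = tab, USE.NAMES = FALSE)
  }, numeric(length(pool)))
  idx <- withr::with_seed(seed, {
    lapply(seq_len(n_iter), function(i) sample.int(length(pool), size))
  })
  out <- list()
  if (want_ld) {
    out$mean_pairwise_ld <- vapply(idx, function(ix) {
      d <- dmat[ix, ix]
      mean(d[upper.tri(d)])
    }, numeric(1))
  }
  for (j in seq_along(props)) {
    pv <- pvals[, j]
    out[[props[j]]] <- vapply(idx, function(ix) mean(pv[ix]), numeric(1))
  }
  structure(as_tibble(out), size = size, pool_size = length(pool),
            class = c("null_dist", class(tibble())))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |F_a - F_b|` with p-value from [stats::ks.test()] (exact for
#' small samples, asymptotic otherwise).
#'
#' @param a,b numeric vectors (non-empty).
#' @return one-row tibble with `D` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty")
  kt <- suppressWarnings(ks.test(a, b))
  tibble(D = unname(kt$statistic), p = kt$p.value)
}

#' Compare cluster feature averages against the random-group null
#'
#' For each feature: the set of per-cluster averages (one value per
#' cluster) is compared against the null averages with a two-sample KS
#' test, and each cluster average is z-scored against the null mean/sd for
#' reporting on a common scale.
#'
#' @param cluster_stats a [cluster_feature_stats()] tibble, already
#'   filtered to one locus.
#' @param null a [null_feature_distribution()] tibble.
#' @return list with `tests` (per-feature D, p) and `scaled` (cluster
#'   averages z-scored against the null).
#' @export
feature_null_comparison <- function(cluster_stats, null) {
  feats <- intersect(names(null), names(cluster_stats))
  tests <- map(feats, function(f) {
    bind_cols(tibble(feature = f), ks_two_sample(cluster_stats[[f]], null[[f]]))
  }) %>% bind_rows()
  scaled <- cluster_stats
  for (f in feats) {
    mu <- mean(null[[f]]); sdv <- sd(null[[f]])
    scaled[[f]] <- if (sdv > 0) (cluster_stats[[f]] - mu) / sdv else NA_real_
  }
  list(tests = tests, scaled = scaled)
}

#' Motif enrichment arithmetic
#'
#' Given sequence-level presence counts of a motif inside (`k_in` of
#' `n_in`) and outside (`k_out` of `n_out`) a cluster, computes the
#' enrichment ratio `(k_in/n_in) / (k_out/n_out)` — NA when the motif never
#' occurs outside — and a one-sided Fisher exact p-value for
#' over-representation. Vectorized over motifs.
#'
#' @param k_in,n_in in-group sequences containing the motif / total.
#' @param k_out,n_out out-group sequences containing the motif / total.
#' @return tibble with `prop_in`, `prop_out`, `enrichment_ratio`, `p`.
#' @export
motif_enrichment <- function(k_in, n_in, k_out, n_out) {
  if (any(n_in == 0) || any(n_out == 0)) abort("group sizes must be positive")
  if (any(k_in > n_in) || any(k_out > n_out) || any(c(k_in, k_out) < 0)) {
    abort("inconsistent counts")
  }
  ratio <- ifelse(k_out == 0, NA_real_, (k_in / n_in) / (k_out / n_out))
  # one-sided Fisher exact (over-representation) via the hypergeometric tail
  p <- phyper(k_in - 1, k_in + k_out, n_in + n_out - k_in - k_out, n_in,
              lower.tail = FALSE)
  tibble(
    k_in = k_in, n_in = n_in, k_out = k_out, n_out = n_out,
    prop_in = k_in / n_in, prop_out = k_out / n_out,
    enrichment_ratio = ratio, p = p
  )
}

#' Discrete motif scan of a cluster against the remaining pool
#'
#' Enumerates every contiguous substring of widths `w_min`..`w_max` that
#' occurs in at least two in-group sequences, counts sequence-level
#' presence (a sequence counts once however often the motif recurs in it)
#' in both groups, applies [motif_enrichment()], BH-adjusts the one-sided
#' p-values over the full enumeration family (every distinct substring
#' seen, not only the recurring ones, so the recurrence preselection does
#' not bias the false-discovery control), keeps hits with adjusted p below
#' `alpha`, and greedily de-duplicates: a motif contained in an
#' already-reported, at-least-as-significant longer motif is suppressed.
#'
#' @param in_group,out_group disjoint character vectors of sequences.
#' @param w_min,w_max motif width range (defaults 3 and 10).
#' @param alpha significance threshold on the BH-adjusted p (default 0.05).
#' @return tibble of reported motifs: `pattern`, `width`, counts,
#'   proportions, `enrichment_ratio`, `p`, `q`; ordered by `q` then `p`.
#' @export
scan_motifs <- function(in_group, out_group, w_min = 3, w_max = 10,
                        alpha = 0.05) {
  if (length(in_group) == 0 || length(out_group) == 0) abort("both groups must be non-empty")
  if (length(intersect(in_group, out_group))) abort("groups must be disjoint")

  substrings_of <- function(s) {
    n <- nchar(s)
    out <- character(0)
    for (w in w_min:min(w_max, n)) {
      out <- c(out, substring(s, 1:(n - w + 1), w:n))
    }
    unique(out)
  }
  per_seq <- lapply(in_group, substrings_of)
  tab <- table(unlist(per_seq))
  # the multiplicity family is every enumerated substring; patterns seen in
  # a single sequence cannot be motifs but still count towards the family,
  # otherwise the preselection would bias the false-discovery control
  n_family <- length(tab)
  cand <- names(tab)[tab >= 2]
  if (length(cand) == 0) return(empty_motif_table())

  count_presence <- function(patterns, seqs) {
    vapply(patterns, function(p) sum(stringr::str_detect(seqs, stringr::fixed(p))),
           integer(1), USE.NAMES = FALSE)
  }
  k_in <- count_presence(cand, in_group)
  k_out <- count_presence(cand, out_group)
  hits <- bind_cols(
    tibble(pattern = cand, width = nchar(cand)),
    motif_enrichment(k_in, length(in_group), k_out, length(out_group))
  ) %>%
    mutate(q = p.adjust(.data$p, method = "BH", n = n_family)) %>%
    filter(.data$q < alpha) %>%
    arrange(.data$p, desc(.data$width), .data$pattern)
  if (nrow(hits) == 0) return(empty_motif_table())

  keep <- logical(nrow(hits))
  kept_patterns <- character(0)
  for (i in seq_len(nrow(hits))) {
    contained <- any(stringr::str_detect(kept_patterns, stringr::fixed(hits$pattern[i])))
    if (!contained) {
      keep[i] <- TRUE
      kept_patterns <- c(kept_patterns, hits$pattern[i])
    }
  }
  hits[keep, , drop = FALSE]
}

empty_motif_table <- function() {
  tibble(
    pattern = character(), width = integer(), k_in = integer(),
    n_in = integer(), k_out = integer(), n_out = integer(),
    prop_in = numeric(), prop_out = numeric(),
    enrichment_ratio = numeric(), p = numeric(), q = numeric()
  )
}
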