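# Fixture builders and independent brute-force oracles shared across tests.

# quick repertoire from a count vector; clonotype i encoded in base 20
make_rep <- function(counts, locus = "TRB", seqs = NULL, ...) {
  n <- length(counts)
  if (is.null(seqs)) {
    seqs <- vapply(seq_len(n), function(i) {
      code <- AA_ALPHABET[1 + c(i %% 20, (i %/% 20) %% 20, (i %/% 400) %% 20)]
      paste0("CASS", paste(code, collapse = ""), "F")
    }, character(1))
  }
  repertoire(seqs, counts, locus, quiet = TRUE, ...)
}

# random valid CDR3-like strings without relying on the package generator
random_seqs <- function(n, len_min = 8, len_max = 16) {
  vapply(seq_len(n), function(i) {
    L <- sample(len_min:len_max, 1)
    paste0("C", paste(sample(AA_ALPHABET, L - 2, replace = TRUE), collapse = ""), "F")
  }, character(1))
}

# small paired cohort built directly from repertoire objects
toy_cohort <- function() {
  mk <- function(study, ind, locus, seqs, counts, cond = "healthy", subs = NULL) {
    repertoire(seqs, counts, locus, cell_subset = subs, individual_id = ind,
               study_id = study, condition = cond, quiet = TRUE)
  }
  cohort_from_repertoires(list(
    mk("S1", "i1", "IGH", c("CAAAF", "CDDF", "CEEF"), c(5, 3, 2)),
    mk("S1", "i1", "TRB", c("CHHF", "CIIF"), c(4, 6)),
    mk("S1", "i2", "IGH", c("CAAAF", "CGGF"), c(1, 9)),
    mk("S1", "i2", "TRB", c("CHHF", "CKKF"), c(2, 8))
  ))
}

# O(n^2) Gini double-sum oracle
brute_gini <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# O(n^2) mean pairwise Levenshtein oracle (scalar loop, no adist matrix call)
brute_mean_ld <- function(seqs) {
  n <- length(seqs)
  tot <- 0; k <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + drop(adist(seqs[i], seqs[j])); k <- k + 1
  }
  tot / k
}

# all-pairs LD edge list oracle
brute_ld_edges <- function(seqs, max_dist) {
  d <- adist(seqs)
  hit <- which(d >= 1 & d <= max_dist & upper.tri(d), arr.ind = TRUE)
  e <- cbind(pmin(hit[, 1], hit[, 2]), pmax(hit[, 1], hit[, 2]))
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# base-R network metric oracles from an adjacency matrix
floyd_distances <- function(A) {
  D <- ifelse(A == 1, 1, Inf); diag(D) <- 0
  for (k in seq_len(nrow(A))) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

oracle_global_efficiency <- function(A) {
  if (nrow(A) < 2) return(0)
  iv <- 1 / floyd_distances(A)
  mean(iv[upper.tri(iv)])
}

oracle_metrics <- function(A) {
  n <- nrow(A); deg <- rowSums(A); m <- sum(A) / 2
  tri <- diag(A %*% A %*% A) / 2
  cc <- ifelse(deg >= 2, tri / (deg * (deg - 1) / 2), 0)
  leff <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) 0 else oracle_global_efficiency(A[nb, nb, drop = FALSE])
  }, numeric(1))
  idx <- which(A == 1 & upper.tri(A), arr.ind = TRUE)
  dd <- rbind(cbind(deg[idx[, 1]], deg[idx[, 2]]),
              cbind(deg[idx[, 2]], deg[idx[, 1]]))
  assort <- if (nrow(dd) && sd(dd[, 1]) > 0) cor(dd[, 1], dd[, 2]) else NA_real_
  list(
    assortativity = assort,
    avg_degree = 2 * m / n,
    avg_clustering = mean(cc),
    density = 2 * m / (n * (n - 1)),
    local_efficiency = mean(leff),
    global_efficiency = oracle_global_efficiency(A)
  )
}

graph_adjacency <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g$graph))
}

# hypergeometric enumeration oracle for the 2x2 Fisher exact two-sided p
brute_fisher_2x2 <- function(a, b, c, d) {
  # margins fixed: row1 = a+b, col1 = a+c, N = a+b+c+d
  N <- a + b + c + d; r1 <- a + b; c1 <- a + c
  lo <- max(0, r1 + c1 - N); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(c1, x) + lchoose(N - c1, r1 - x) - lchoose(N, r1))
  }, numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
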