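# Public clonotypes, proportion matrices, subset top-k analysis,
# pairwise B x T correlations and cluster extraction.

test_that("public clonotypes require presence in at least two individuals", {
  co <- toy_cohort()
  pub <- find_public_clonotypes(co, "IGH")
  expect_equal(pub$junction_aa, "CAAAF") # shared by i1 and i2
  expect_equal(pub$n_individuals, 2)
  expect_false("CDDF" %in% pub$junction_aa) # private to i1
  pub3 <- find_public_clonotypes(co, "IGH", min_individuals = 3)
  expect_equal(nrow(pub3), 0)
})

test_that("proportion matrices carry exact proportions and exact zeros", {
  co <- toy_cohort()
  m <- proportion_matrix(co, c("CAAAF", "CDDF"), "IGH")
  expect_equal(dim(m), c(2, 2))
  expect_equal(m["S1:i1", "CAAAF"], 0.5)
  expect_equal(m["S1:i2", "CAAAF"], 0.1)
  expect_equal(m["S1:i2", "CDDF"], 0)   # absent -> exact zero

  # column occupancy agrees with the publicity bookkeeping
  pub <- find_public_clonotypes(co, "IGH")
  mp <- proportion_matrix(co, pub, "IGH")
  expect_equal(unname(colSums(mp > 0)), pub$n_individuals)
})

test_that("top public clonotypes per subset rank by pooled frequency", {
  mk <- function(ind, seqs, counts, subs) {
    repertoire(seqs, counts, "TRB", cell_subset = subs, individual_id = ind,
               study_id = "S1", condition = "healthy", quiet = TRUE)
  }
  # pooled counts: CAAF = 10, CDDF = 7, CEEF = 1 (memory_CD4)
  co <- cohort_from_repertoires(list(
    mk("i1", c("CAAF", "CDDF", "CEEF"), c(6, 3, 1), rep("memory_CD4", 3)),
    mk("i2", c("CAAF", "CDDF", "CGGF"), c(4, 4, 2), c("memory_CD4", "memory_CD4", "naive_CD8")),
    repertoire("CWWF", 1, "IGH", individual_id = "i1", study_id = "S1",
               condition = "healthy", quiet = TRUE),
    repertoire("CWWF", 1, "IGH", individual_id = "i2", study_id = "S1",
               condition = "healthy", quiet = TRUE)
  ))
  expect_equal(top_public_by_subset(co, "memory_CD4", k = 2), c("CAAF", "CDDF"))
  # k beyond the public pool returns everything with a warning
  expect_warning(all3 <- top_public_by_subset(co, "memory_CD4", k = 50), "only 2")
  expect_equal(all3, c("CAAF", "CDDF"))
  expect_error(top_public_by_subset(co, "naive_CD4"), "absent")
})

test_that("high-correlation counting and Fisher comparison match the enumeration oracle", {
  pairs <- tibble::tibble(
    category = rep(c("focal", "other"), c(100, 100)),
    r = c(rep(0.9, 10), rep(0, 90), rep(0.9, 1), rep(0, 99)),
    p = 0.001
  )
  out <- count_high_correlations(pairs, r_thresh = 0.7)
  expect_equal(out$counts$n_high[out$counts$category == "focal"], 10)
  expect_equal(out$counts$fraction[out$counts$category == "other"], 0.01)
  # [[10, 90], [1, 99]] two-sided Fisher against exact hypergeometric enumeration
  pf <- out$fisher$p[out$fisher$category == "focal"]
  expect_equal(pf, brute_fisher_2x2(10, 90, 1, 99), tolerance = 1e-10)

  # all-zero correlations give zero fractions
  null_pairs <- tibble::tibble(category = rep("a", 10), r = 0, p = 1)
  expect_equal(count_high_correlations(null_pairs, 0.7)$counts$fraction, 0)
})

test_that("subset pair correlations find planted memory-subset co-variation", {
  withr::with_seed(42, {
    n_ind <- 10
    shared <- abs(rnorm(n_ind, 10, 4)) + 1 # latent factor over individuals
    mk <- function(ind, f) {
      # two clones per memory subset track f, two have flat counts, so the
      # tracked clones' within-subset proportions co-vary with f
      list(
        repertoire(c("CMEMAAF", "CMEMDDF", "CMEMKKF", "CMEMLLF",
                     "CNAIVAF", "CNAIVDF"),
                   c(round(c(3 * f, 2 * f)) + 1, 25, 35, sample(5:50, 2)),
                   "IGH",
                   cell_subset = c(rep("memory_B", 4), rep("naive_B", 2)),
                   individual_id = ind, study_id = "S1", condition = "healthy",
                   quiet = TRUE),
        repertoire(c("CMEMTAF", "CMEMTDF", "CMEMTKF", "CMEMTLF",
                     "CNTAF", "CNTDF"),
                   c(round(c(4 * f, 2 * f)) + 1, 25, 35, sample(5:50, 2)),
                   "TRB",
                   cell_subset = c(rep("memory_CD4", 4), rep("naive_CD4", 2)),
                   individual_id = ind, study_id = "S1", condition = "healthy",
                   quiet = TRUE)
      )
    }
    co <- cohort_from_repertoires(
      unlist(lapply(seq_len(n_ind), function(i) mk(paste0("i", i), shared[i])),
             recursive = FALSE)
    )
  })
  pairs <- subset_pair_correlations(co, k = 4)
  expect_true(all(c("memory_B|memory_CD4", "naive_B|naive_CD4") %in% pairs$category))
  labelled <- pairs %>%
    dplyr::mutate(cat = ifelse(category == "memory_B|memory_CD4", "memory", "other"))
  out <- count_high_correlations(
    dplyr::select(labelled, category = cat, r, p), r_thresh = 0.7,
    focal = "memory", alternative = "greater"
  )
  fr <- out$counts$fraction
  names(fr) <- out$counts$category
  expect_gt(fr["memory"], fr["other"])
})

test_that("pairwise B x T correlations: exact linear pairs, cardinality, NA handling", {
  withr::with_seed(6, {
    n <- 40
    b <- matrix(runif(n * 3), n, dimnames = list(paste0("S1:i", 1:n), paste0("B", 1:3)))
    t_ <- matrix(0, n, 4, dimnames = list(paste0("S1:i", 1:n), paste0("T", 1:4)))
    t_[, 1] <- 2 * b[, 1]            # exact linear image
    t_[, 2] <- runif(n)              # independent
    t_[, 3] <- 0                     # constant -> NA
    t_[, 4] <- -b[, 2]               # exact negative
  })
  bt <- pairwise_bt_correlations(b, t_)
  expect_equal(bt$r["B1", "T1"], 0.999999, tolerance = 1e-6)
  expect_equal(bt$r["B2", "T4"], -0.999999, tolerance = 1e-6)
  expect_true(all(is.na(bt$r[, "T3"])))
  expect_lt(abs(bt$r["B3", "T2"]), 0.5)
  td <- tidy(bt)
  expect_equal(nrow(td), 12)

  # per-study pooling matches fisher_z_meta on the per-study correlations
  study <- rep(c("S1", "S2"), each = 20)
  rn <- paste0(study, ":i", 1:40)
  rownames(b) <- rownames(t_) <- rn
  bt2 <- pairwise_bt_correlations(b, t_)
  r1 <- cor(b[1:20, "B3"], t_[1:20, "T2"])
  r2 <- cor(b[21:40, "B3"], t_[21:40, "T2"])
  expect_equal(bt2$r["B3", "T2"], fisher_z_meta(c(r1, r2), c(20, 20))$r,
               tolerance = 1e-12)
  expect_equal(bt2$n_studies["B3", "T2"], 2)
})

test_that("cluster extraction recovers planted blocks and ignores empty matrices", {
  # block-diagonal pooled-r matrix: two r = 0.9 blocks, 0 elsewhere
  r <- matrix(0, 6, 9, dimnames = list(paste0("B", 1:6), paste0("T", 1:9)))
  r[1:3, 1:4] <- 0.9
  r[4:6, 5:9] <- 0.9
  btc <- structure(list(r = r, p = r * 0, n_studies = r * 0 + 1,
                        b_clonotypes = rownames(r), t_clonotypes = colnames(r)),
                   class = "bt_cor")
  cl <- cluster_correlation_matrix(btc, k_b = 2, k_t = 2, min_score = 0.5)
  expect_equal(nrow(cl), 2)
  got_b <- lapply(cl$b_members, sort)
  is_b123 <- vapply(got_b, identical, logical(1), y = c("B1", "B2", "B3"))
  is_b456 <- vapply(got_b, identical, logical(1), y = c("B4", "B5", "B6"))
  expect_true(any(is_b123) && any(is_b456))
  got_t <- cl$t_members[[which(is_b123)]]
  expect_equal(sort(got_t), paste0("T", 1:4))

  # members are assigned to at most one cluster pair
  expect_equal(anyDuplicated(unlist(cl$b_members)), 0)
  expect_equal(anyDuplicated(unlist(cl$t_members)), 0)

  # permutation of rows/columns leaves the recovered membership unchanged
  pr <- sample(6); pc <- sample(9)
  btp <- structure(list(r = r[pr, pc], p = r[pr, pc] * 0,
                        n_studies = r[pr, pc] * 0 + 1,
                        b_clonotypes = rownames(r)[pr],
                        t_clonotypes = colnames(r)[pc]),
                   class = "bt_cor")
  clp <- cluster_correlation_matrix(btp, k_b = 2, k_t = 2, min_score = 0.5)
  expect_setequal(
    vapply(clp$b_members, paste, character(1), collapse = ","),
    vapply(cl$b_members, paste, character(1), collapse = ",")
  )

  # all-zero matrix yields no cluster pairs
  z <- structure(list(r = r * 0, p = r * 0, n_studies = r * 0 + 1,
                      b_clonotypes = rownames(r), t_clonotypes = colnames(r)),
                 class = "bt_cor")
  expect_equal(nrow(cluster_correlation_matrix(z, k_b = 2, k_t = 2)), 0)

  # degenerate matrix errors
  one <- structure(list(r = r[1, , drop = FALSE], p = NULL, n_studies = NULL,
                        b_clonotypes = "B1", t_clonotypes = colnames(r)),
                   class = "bt_cor")
  expect_error(cluster_correlation_matrix(one), "degenerate")
})

test_that("random group sampling is deterministic, exact-size and consistent", {
  pool <- paste0("C", strsplit(paste(LETTERS[1:20], collapse = ""), "")[[1]], "AF")
  g1 <- sample_random_groups(pool, 5, n_iter = 50, seed = 9)
  g2 <- sample_random_groups(pool, 5, n_iter = 50, seed = 9)
  expect_identical(g1, g2)
  expect_true(all(vapply(g1, length, integer(1)) == 5))
  expect_true(all(vapply(g1, function(g) all(g %in% pool), logical(1))))
  # size = pool: every group is the whole pool
  gfull <- sample_random_groups(pool, length(pool), n_iter = 3, seed = 1)
  expect_true(all(vapply(gfull, setequal, logical(1), y = pool)))
  expect_error(sample_random_groups(pool, 21, 10), "exceeds")
})

test_that("adjusted Rand index matches mclust and behaves at the extremes", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, c(2, 2, 3, 3, 1, 1)), 1) # label-invariant
  skip_if_not_installed("mclust")
  withr::with_seed(2, {
    for (i in 1:5) {
      x <- sample(1:4, 30, TRUE); y <- sample(1:3, 30, TRUE)
      expect_equal(adjusted_rand_index(x, y), mclust::adjustedRandIndex(x, y),
                   tolerance = 1e-12)
    }
  })
})
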