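# Pairwise LD, physicochemical averages, null distributions, KS tests and
# motif enrichment.

test_that("mean pairwise LD matches hand and brute-force values", {
  expect_equal(mean_pairwise_ld(c("AAA", "AAB", "ABB")), (1 + 2 + 1) / 3,
               tolerance = 1e-12)
  expect_equal(mean_pairwise_ld(c("CAAAAF", "CWWWWF")), 4.0)
  expect_error(mean_pairwise_ld("CAF"), "< 2")

  withr::with_seed(14, seqs <- unique(random_seqs(100, 8, 14)))
  expect_equal(mean_pairwise_ld(seqs), brute_mean_ld(seqs), tolerance = 1e-12)
})

test_that("sequence and group property means follow the table arithmetic", {
  tab <- aa_property_table()
  valA <- tab$hydropathy[tab$residue == "A"]
  valD <- tab$hydropathy[tab$residue == "D"]
  expect_equal(sequence_property_mean("AAAA", "hydropathy"), valA)
  expect_equal(sequence_property_mean("ADAD", "hydropathy"), (valA + valD) / 2)
  # order invariance
  expect_equal(sequence_property_mean("ADDA", "hydropathy"),
               sequence_property_mean("DAAD", "hydropathy"))
  expect_error(sequence_property_mean("AXZ", "hydropathy"), "absent")
  expect_error(sequence_property_mean("AAA", "nosuch"), "unknown property")

  # charge convention: R/K = +1, D/E = -1, H = 0
  expect_equal(sequence_property_mean("RKDE", "charge"), 0)
  expect_equal(sequence_property_mean("RKH", "charge"), 2 / 3)

  # group mean: identical members give the member value; mixed gives midpoint
  expect_equal(group_property_mean(c("AAAA", "AAAA"), "volume"),
               sequence_property_mean("AAAA", "volume"))
  expect_equal(group_property_mean(c("AAAA", "DDDD"), "kf3"),
               (sequence_property_mean("AAAA", "kf3") +
                sequence_property_mean("DDDD", "kf3")) / 2)

  # 50-sequence group against a direct double-loop oracle
  withr::with_seed(15, grp <- random_seqs(50, 8, 14))
  direct <- mean(vapply(grp, function(s) {
    res <- strsplit(s, "")[[1]]
    mean(vapply(res, function(a) tab$kf7[tab$residue == a], numeric(1)))
  }, numeric(1)))
  expect_equal(group_property_mean(grp, "kf7"), direct, tolerance = 1e-12)

  # every property is defined for all 20 residues
  expect_equal(nrow(tab), 20)
  expect_false(anyNA(tab))
})

test_that("null feature distributions are reproducible and centred on the pool", {
  withr::with_seed(16, pool <- unique(random_seqs(60, 10, 14)))
  n1 <- null_feature_distribution(pool, size = 8, n_iter = 400,
                                  features = c("mean_pairwise_ld", "charge"),
                                  seed = 3)
  n2 <- null_feature_distribution(pool, size = 8, n_iter = 400,
                                  features = c("mean_pairwise_ld", "charge"),
                                  seed = 3)
  expect_equal(n1, n2)
  expect_equal(nrow(n1), 400)
  expect_gt(sd(n1$mean_pairwise_ld), 0)

  # null mean of a property approximates the pool-wide mean within 3 SE
  pool_mean <- group_property_mean(pool, "charge")
  se <- sd(n1$charge) / sqrt(nrow(n1))
  expect_lt(abs(mean(n1$charge) - pool_mean), 3 * se + 1e-12)

  # group averages equal direct evaluation of the same groups
  grps <- sample_random_groups(pool, 8, n_iter = 5, seed = 3)
  expect_equal(n1$mean_pairwise_ld[1:5],
               vapply(grps, mean_pairwise_ld, numeric(1)), tolerance = 1e-12)
})

test_that("KS test covers degenerate and disjoint cases", {
  same <- ks_two_sample(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  apart <- ks_two_sample(c(1, 2, 3), c(10, 11, 12))
  expect_equal(apart$D, 1.0)
  expect_lt(apart$p, 0.11)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("motif enrichment reproduces ratio arithmetic and the Fisher p", {
  out <- motif_enrichment(6, 100, 24, 2400)
  expect_equal(out$enrichment_ratio, (6 / 100) / (24 / 2400), tolerance = 1e-12)
  # one-sided Fisher exact agreement with fisher.test
  ft <- fisher.test(matrix(c(6, 94, 24, 2376), 2, byrow = TRUE),
                    alternative = "greater")
  expect_equal(out$p, ft$p.value, tolerance = 1e-10)

  # zero out-group occurrences: ratio undefined, p still computed
  na_out <- motif_enrichment(5, 50, 0, 1000)
  expect_true(is.na(na_out$enrichment_ratio))
  expect_lt(na_out$p, 1e-6)

  expect_error(motif_enrichment(5, 0, 1, 10), "positive")
  expect_error(motif_enrichment(11, 10, 1, 10), "inconsistent")
})

test_that("motif scan finds planted motifs and stays quiet under the null", {
  withr::with_seed(23, {
    outg <- unique(random_seqs(100, 10, 14))
    ing <- vapply(1:10, function(i) {
      s <- random_seqs(1, 10, 14)
      paste0(substr(s, 1, 4), "WGQ", substr(s, 5, nchar(s)))
    }, character(1))
  })
  hits <- scan_motifs(ing, outg)
  expect_true("WGQ" %in% hits$pattern ||
              any(grepl("WGQ", hits$pattern, fixed = TRUE)))
  wgq <- hits[hits$pattern == "WGQ" | grepl("WGQ", hits$pattern, fixed = TRUE), ][1, ]
  expect_true(is.na(wgq$enrichment_ratio)) # k_out = 0
  expect_lt(wgq$p, 1e-6)

  # reported motifs are not substrings of more significant reported motifs
  if (nrow(hits) > 1) {
    for (i in 2:nrow(hits)) {
      expect_false(any(grepl(hits$pattern[i], hits$pattern[seq_len(i - 1)],
                             fixed = TRUE)))
    }
  }

  # in-group drawn from the same distribution: almost never any hit
  withr::with_seed(24, {
    clean <- 0
    for (s in 1:5) {
      all_seqs <- unique(random_seqs(120, 10, 14))
      nh <- scan_motifs(all_seqs[1:15], all_seqs[16:length(all_seqs)])
      if (nrow(nh) == 0) clean <- clean + 1
    }
  })
  expect_gte(clean, 4)

  expect_error(scan_motifs(c("CAF"), c("CAF", "CWF")), "disjoint")
})

test_that("feature-null comparison z-scores clusters against the null", {
  withr::with_seed(25, pool <- unique(random_seqs(50, 10, 14)))
  null <- null_feature_distribution(pool, 6, n_iter = 300,
                                    features = c("mean_pairwise_ld", "kf1"),
                                    seed = 7)
  cs <- tibble::tibble(
    cluster_id = 1:2, locus = "TRB", n_members = 6,
    mean_pairwise_ld = c(2, 3), kf1 = c(0.1, 0.2)
  )
  cmp <- feature_null_comparison(cs, null)
  expect_setequal(cmp$tests$feature, c("mean_pairwise_ld", "kf1"))
  expect_equal(
    cmp$scaled$mean_pairwise_ld,
    (c(2, 3) - mean(null$mean_pairwise_ld)) / sd(null$mean_pairwise_ld),
    tolerance = 1e-12
  )
  # tight clusters sit far left of the null
  expect_true(all(cmp$scaled$mean_pairwise_ld < -2))
})
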