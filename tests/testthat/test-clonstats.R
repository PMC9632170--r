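# Clonality/diversity statistics, their identities, and downsampling.

test_that("clonal volume and clone-fraction bins match hand values", {
  r <- make_rep(c(5, 3, 2))
  expect_equal(clonal_volume(r), 3)

  hyper <- make_rep(c(96, 1, 1, 1, 1))
  b <- clone_fraction_bins(hyper, bin_thresholds())
  expect_equal(b$hyper_prop, 0.96)
  expect_equal(b$top_prop, 1) # repertoire smaller than top_n sums to 1

  rare <- make_rep(c(1, 1, 1))
  expect_equal(clone_fraction_bins(rare)$rare_prop, 1.0)

  # top-100 on a Zipf-ish repertoire equals the brute-force largest-100 sum
  withr::with_seed(4, {
    cnt <- as.integer(round(2000 * (1:200)^-1.2))
    cnt <- pmax(cnt, 1)
    zipf <- make_rep(sample(cnt))
  })
  got <- clone_fraction_bins(zipf)$top_prop
  expect_equal(got, sum(sort(zipf$proportion, decreasing = TRUE)[1:100]),
               tolerance = 1e-12)
})

test_that("chao1 matches hand-evaluated classic and bias-corrected forms", {
  r <- make_rep(c(1, 1, 2, 3))
  expect_equal(chao1(r, bias_corrected = FALSE), 6.0) # 4 + 4/2
  expect_equal(chao1(r, bias_corrected = TRUE), 4.5)  # 4 + 2*1/4
  # no singletons: estimator returns the observed volume
  expect_equal(chao1(make_rep(c(3, 3, 3))), 3.0)
  # classic form with F2 = 0 falls back to bias-corrected with a message
  expect_message(v <- chao1(make_rep(c(1, 1, 3)), bias_corrected = FALSE), "doubletons")
  expect_equal(v, 3 + 2 * 1 / 2)
})

test_that("Hill numbers, Gini-Simpson and Gini match hand values and limits", {
  eq4 <- make_rep(c(2, 2, 2, 2))
  expect_equal(hill_number(eq4, 1), 4.0)
  expect_equal(hill_number(eq4, 2), 4.0)
  expect_equal(gini_simpson(eq4), 0.75)
  expect_equal(gini_coefficient(eq4), 0.0)

  single <- make_rep(5)
  expect_equal(hill_number(single, 1), 1.0)
  expect_equal(hill_number(single, 2), 1.0)
  expect_equal(gini_simpson(single), 0.0)

  r <- make_rep(c(2, 1, 1)) # proportions 0.5, 0.25, 0.25
  expect_equal(hill_number(r, 2), 1 / 0.375, tolerance = 1e-12)
  expect_equal(gini_simpson(r), 0.625, tolerance = 1e-12)

  expect_equal(gini_coefficient(make_rep(c(3, 1))), 0.25) # 2*2/(2*4*2)
})

test_that("diversity identities hold on random repertoires", {
  withr::with_seed(9, {
    for (i in 1:20) {
      r <- make_rep(sample(1:40, sample(5:60, 1), replace = TRUE))
      s <- clonal_volume(r)
      expect_gte(chao1(r), s)
      if (sum(r$duplicate_count == 1) == 0) expect_equal(chao1(r), s)
      h1 <- hill_number(r, 1); h2 <- hill_number(r, 2)
      expect_gte(h1, h2 - 1e-12)            # Hill numbers non-increasing in q
      expect_true(h1 >= 1 && h1 <= s + 1e-9)
      expect_equal(gini_simpson(r), 1 - 1 / h2, tolerance = 1e-12)
      # Gini invariant under integer count rescaling
      r5 <- repertoire(r$junction_aa, r$duplicate_count * 5, "TRB", quiet = TRUE)
      expect_equal(gini_coefficient(r), gini_coefficient(r5), tolerance = 1e-12)
    }
  })
})

test_that("sorted-formula Gini equals the O(n^2) double-sum oracle", {
  withr::with_seed(21, {
    cnt <- sample(1:500, 500, replace = TRUE)
  })
  r <- make_rep(cnt)
  expect_equal(gini_coefficient(r), brute_gini(r$duplicate_count),
               tolerance = 1e-10)
})

test_that("downsampling behaves in both modes", {
  withr::with_seed(3, {
    r <- repertoire(random_seqs(1000), sample(1:30, 1000, TRUE), "TRB", quiet = TRUE)
  })
  # clonotype mode: exact cardinality, frequency removed
  d <- downsample(r, 200, mode = "clonotypes", seed = 5)
  expect_equal(nrow(d), 200)
  expect_true(all(d$duplicate_count == 1))
  expect_true(all(d$junction_aa %in% r$junction_aa))
  # size = volume reproduces the clonotype set
  d2 <- downsample(r, nrow(r), mode = "clonotypes", seed = 5)
  expect_setequal(d2$junction_aa, r$junction_aa)

  # reads mode: exhaustive draw recovers the original counts
  tot <- sum(r$duplicate_count)
  d3 <- downsample(r, tot, mode = "reads", seed = 5)
  expect_equal(nrow(d3), nrow(r))
  expect_equal(
    d3$duplicate_count[match(r$junction_aa, d3$junction_aa)],
    r$duplicate_count
  )
  # partial reads draw has the requested total
  d4 <- downsample(r, 500, mode = "reads", seed = 5)
  expect_equal(sum(d4$duplicate_count), 500)

  # oversized request is skipped with a warning
  expect_warning(out <- downsample(r, nrow(r) + 1, mode = "clonotypes"), "skipped")
  expect_null(out)
})

test_that("read downsampling preserves expected proportions", {
  r <- make_rep(c(400, rep(2, 300)))
  top_true <- r$proportion[1]
  draws <- vapply(1:200, function(i) {
    d <- downsample(r, 250, mode = "reads", seed = i)
    top <- d$proportion[d$junction_aa == r$junction_aa[1]]
    if (length(top)) top else 0
  }, numeric(1))
  n <- 250; N <- sum(r$duplicate_count); K <- r$duplicate_count[1]
  sd_hyper <- sqrt(n * (K / N) * (1 - K / N) * (N - n) / (N - 1)) / n
  expect_lt(abs(mean(draws) - top_true), 3 * sd_hyper)
})

test_that("summarize_cohort emits one row per repertoire per size and flags skips", {
  co <- toy_cohort()
  full <- summarize_cohort(co)
  expect_equal(nrow(full), 4)
  expect_true(all(c("clonal_volume", "top_prop", "hyper_prop", "small_prop",
                    "rare_prop", "chao1", "hill_q1", "hill_q2",
                    "gini_simpson", "gini") %in% names(full)))

  # full-size rows agree with per-metric single calls
  r11 <- get_repertoire(co, "S1", "i1", "IGH")
  row <- full[full$individual_id == "i1" & full$locus == "IGH", ]
  expect_equal(row$chao1, chao1(r11))
  expect_equal(row$gini, gini_coefficient(r11))

  # a size larger than a repertoire's reads is flagged skipped, not fatal
  sz <- summarize_cohort(co, sizes = c(5, 1000), mode = "reads", seed = 2)
  expect_equal(nrow(sz), 12)
  expect_true(all(sz$skipped[sz$size == "1000"]))
  expect_false(any(sz$skipped[sz$size == "5"]))

  # deterministic given the seed
  sz2 <- summarize_cohort(co, sizes = c(5, 1000), mode = "reads", seed = 2)
  expect_equal(sz, sz2)
})
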