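test_that("marker means and shares reproduce the published focus summaries", {
  foci <- expand_foci_totals()
  mm <- marker_means(foci)

  cepa <- mm[mm$sample_id == "cepa", ]
  expect_equal(round_half_up(cepa$mlh1_mean, 1), 11.1)
  expect_equal(round_half_up(cepa$mus81_mean, 1), 4.1)
  expect_equal(cepa$mlh1_share, 73)
  expect_equal(cepa$mus81_share, 27)

  dip <- mm[mm$sample_id == "f1_diploid", ]
  expect_equal(dip$mlh1_share, 70)
  expect_equal(dip$mus81_share, 30)

  # shares always sum to 100
  expect_true(all(mm$mlh1_share + mm$mus81_share == 100))

  # symmetric input gives a 50:50 split
  sym <- data.frame(sample_id = "S", slide_id = rep(c("s1", "s2"), each = 3),
                    cell_id = rep(sprintf("c%d", 1:3), 2),
                    marker = rep(c("MLH1", "MUS81"), each = 3),
                    count = c(4, 5, 6, 4, 5, 6))
  mm_sym <- marker_means(sym)
  expect_equal(mm_sym$mlh1_share, 50)

  # missing marker errors with its name
  expect_error(marker_means(foci[foci$marker == "MLH1", ]), "MUS81",
               class = "chiasmetry_validation_error")
})

test_that("artificial population enumerates the cross product and exclusions", {
  pop <- artificial_population(c(2, 3), c(1, 2))
  expect_equal(pop$ratios, c(2, 1, 3, 1.5))
  expect_equal(pop$n_pairs, 4)
  expect_equal(pop$n_excluded, 0)

  expect_equal(artificial_population(5, 5)$ratios, 1)

  pop <- artificial_population(c(4, 4), c(0, 2))
  expect_equal(pop$ratios, c(2, 2))
  expect_equal(pop$n_excluded, 2)

  expect_error(artificial_population(c(1, 2), 0), "no finite ratios",
               class = "chiasmetry_validation_error")

  # size invariant under random inputs
  set.seed(5)
  for (i in 1:20) {
    a <- rpois(sample(1:8, 1), 6)
    b <- rpois(sample(1:8, 1), 3)
    if (all(b == 0)) next
    pop <- artificial_population(a, b)
    expect_equal(pop$n_pairs + pop$n_excluded, length(a) * length(b))
  }
})

test_that("inverse-ratio weighting equals the harmonic mean", {
  est <- weighted_mean_ratio(c(1, 2, 4))
  expect_equal(est$estimate, 3 / (1 + 0.5 + 0.25)) # 1.7143, hand computed
  expect_equal(est$estimate, 1 / mean(1 / c(1, 2, 4)), tolerance = 1e-12)

  set.seed(8)
  for (i in 1:50) {
    r <- rexp(sample(2:40, 1)) + 0.1
    est <- weighted_mean_ratio(r)
    expect_equal(est$estimate, 1 / mean(1 / r), tolerance = 1e-12)
    # harmonic <= arithmetic, strict when ratios differ
    un <- weighted_mean_ratio(r, "unweighted")
    expect_true(est$estimate <= un$estimate + 1e-12)
    # any positive weighting stays inside the ratio range
    dev <- weighted_mean_ratio(r, "inverse_abs_deviation")
    for (e in list(est, un, dev)) {
      expect_true(e$estimate >= min(r) - 1e-12 && e$estimate <= max(r) + 1e-12)
    }
  }

  # constancy under every scheme
  for (scheme in c("inverse_ratio", "inverse_abs_deviation", "unweighted")) {
    expect_equal(weighted_mean_ratio(rep(2.5, 10), scheme)$estimate, 2.5)
  }

  expect_equal(weighted_mean_ratio(c(2, 1, 3, 1.5), "unweighted")$estimate,
               1.875)
})

test_that("slide consistency check compares the slide ratio to the pair-ratio interval", {
  # identical constant counts: slide ratio equals every pair ratio
  const <- data.frame(sample_id = "S", slide_id = rep(c("s1", "s2"), each = 4),
                      cell_id = rep(sprintf("c%d", 1:4), 2),
                      marker = rep(c("MLH1", "MUS81"), each = 4),
                      count = c(rep(8L, 4), rep(4L, 4)))
  mm <- marker_means(const)
  est <- weighted_mean_ratio(artificial_population(rep(8L, 4), rep(4L, 4)))
  chk <- slide_consistency_check(mm, est)
  expect_true(chk$consistent)
  expect_equal(chk$slide_ratio, 2)

  # adversarial: population from one pair of cells, means from another
  est_far <- weighted_mean_ratio(artificial_population(rep(40L, 4),
                                                       rep(2L, 4)))
  expect_false(slide_consistency_check(mm, est_far)$consistent)

  # swapping marker labels inverts the ratio and preserves the verdict
  swapped <- const
  swapped$marker <- rep(c("MUS81", "MLH1"), each = 4)
  mm_sw <- marker_means(swapped)
  est_sw <- weighted_mean_ratio(artificial_population(rep(4L, 4), rep(8L, 4)))
  chk_sw <- slide_consistency_check(mm_sw, est_sw)
  expect_equal(chk_sw$slide_ratio, 1 / chk$slide_ratio)
  expect_equal(chk_sw$consistent, chk$consistent)
})

test_that("Wilcoxon comparisons use the exact distribution for small tie-free groups", {
  cmp <- compare_counts(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$method, "exact")
  expect_equal(cmp$p_value, 0.1) # 2 of the 20 arrangements are as extreme

  cmp <- compare_counts(c(1, 2, 3), c(1, 2, 3))
  expect_equal(cmp$p_value, 1)

  # exact path matches full enumeration for all small tie-free inputs
  set.seed(30)
  for (i in 1:30) {
    n_a <- sample(2:5, 1)
    n_b <- sample(2:5, 1)
    vals <- sample(1:100, n_a + n_b) # distinct: no ties
    a <- vals[seq_len(n_a)]
    b <- vals[-seq_len(n_a)]
    expect_equal(compare_counts(a, b)$p_value, oracle_wilcoxon_p(a, b),
                 tolerance = 1e-12)
  }

  # large/tied inputs switch to the corrected normal approximation
  cmp <- compare_counts(rep(1:5, 4), rep(2:6, 4))
  expect_equal(cmp$method, "normal")
  expect_true(cmp$p_value > 0 && cmp$p_value < 1)
})

test_that("published between-species MLH1 mean difference recomputes", {
  foci <- expand_foci_totals()
  cmp <- compare_counts(
    foci$count[foci$sample_id == "cepa" & foci$marker == "MLH1"],
    foci$count[foci$sample_id == "fistulosum" & foci$marker == "MLH1"])
  expect_equal(round_half_up(cmp$mean_difference, 1), 4.6)
  expect_equal(cmp$mean_difference, 409 / 37 - 257 / 40, tolerance = 1e-12)
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_equal(fdr_adjust(rep(0.5, 7)), rep(0.5, 7))
  # hand-computed: min over j >= i of p_(j) * m / j, in input order
  expect_equal(fdr_adjust(c(0.005, 0.04, 0.03)), c(0.015, 0.04, 0.04))

  set.seed(9)
  p <- runif(20)
  adj <- fdr_adjust(p)
  expect_true(all(adj <= 1) && all(adj >= p))
  # order-preserving in the sorted domain
  expect_equal(order(adj[order(p)]), seq_along(p))

  expect_error(fdr_adjust(c(0.5, 1.2)),
               class = "chiasmetry_validation_error")
})

test_that("pairwise group comparisons carry FDR-adjusted p-values", {
  foci <- expand_foci_totals()
  tests <- compare_foci_groups(foci, "MLH1")
  expect_equal(nrow(tests), 6)
  expect_true(all(tests$p_fdr >= tests$p_value))
  expect_equal(tests$p_fdr, fdr_adjust(tests$p_value))
})
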