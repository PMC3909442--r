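# Concordance statistic, permutation/exact nulls, empirical p-value.

test_that("concordance statistic counts families sharing a subtype", {
  fams <- list(f1 = c("a", "b"), f2 = c("c", "d"), f3 = "e",
               f4 = c("f", "g", "h"))
  labs <- c(a = "LumA", b = "LumA",       # concordant pair
            c = "LumA", d = "LumB",       # discordant pair
            e = "Basal-like",             # singleton: can never contribute
            f = "LumB", g = "LumB", h = "Basal-like") # 2 of 3 concordant
  expect_identical(concordance_statistic(fams, labs), 2L)

  # all-singleton cohort
  expect_identical(
    concordance_statistic(list(f1 = "a", f2 = "b"),
                          c(a = "LumA", b = "LumA")), 0L)

  # missing label names the sample
  expect_error(concordance_statistic(fams, labs[-1]), "a")

  # duplicate sample id across families is rejected
  expect_error(concordance_statistic(list(f1 = "a", f2 = "a"),
                                     c(a = "LumA")),
               "more than one family")
})

test_that("statistic and p-value are invariant to relabeling", {
  set.seed(11)
  for (i in 1:5) {
    sizes <- sample(1:3, 6, replace = TRUE)
    n <- sum(sizes)
    sid <- sprintf("s%02d", seq_len(n))
    fams <- split(sid, rep.int(seq_along(sizes), sizes))
    names(fams) <- sprintf("fam%d", seq_along(sizes))
    labs <- stats::setNames(sample(LETTERS[1:3], n, replace = TRUE), sid)

    s0 <- concordance_statistic(fams, labs)

    # bijective rename of subtypes
    ren <- c(A = "Q", B = "R", C = "S")
    expect_identical(concordance_statistic(fams,
                                           stats::setNames(ren[labs], sid)),
                     s0)
    # permuting family ids
    expect_identical(concordance_statistic(fams[sample(length(fams))], labs),
                     s0)
  }
})

test_that("toy two-family null matches complete enumeration", {
  labels <- c("A", "A", "B", "B")
  sizes <- c(2, 2)

  # independent oracle: all 24 ordered arrangements, statistic per column
  perms <- all_permutations(labels)
  stats_enum <- apply(perms, 2, stat_by_blocks, sizes = sizes)
  expect_equal(mean(stats_enum == 2), 1 / 3) # concordance of one pair forces the other
  expect_equal(mean(stats_enum == 0), 2 / 3)
  expect_true(all(stats_enum %in% c(0, 2)))

  nd <- exact_null(labels, sizes)
  expect_equal(nd$mass[nd$support == 2], 1 / 3)
  expect_equal(nd$mass[nd$support == 0], 2 / 3)
  expect_equal(sum(nd$mass), 1, tolerance = 1e-12)
  expect_equal(empirical_pvalue(nd, 2), 1 / 3)

  # degenerate pools
  nd_same <- exact_null(c("A", "A", "A", "A"), c(2, 2))
  expect_equal(nd_same$mass[nd_same$support == 2], 1) # point mass at 2
  nd_singl <- exact_null(c("A", "B", "A"), c(1, 1, 1))
  expect_equal(nd_singl$mass[nd_singl$support == 0], 1) # sizes all 1
})

test_that("Monte-Carlo null converges to the exact null", {
  labels <- rep(c("Basal-like", "HER2-enriched", "LumA", "LumB",
                  "Normal-like"), c(4, 1, 3, 2, 2))
  sizes <- c(2, 2, 2, 3, 3)
  ex <- exact_null(labels, sizes)
  mc <- permutation_null(labels, sizes, n_replicates = 2e4, seed = 5)
  expect_identical(mc$support, ex$support)
  se <- sqrt(ex$mass * (1 - ex$mass) / mc$n_replicates)
  expect_true(all(abs(mc$mass - ex$mass) <= 3 * se + 1e-12))

  # same seed => identical null; different seed => (almost surely) not
  mc2 <- permutation_null(labels, sizes, n_replicates = 2e4, seed = 5)
  expect_identical(mc$mass, mc2$mass)
})

test_that("empirical p-value follows the upper-tail conventions", {
  nd <- exact_null(c("A", "A", "B", "B"), c(2, 2))
  expect_equal(empirical_pvalue(nd, 0), 1)        # every replicate >= 0
  expect_equal(empirical_pvalue(nd, 3), 0)        # beyond the max support
  expect_error(empirical_pvalue(nd, 2, convention = "add_one"),
               "Monte-Carlo")

  mc <- permutation_null(c("A", "A", "B", "B"), c(2, 2),
                         n_replicates = 999, seed = 2)
  r <- round(sum(mc$mass[mc$support >= 2]) * 999)
  expect_equal(empirical_pvalue(mc, 2, convention = "add_one"),
               (r + 1) / 1000)
})

test_that("input contracts are enforced", {
  expect_error(permutation_null(c("A", "B"), c(2, 2)), "sizes sum")
  expect_error(exact_null(c("A", "B"), c(2, 2)), "sizes sum")
  expect_error(exact_null(rep(LETTERS[1:5], 10), rep(2, 25)), "budget")
  expect_error(run_aggregation_test(list(f1 = "a", f2 = "b"),
                                    c(a = "LumA", b = "LumA")),
               "two or more members")
})

test_that("the bundled 11-family table reproduces its published behaviour", {
  t3 <- load_family_subtypes(famagg_example("table3.csv"))
  expect_identical(concordance_statistic(t3$families, t3$labels), 8L)

  rep <- run_aggregation_test(t3$families, t3$labels,
                              n_replicates = 2e4, seed = 17)
  expect_identical(rep$observed_statistic, 8L)
  expect_identical(rep$pool_policy, "multicase_only")
  # pooled multiset: 3 basal, 2 HER2, 9 lumA, 8 lumB, 1 normal over 11 families
  expect_identical(sum(rep$family_sizes), 23L)
  expect_identical(as.integer(rep$label_multiset),
                   c(3L, 2L, 9L, 8L, 1L))
  expect_lt(rep$p_value, 0.01)
})

test_that("the confirmation-cohort table yields observed statistic 4", {
  t4 <- load_family_subtypes(famagg_example("table4.csv"))
  # strict definition: the family with two Normal-like tumors counts too
  expect_identical(concordance_statistic(t4$families, t4$labels), 4L)

  # restricted to the three two-case families the count is 3
  two_case <- c("L101", "L414", "L505")
  fams <- t4$families[t4$families$family_id %in% two_case, ]
  expect_identical(concordance_statistic(fams, t4$labels), 3L)

  rep <- run_aggregation_test(t4$families, t4$labels, method = "exact")
  expect_equal(rep$p_value, 0.016912, tolerance = 1e-4)
})

test_that("singleton families never change a multicase-only report", {
  t4 <- load_family_subtypes(famagg_example("table4.csv"))
  fams2 <- rbind(t4$families,
                 data.frame(family_id = c("X1", "X2"),
                            sample_id = c("x1", "x2")))
  labs2 <- c(t4$labels, x1 = "LumA", x2 = "LumA")
  r1 <- run_aggregation_test(t4$families, t4$labels,
                             n_replicates = 5e3, seed = 9)
  r2 <- run_aggregation_test(fams2, labs2, n_replicates = 5e3, seed = 9)
  expect_identical(r1$observed_statistic, r2$observed_statistic)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$null$mass, r2$null$mass)

  # under all_samples the singletons do enter the pool
  r3 <- run_aggregation_test(fams2, labs2, n_replicates = 5e3, seed = 9,
                             pool_policy = "all_samples")
  expect_identical(sum(r3$family_sizes), 14L)
})
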