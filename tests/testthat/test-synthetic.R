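# Synthetic cohort generator: structure, determinism, null embedding.

test_that("configuration invariants are validated", {
  expect_error(synthetic_config(prevalence = c(0.5, 0.5)), "one entry per")
  expect_error(synthetic_config(prevalence = c(0.5, 0.2, 0.1, 0.1, 0.2)),
               "sum to 1")
  expect_error(synthetic_config(rho = 1.5), "rho")
  expect_error(synthetic_config(sigma = 0), "sigma")
  expect_error(synthetic_config(n_genes = 20), "exceed")
  expect_error(synthetic_config(family_sizes = c(2, 0)), "family sizes")
})

test_that("centroids have the documented block structure", {
  cfg <- synthetic_config(n_genes = 100, n_markers_per_subtype = 10)
  cen <- generate_centroids(cfg)
  expect_identical(dim(cen), c(100L, 5L))
  # exactly 50 genes deviate from baseline, 10 per column
  expect_identical(sum(rowSums(cen != 0) > 0), 50L)
  expect_equal(unname(colSums(cen != 0)), rep(10, 5))
  # marker genes carry baseline + delta in their own column only
  expect_true(all(cen[1:10, 1] == cfg$delta))
  expect_true(all(cen[1:10, -1] == 0))

  # zero effect collapses all columns
  cen0 <- generate_centroids(synthetic_config(n_genes = 100, delta = 0))
  expect_true(all(cen0 == cen0[, 1]))

  # byte-identical regeneration
  expect_identical(cen, generate_centroids(cfg))
})

test_that("identical configuration yields an identical cohort", {
  cfg <- tiny_config(family_sizes = c(rep(2L, 5), 3L), rho = 0.5, seed = 99)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$expression, c2$expression)
  expect_identical(c1$annotation, c2$annotation)
  m1 <- generate_methylation(cfg, c1, "g00001")
  m2 <- generate_methylation(cfg, c2, "g00001")
  expect_identical(m1$methylation, m2$methylation)
  expect_identical(m1$expression, m2$expression)
})

test_that("rho = 1 forces every multi-case family to be concordant", {
  cfg <- tiny_config(family_sizes = c(rep(1L, 4), rep(2L, 6), 3L), rho = 1,
                     seed = 3)
  co <- generate_cohort(cfg)
  labs <- stats::setNames(co$annotation$subtype, co$annotation$sample_id)
  expect_identical(concordance_statistic(co$families, labs), 7L)
})

test_that("generated labels follow the prevalence vector", {
  prev <- c(0.13, 0.10, 0.47, 0.26, 0.04)
  cfg <- synthetic_config(n_genes = 5, n_markers_per_subtype = 1,
                          prevalence = prev,
                          family_sizes = rep(1L, 4000), seed = 21)
  co <- generate_cohort(cfg)
  freq <- table(factor(co$annotation$subtype,
                       levels = cfg$subtype_names)) / 4000
  gof <- stats::chisq.test(table(factor(co$annotation$subtype,
                                        levels = cfg$subtype_names)),
                           p = prev)
  expect_gt(gof$p.value, 1e-3)
  expect_true(all(abs(as.numeric(freq) - prev) < 0.03))
})

test_that("at rho = 0 the statistic's distribution equals the permutation null", {
  # family labels are exchangeable under the null, so conditional on the
  # label multiset the generated arrangement is uniform: the cohort
  # statistic and one random-reassignment replicate of the same labels are
  # identically distributed. Compare the two samples over many cohorts.
  sizes <- c(rep(2L, 10), 3L)
  n_cohorts <- 10000
  stats_obs <- integer(n_cohorts)
  stats_null <- integer(n_cohorts)
  for (i in seq_len(n_cohorts)) {
    co <- generate_cohort(
      synthetic_config(n_genes = 5, n_markers_per_subtype = 1,
                       family_sizes = sizes, rho = 0, seed = 1000L + i))
    labs <- stats::setNames(co$annotation$subtype, co$annotation$sample_id)
    stats_obs[i] <- concordance_statistic(co$families, labs)
    nd <- permutation_null(unname(labs), sizes, n_replicates = 1,
                           seed = 900000L + i)
    stats_null[i] <- nd$support[nd$mass > 0]
  }
  counts <- rbind(tabulate(stats_obs + 1L, 12), tabulate(stats_null + 1L, 12))
  keep <- colSums(counts) >= 10 # pool sparse cells
  tab <- counts[, keep, drop = FALSE]
  pooled <- rowSums(counts[, !keep, drop = FALSE])
  if (sum(pooled) > 0) tab <- cbind(tab, pooled)
  gof <- suppressWarnings(stats::chisq.test(tab))
  expect_gt(gof$p.value, 1e-3)
})

test_that("expected concordance is nondecreasing in rho", {
  mean_stat <- vapply(c(0, 0.3, 0.6, 0.9), function(rho) {
    stats_i <- vapply(1:300, function(i) {
      co <- generate_cohort(
        synthetic_config(n_genes = 5, n_markers_per_subtype = 1,
                         family_sizes = c(rep(2L, 10), 3L), rho = rho,
                         seed = 5000L + i))
      labs <- stats::setNames(co$annotation$subtype,
                              co$annotation$sample_id)
      concordance_statistic(co$families, labs)
    }, integer(1))
    mean(stats_i)
  }, numeric(1))
  expect_true(all(diff(mean_stat) > 0))
})

test_that("methylation ratios straddle the threshold by construction", {
  cfg <- tiny_config(family_sizes = rep(1L, 100), methylated_fraction = 0.5,
                     methylation_knockdown = 3, sigma = 1, seed = 8)
  co0 <- generate_cohort(cfg)
  co <- generate_methylation(cfg, co0, "g00001")
  truth <- co$annotation$methylated
  r <- co$methylation$ratio
  expect_true(all(r[truth] > 0.3 & r[truth] < 0.8))
  expect_true(all(r[!truth] < 0.1))   # never exceeds the 0.2 threshold

  # knockdown is applied to the target gene only, in methylated samples only
  expect_equal(co$expression["g00001", ],
               co0$expression["g00001", ] - 3 * truth)
  expect_identical(co$expression["g00002", ], co0$expression["g00002", ])

  # zero methylated fraction: all ratios low, zero positive downstream calls
  cfg0 <- tiny_config(family_sizes = rep(1L, 50), methylated_fraction = 0)
  com <- generate_methylation(cfg0, generate_cohort(cfg0), "g00001")
  expect_true(all(com$methylation$ratio < 0.1))
  expect_identical(sum(call_methylation(com$methylation)$positive), 0L)

  expect_error(generate_methylation(cfg, co0, "nope"), "not present")
})

test_that("a cohort round-trips through plain-text files", {
  cfg <- tiny_config(family_sizes = c(2L, 2L, 3L), seed = 12,
                     methylated_fraction = 0.5)
  co <- generate_methylation(cfg, generate_cohort(cfg), "g00001")
  dir <- tempfile()
  files <- write_cohort(co, dir)
  expect_equal(load_expression(files["expression"]), co$expression,
               tolerance = 1e-12)
  expect_identical(load_families(files["families"])$sample_id,
                   co$families$sample_id)
  expect_equal(load_ratios(files["methylation"])$ratio,
               co$methylation$ratio, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
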