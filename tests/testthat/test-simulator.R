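# Cohort simulator: determinism, agreement with exact CRF probabilities,
# two-exam matrix structure, and Dirichlet-Multinomial clusters.

test_that("identical configurations reproduce the cohort bit for bit", {
  cfg <- cohort_config(n_individuals = 12, n_genes = 10, n_annotations = 5,
                       seed = 33)
  a <- simulate_watershed_instances(cfg)
  b <- simulate_watershed_instances(cfg)
  expect_identical(a$E, b$E)
  expect_identical(a$G, b$G)
  expect_identical(a$median_z, b$median_z)
  expect_identical(a$variants, b$variants)
  expect_identical(a$truth$Z, b$truth$Z)
  # and a different seed changes it
  cfg2 <- cohort_config(n_individuals = 12, n_genes = 10, n_annotations = 5,
                        seed = 34)
  expect_false(identical(simulate_watershed_instances(cfg2)$E, a$E))
})

zero_potential_params <- function(K = 4, P = 3) {
  base <- default_sim_params(K, P)
  base$beta[] <- 0
  base$theta[] <- 0
  base
}

test_that("zero potentials give latent states at one half per signal", {
  cfg <- cohort_config(n_individuals = 100, n_genes = 100, n_annotations = 3,
                       true_params = zero_potential_params(),
                       n2_fraction = 0, missing_rate = 0, seed = 55)
  coh <- simulate_watershed_instances(cfg)
  freq <- colMeans(coh$truth$Z)
  se <- sqrt(0.25 / nrow(coh$truth$Z))
  expect_true(all(abs(freq - 0.5) < 3 * se))
})

test_that("pairwise coupling induces the correlation exact enumeration predicts", {
  params <- zero_potential_params()
  params$theta[1, 2] <- params$theta[2, 1] <- 1.5
  cfg <- cohort_config(n_individuals = 100, n_genes = 100, n_annotations = 3,
                       true_params = params, n2_fraction = 0,
                       missing_rate = 0, seed = 56)
  coh <- simulate_watershed_instances(cfg)
  Z <- coh$truth$Z
  expect_gt(cor(Z[, 1], Z[, 2]), 0)
  # exact joint P(Z1 = 1, Z2 = 1) by brute-force enumeration
  oracle <- naive_posterior(rnorm(3) * 0, rep(NA_integer_, 4), params)
  p11 <- sum(oracle$prob[oracle$states[, 1] == 1 & oracle$states[, 2] == 1])
  emp <- mean(Z[, 1] == 1 & Z[, 2] == 1)
  expect_lt(abs(emp - p11), 3 * sqrt(p11 * (1 - p11) / nrow(Z)))
})

test_that("empirical (Z, E) frequencies converge to the exact generative law", {
  # two signals with no annotation effect: iid instances, enumerable law
  params <- default_sim_params(n_signals = 2, n_annotations = 2,
                               n_informative = 0)
  params$beta[, 1] <- -0.5
  cfg <- cohort_config(n_individuals = 250, n_genes = 200, n_annotations = 2,
                       n_signals = 2, true_params = params,
                       n2_fraction = 0, missing_rate = 0, seed = 57)
  coh <- simulate_watershed_instances(cfg)
  n <- nrow(coh$E)
  # exact P(z, e) over 4 latent x 9 emission configurations
  st <- naive_states(2)
  pz <- naive_posterior(c(0, 0), c(NA_integer_, NA_integer_), params)$prob
  tv <- 0
  for (s in 1:4) for (e1 in 1:3) for (e2 in 1:3) {
    pexact <- pz[s] * params$phi[[1]][st[s, 1] + 1, e1] *
      params$phi[[2]][st[s, 2] + 1, e2]
    pemp <- mean(coh$truth$Z[, 1] == st[s, 1] & coh$truth$Z[, 2] == st[s, 2] &
                   coh$E[, 1] == e1 & coh$E[, 2] == e2)
    tv <- tv + abs(pexact - pemp) / 2
  }
  expect_lt(tv, 0.02)
})

test_that("emitted statuses are consistent with the stored latent draws", {
  cfg <- cohort_config(n_individuals = 30, n_genes = 30, n_annotations = 4,
                       n2_fraction = 0.05, missing_rate = 0.1, seed = 58)
  coh <- simulate_watershed_instances(cfg)
  # binarizing the stored Z-scores reproduces the emitted categories
  E2 <- binarize_outliers(coh$median_z)
  expect_identical(E2[!is.na(coh$E)], coh$E[!is.na(coh$E)])
  # N2 partners share gene, annotations and a variant
  if (nrow(coh$n2_pairs) > 0) {
    pr <- coh$n2_pairs[1, ]
    i <- which(coh$instances$gene == pr$gene &
                 coh$instances$individual == pr$held_in)
    j <- which(coh$instances$gene == pr$gene &
                 coh$instances$individual == pr$held_out)
    expect_equal(coh$G[i, ], coh$G[j, ])
    expect_equal(coh$truth$Z[i, ], coh$truth$Z[j, ])
  }
})

test_that("perfect exam correlation collapses the two exams onto one draw", {
  cfg <- cohort_config(n_individuals = 20, n_genes = 30, n_annotations = 2,
                       exam_correlation = 1, outlier_inject_rate = 0,
                       seed = 60)
  m <- simulate_omics_matrices(cfg)
  expect_equal(m$exam1, m$exam5, tolerance = 1e-12)
})

test_that("cross-exam correlation matches the configured level", {
  cfg <- cohort_config(n_individuals = 900, n_genes = 150, n_annotations = 2,
                       exam_correlation = 0.67, outlier_inject_rate = 0,
                       seed = 61)
  m <- simulate_omics_matrices(cfg)
  r <- vapply(seq_len(nrow(m$exam1)), function(i)
    cor(m$exam1[i, ], m$exam5[i, ]), numeric(1))
  expect_lt(abs(median(r) - 0.67), 0.05)
})

test_that("an injected outlier is recovered by the joint-outlier caller", {
  cfg <- cohort_config(n_individuals = 20, n_genes = 50,
                       n_annotations = 2, exam_correlation = 0.67,
                       outlier_inject_rate = 0.001, outlier_magnitude = 5,
                       seed = 62)
  m <- simulate_omics_matrices(cfg)
  expect_equal(nrow(m$injected), 1)
  calls <- call_joint_outliers(m$exam1, m$exam5, threshold = 3)
  is_out <- matrix(calls$status %in% c("over_outlier", "under_outlier"),
                   nrow(calls$status))
  found <- which(is_out, arr.ind = TRUE)
  expect_equal(nrow(found), 1)
  expect_equal(unname(found[1, ]),
               c(m$injected$feature, m$injected$individual))
})

test_that("junction clusters respect depths and reject bad concentrations", {
  cfg <- cohort_config(n_individuals = 50, n_genes = 5, seed = 63,
                       mean_depth = 100)
  cl <- simulate_junction_clusters(cfg, n_clusters = 2)[[1]]
  expect_true(all(rowSums(cl$counts) >= 0))
  expect_equal(ncol(cl$counts), 3)
  # explicit zero-depth individual yields an all-zero row
  cl0 <- simulate_junction_clusters(cfg, alpha = c(10, 10),
                                    depths = c(0, rep(100, 49)))[[1]]
  expect_equal(unname(cl0$counts[1, ]), c(0L, 0L))
  expect_true(all(rowSums(cl0$counts[-1, ]) == 100))
  expect_error(simulate_junction_clusters(cfg, alpha = c(10, -1)),
               "positive")
})

test_that("symmetric concentrations give balanced junction usage", {
  cfg <- cohort_config(n_individuals = 1000, n_genes = 5, seed = 64)
  cl <- simulate_junction_clusters(cfg, alpha = c(10, 10),
                                   depths = 100)[[1]]
  prop1 <- cl$counts[, 1] / rowSums(cl$counts)
  # Var(p1) = mu(1-mu)(n+a0)/(n(1+a0)) at mu=.5, n=100, a0=20
  se <- sqrt(0.25 * 120 / (100 * 21) / 1000)
  expect_lt(abs(mean(prop1) - 0.5), 3 * se)
})

test_that("invalid configurations are rejected with clear errors", {
  expect_error(cohort_config(0, 10), "positive")
  expect_error(cohort_config(10, 10, exam_correlation = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(10, 10, n2_fraction = -0.1), "\\[0, 1\\]")
  wrong <- default_sim_params(4, 7)
  expect_error(cohort_config(10, 10, n_annotations = 5, true_params = wrong),
               "annotation")
})
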