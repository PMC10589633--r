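# Outlier calling: filters, transforms, residualization, gene-level
# aggregation, joint calls, global-outlier removal, replication, sharing.

test_that("expression filter keeps genes supported in enough individuals", {
  # 10-gene fixture, 5 individuals; hand-worked pass pattern
  counts <- matrix(0, 10, 5)
  tpm <- matrix(0, 10, 5)
  counts[1, 1] <- 6;  tpm[1, 1] <- 0.2       # 20% of individuals, boundary
  counts[2, ] <- 100; tpm[2, ] <- 5          # clear pass
  counts[3, 1] <- 5;  tpm[3, 1] <- 5         # too few reads
  counts[4, 1] <- 50; tpm[4, 1] <- 0.1       # TPM not strictly above 0.1
  counts[5, 1:2] <- 6; tpm[5, 1:2] <- 0.11   # 40% pass
  # genes 6-10: all zero                      -> removed
  vals <- log2(tpm + 2)
  rownames(vals) <- rownames(counts) <- rownames(tpm) <- paste0("g", 1:10)
  kept <- filter_expression_matrix(vals, counts, tpm)
  expect_equal(rownames(kept), c("g1", "g2", "g5"))
  expect_error(filter_expression_matrix(vals[6:10, , drop = FALSE],
                                        counts[6:10, , drop = FALSE],
                                        tpm[6:10, , drop = FALSE]),
               "filter")
})

test_that("the m-value transform has its textbook identities", {
  expect_equal(mvalue_transform(0.5), 0)
  expect_equal(mvalue_transform(0.8), 2)
  expect_equal(mvalue_transform(0.2), -2)
  b <- seq(0.01, 0.99, by = 0.01)
  expect_equal(mvalue_inverse(mvalue_transform(b)), b, tolerance = 1e-12)
  expect_true(all(diff(mvalue_transform(b)) > 0))
  expect_error(mvalue_transform(0), "strictly inside")
  expect_error(mvalue_transform(1), "strictly inside")
})

test_that("hidden factors reproduce the spectrum and are orthogonal", {
  set.seed(88)
  # rank-1 matrix: one factor explains essentially all variance
  u <- rnorm(20); v <- rnorm(12)
  X1 <- outer(u, v)
  f1 <- estimate_hidden_factors(X1, 1)
  expect_gt(attr(f1, "explained_variance")[1], 0.999)
  # general fixture vs an independent eigen-decomposition oracle
  X <- matrix(rnorm(20 * 30), 20, 30)
  f <- estimate_hidden_factors(X, 5)
  expect_lt(max(abs(crossprod(f) - diag(5))), 1e-8)
  Xc <- X - rowMeans(X)
  ev <- eigen(crossprod(Xc), symmetric = TRUE)$values
  expect_equal(attr(f, "explained_variance"),
               (ev / sum(ev))[1:5], tolerance = 1e-10)
  expect_error(estimate_hidden_factors(X, 20), "at most")
})

test_that("residualization matches closed-form hat-matrix residuals", {
  set.seed(90)
  n_ind <- 8
  vals <- matrix(rnorm(5 * n_ind), 5, n_ind)
  cov <- matrix(rnorm(n_ind * 2), n_ind, 2,
                dimnames = list(NULL, c("c1", "c2")))
  z <- residualize_and_scale(vals, cov, min_obs = 5)
  X <- cbind(1, cov)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  for (i in 1:5) {
    res <- drop((diag(n_ind) - H) %*% vals[i, ])
    expect_equal(unname(z[i, ]), unname(scale(res)[, 1]), tolerance = 1e-10)
  }
  # per-feature mean 0, sd 1
  expect_lt(max(abs(rowMeans(z))), 1e-8)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-8)
})

test_that("residualization handles orthogonal covariates and degenerate designs", {
  # covariate orthogonal to the (centered) feature: Z = standardized values
  y <- c(-3, -1, 0, 1, 3, 0)
  cov <- matrix(c(1, -3, 0, 3, -1, 0), ncol = 1) # orthogonal to y and to 1
  z <- residualize_and_scale(matrix(y, 1), cov, min_obs = 5)
  expect_equal(unname(z[1, ]), unname(scale(y)[, 1]), tolerance = 1e-10)
  # a feature among its own covariates -> zero residual variance -> excluded
  expect_warning(
    z2 <- residualize_and_scale(matrix(y, 1), matrix(y, ncol = 1),
                                min_obs = 5),
    "zero residual variance")
  expect_true(all(is.na(z2)))
  # collinear design is a hard error naming the column
  bad <- cbind(a = cov[, 1], b = 2 * cov[, 1])
  expect_error(residualize_and_scale(matrix(y, 1), bad, min_obs = 5),
               "collinear")
})

test_that("gene-level methylation takes the median Z upstream of the TSS", {
  cpg_z <- rbind(cg1 = c(1, 5), cg2 = c(3, -1), cg3 = c(10, 10))
  colnames(cpg_z) <- c("I1", "I2")
  coords <- data.frame(cpg = c("cg1", "cg2", "cg3"), chrom = "chr1",
                       pos = c(9000L, 9900L, 8400L))
  tss <- data.frame(gene = c("gPlus", "gMinus"), chrom = "chr1",
                    tss = c(10000L, 8900L), strand = c("+", "-"))
  gz <- gene_level_methylation(cpg_z, coords, tss)
  # gPlus (+ strand, TSS 10000): window [8500, 10000] -> cg1, cg2; cg3 at
  # 8400 is 1600 bp upstream and excluded
  expect_equal(unname(gz["gPlus", ]), c(2, 2))
  # gMinus (- strand, TSS 8900): window [8900, 10400] -> cg1, cg2
  expect_equal(unname(gz["gMinus", ]), c(2, 2))
  # a single qualifying CpG passes through unchanged
  gz1 <- gene_level_methylation(cpg_z[1, , drop = FALSE], coords[1, ],
                                tss[1, , drop = FALSE])
  expect_equal(unname(gz1[1, ]), c(1, 5))
  expect_error(
    gene_level_methylation(rbind(cgX = c(0, 0)), coords, tss),
    "no coordinates")
})

test_that("joint outlier statuses follow the two-exam rules", {
  z1 <- matrix(c(3.2, 3.2, 0.5, -3.4, 0.5, NA), 6, 1,
               dimnames = list(paste0("f", 1:6), "I1"))
  z5 <- matrix(c(3.5, 1.5, -0.9, -3.1, 2.5, 1), 6, 1,
               dimnames = dimnames(z1))
  calls <- call_joint_outliers(z1, z5, threshold = 3)
  expect_equal(unname(calls$status[, 1]),
               c("over_outlier", "neither", "control", "under_outlier",
                 "neither", "missing"))
  # outliers and controls are disjoint by construction
  expect_false(any(calls$status == "over_outlier" &
                     calls$status == "control"))
  expect_error(call_joint_outliers(z1, z5[1:3, , drop = FALSE]), "aligned")
})

test_that("global-outlier removal applies the Tukey fence per individual", {
  # counts {2,3,3,4,50}: Q3 = 4, IQR = 1, fence 5.5 -> only the 50 removed
  set.seed(91)
  n_feat <- 80
  status_counts <- c(2, 3, 3, 4, 50)
  z1 <- matrix(0, n_feat, 5,
               dimnames = list(paste0("f", 1:n_feat), paste0("I", 1:5)))
  for (j in 1:5) z1[seq_len(status_counts[j]), j] <- 4
  z5 <- z1
  calls <- call_joint_outliers(z1, z5, threshold = 3)
  cleaned <- remove_global_outliers(calls)
  expect_equal(cleaned$global_outliers, "I5")
  expect_true(all(cleaned$status[, "I5"] == "missing"))
  expect_true(any(cleaned$status[, "I4"] == "over_outlier"))
  # equal counts: IQR 0, fence = Q3, nobody removed
  z1e <- matrix(0, 10, 4); z1e[1:2, ] <- 4
  dimnames(z1e) <- list(paste0("f", 1:10), paste0("I", 1:4))
  eq <- remove_global_outliers(call_joint_outliers(z1e, z1e, 3))
  expect_equal(length(eq$global_outliers), 0)
  # a single individual is never removed
  solo <- remove_global_outliers(
    call_joint_outliers(z1[, 1, drop = FALSE], z5[, 1, drop = FALSE], 3))
  expect_equal(length(solo$global_outliers), 0)
})

test_that("replication across exams counts sign-consistent exceedances", {
  z1 <- matrix(c(4, 4, 4, -4, -4, -4, 0.5), 7, 1,
               dimnames = list(paste0("f", 1:7), "I1"))
  z5 <- matrix(c(3, 1, 2.5, -3, -1, 2.5, 4), 7, 1,
               dimnames = dimnames(z1))
  # 6 exam-1 outliers at |Z|>3; replicating at |Z|>2 with same sign:
  # f1 (3), f3 (2.5), f4 (-3); f6 flips sign -> 3/6
  expect_equal(as.numeric(replication_rate(z1, z5, 3)), 0.5)
  expect_equal(attr(replication_rate(z1, z5, 3), "n_outliers"), 6)
  # all replicate
  expect_equal(as.numeric(replication_rate(z1[c(1, 3), , drop = FALSE],
                                           z5[c(1, 3), , drop = FALSE], 3)), 1)
  # under-direction with a sign flip in exam 5 does not count
  expect_equal(as.numeric(
    replication_rate(z1[6, , drop = FALSE], z5[6, , drop = FALSE], 3,
                     direction = "under")), 0)
  expect_error(replication_rate(z1[7, , drop = FALSE],
                                z5[7, , drop = FALSE], 3), "undefined")
})

test_that("replication rate is non-increasing in the call threshold on nested sets", {
  set.seed(93)
  cfg <- cohort_config(n_individuals = 80, n_genes = 100, n_annotations = 2,
                       exam_correlation = 0.6, outlier_inject_rate = 0.02,
                       seed = 94)
  m <- simulate_omics_matrices(cfg)
  rates <- vapply(c(2, 2.5, 3, 3.5), function(thr)
    as.numeric(replication_rate(m$exam1, m$exam5, thr)), numeric(1))
  expect_true(all(diff(rates) >= -1e-12))
})

test_that("cross-omics sharing detects a constructed shift", {
  feats <- paste0("f", 1:60); inds <- paste0("I", 1:20)
  set.seed(95)
  za <- matrix(0, 60, 20, dimnames = list(feats, inds))
  za[1:5, 1] <- 4  # signal-a outliers
  calls_a <- call_joint_outliers(za, za, threshold = 3)
  zb <- matrix(rnorm(60 * 20, 0, 0.5), 60, 20, dimnames = list(feats, inds))
  zb[1:5, 1] <- 4  # every a-outlier has |Z_b| = 4
  sh <- cross_omics_sharing(calls_a, zb, zb)
  expect_equal(sh$sharing, 1)
  expect_lt(sh$p_value, 1e-3)
  # disjoint feature universes are an error
  zb2 <- zb; rownames(zb2) <- paste0("x", 1:60)
  expect_error(cross_omics_sharing(calls_a, zb2, zb2), "universe")
  # null case: no shift -> sharing at the background rate, p not small
  zb_null <- matrix(rnorm(60 * 20, 0, 0.5), 60, 20,
                    dimnames = list(feats, inds))
  sh0 <- cross_omics_sharing(calls_a, zb_null, zb_null)
  expect_lt(sh0$sharing, 0.5)
  expect_gt(sh0$p_value, 0.01)
})
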