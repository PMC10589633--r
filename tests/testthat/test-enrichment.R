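# Rare-variant enrichment: rarity filter, window indicator, relative
# risk with CI and tests, enrichment comparison, ancestry matching.

test_that("rarity filtering requires all frequencies below the threshold", {
  v <- data.frame(
    variant_id = paste0("v", 1:4),
    chrom = "chr1", pos = 1:4 * 100L,
    carriers = "I1",
    af_cohort = c(0.005, 0.02, 0.005, 0.005),
    af_gnomad = c(0.005, 0.001, 0.001, NA),
    af_gnomad_afr = c(0.005, 0.001, 0.015, 0.001),
    stringsAsFactors = FALSE
  )
  expect_message(rare <- flag_rare_variants(v), "missing external")
  # v1 rare everywhere; v2 common in cohort; v3 common in a subpopulation;
  # v4 missing external AF treated as 0
  expect_equal(rare$variant_id, c("v1", "v4"))
  v$af_cohort[1] <- 1.2
  expect_error(flag_rare_variants(v), "malformed")
})

test_that("the window indicator is binary, boundary-correct and monotone", {
  v <- data.frame(
    variant_id = c("v1", "v2", "v3"),
    chrom = "chr1",
    pos = c(29999L, 30000L, 5000L),       # gene end 20000: +10kb flank
    carriers = c("I1", "I2", "I1,I2"),
    stringsAsFactors = FALSE
  )
  w <- data.frame(feature = "g1", chrom = "chr1",
                  start = 10000L, end = 20000L)
  ind <- rare_variant_indicator(v, w, flank = 10000,
                                individuals = c("I1", "I2", "I3"))
  # v1 at end + 9999 inside, v2 at end + 10000 outside (half-open),
  # v3 at start - 5000 inside; two variants for I1 still give 1
  expect_equal(unname(ind["g1", ]), c(1L, 1L, 0L))
  # enlarging the window never turns 1 into 0
  for (f in c(0, 2000, 10000, 50000)) {
    ind_f <- rare_variant_indicator(v, w, flank = f,
                                    individuals = c("I1", "I2", "I3"))
    if (f > 0) expect_true(all(ind_f >= prev))
    prev <- ind_f
  }
  expect_error(rare_variant_indicator(v, data.frame(
    feature = "g", chrom = "chr1", start = 10L, end = 5L)), "end < start")
})

test_that("relative risk matches direct arithmetic and scaling behaviour", {
  r <- relative_risk(30, 70, 100, 900)
  expect_equal(r$rr, 3)                     # 0.30 / 0.10
  expect_equal(r$se_log,
               sqrt(1 / 30 - 1 / 100 + 1 / 100 - 1 / 1000), tolerance = 1e-12)
  expect_equal(unname(r$ci_low),
               exp(log(3) - qnorm(0.975) * r$se_log), tolerance = 1e-12)
  expect_equal(unname(r$p_value),
               pt(log(3) / r$se_log, df = 100 + 1000 - 2,
                  lower.tail = FALSE), tolerance = 1e-12)
  expect_true(r$ci_low <= r$rr && r$rr <= r$ci_high)
  # equal proportions give RR = 1
  expect_equal(relative_risk(10, 90, 30, 270)$rr, 1)
  # scaling all cells x10 leaves RR fixed and narrows the CI
  r10 <- relative_risk(300, 700, 1000, 9000)
  expect_equal(r10$rr, 3)
  expect_lt(r10$ci_high - r10$ci_low, r$ci_high - r$ci_low)
  # zero cells are flagged, not corrected
  r0 <- relative_risk(0, 50, 10, 90)
  expect_true(r0$zero_cell)
  expect_true(is.na(r0$p_value))
  expect_error(relative_risk(-1, 5, 5, 5), "non-negative")
})

test_that("relative risk agrees with an exhaustive-count oracle on fuzzed tables", {
  set.seed(201)
  for (i in 1:300) {
    a <- sample(1:50, 1); b <- sample(1:200, 1)
    c <- sample(1:100, 1); d <- sample(1:500, 1)
    # oracle: rebuild proportions by explicit enumeration of instances
    outliers <- c(rep(1, a), rep(0, b))
    controls <- c(rep(1, c), rep(0, d))
    oracle <- mean(outliers) / mean(controls)
    expect_equal(relative_risk(a, b, c, d)$rr, oracle, tolerance = 1e-12)
  }
})

test_that("enrichment comparison is antisymmetric and matches hand arithmetic", {
  r1 <- relative_risk(30, 70, 100, 900)   # log RR = log 3 = 1.0986
  r2 <- relative_risk(20, 180, 100, 900)  # RR = 1
  cmp <- compare_relative_risks(r1, r2)
  expect_equal(cmp$t, (log(3) - log(1)) /
                 sqrt(r1$se_log^2 + r2$se_log^2), tolerance = 1e-10)
  expect_equal(cmp$df, 1100 + 1200 - 2)
  # identical tables: t = 0, p = 1
  same <- compare_relative_risks(r1, relative_risk(30, 70, 100, 900))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  # swapping flips the sign, not the p-value
  rev <- compare_relative_risks(r2, r1)
  expect_equal(rev$t, -cmp$t)
  expect_equal(rev$p_value, cmp$p_value)
  r0 <- relative_risk(0, 50, 10, 90)
  expect_error(compare_relative_risks(r1, r0), "standard error")
})

test_that("ancestry matching picks the nearest control with deterministic ties", {
  pcs <- rbind(O1 = c(0, 0), O2 = c(4, 4),
               C1 = c(0, 0), C2 = c(3, 4), C3 = c(5, 4))
  m <- ancestry_matched_controls(c("O1", "O2"), c("C3", "C1", "C2"), pcs)
  expect_equal(m$control[m$outlier == "O1"], "C1")
  expect_equal(m$distance[m$outlier == "O1"], 0)
  # O2 at (4,4): C2 and C3 both at distance 1 -> lexicographically smaller
  expect_equal(m$control[m$outlier == "O2"], "C2")
  # controls are reusable across outliers
  m2 <- ancestry_matched_controls(c("O1", "O1"), c("C1"), pcs)
  expect_equal(m2$control, c("C1", "C1"))
  expect_error(ancestry_matched_controls("O9", "C1", pcs), "missing PC")
  expect_error(ancestry_matched_controls("O1", character(0), pcs), "empty")
})

test_that("the one-sided enrichment test is calibrated and detects planted risk", {
  set.seed(202)
  # type-I error under no association (modest replicate count here; the
  # full-scale calibration lives in the acceptance suite)
  rejections <- replicate(400, {
    a <- rbinom(1, 150, 0.2); c <- rbinom(1, 850, 0.2)
    if (a == 0 || c == 0) return(FALSE)
    relative_risk(a, 150 - a, c, 850 - c)$p_value < 0.05
  })
  expect_lte(mean(rejections), 0.08)
  # planted relative risk of 3 is recovered
  rr_hat <- replicate(50, {
    a <- rbinom(1, 200, 0.3); c <- rbinom(1, 800, 0.1)
    relative_risk(a, 200 - a, c, 800 - c)$rr
  })
  expect_true(median(rr_hat) > 2.5 && median(rr_hat) < 3.5)
})
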