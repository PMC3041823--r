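test_that("robust_center_scale matches hand values and is consistent", {
  rs <- robust_center_scale(c(1, 2, 3, 4, 5))
  expect_equal(rs$med, 3)
  expect_equal(rs$mad, 1.4826)

  expect_equal(robust_center_scale(rep(7.5, 3)),
               list(med = 7.5, mad = 0))
  expect_equal(robust_center_scale(c(1, NA, 2, 3))$med, 2)
  expect_error(robust_center_scale(c(NA_real_, NA_real_)), "non-missing")

  # consistency: on a large standard-normal sample the scaled MAD
  # approaches the true sd of 1
  set.seed(42)
  expect_equal(robust_center_scale(rnorm(1e5))$mad, 1, tolerance = 0.02)
})

test_that("outlier_cutoff is the type-7 q75 + IQR fence", {
  oc <- outlier_cutoff(1:8)
  expect_s3_class(oc, "OutlierCutoff")
  expect_equal(oc$b, 9.75)  # q75 = 6.25, q25 = 2.75
  expect_equal(oc$source, "all")
  expect_equal(outlier_cutoff(rep(3.2, 5))$b, 3.2)
  expect_equal(outlier_cutoff(c(1:8, NA))$b, 9.75)
  expect_error(outlier_cutoff(NA_real_), "non-missing")

  # N(0,1) limit: q75 + IQR -> qnorm(.75) + 2 * qnorm(.75) = 2.0235
  set.seed(7)
  expect_equal(outlier_cutoff(rnorm(1e5))$b, 3 * qnorm(0.75),
               tolerance = 0.02)
})

test_that("t_statistic matches the pooled two-sample t", {
  f <- make_xg(rbind(c(1, 2, 3)), rbind(c(4, 6, 8)))
  # pooled variance (2 + 8) / 4 = 2.5
  expect_equal(unname(t_statistic(f$x, f$groups)),
               4 / (sqrt(2.5) * sqrt(2 / 3)), tolerance = 1e-12)

  # reference oracle: stats::t.test with equal variances, disease - normal
  set.seed(11)
  for (i in 1:20) {
    v1 <- rnorm(sample(2:9, 1)); v2 <- rnorm(sample(2:9, 1))
    f <- make_xg(rbind(v1), rbind(v2))
    expect_equal(unname(t_statistic(f$x, f$groups)),
                 unname(t.test(v2, v1, var.equal = TRUE)$statistic),
                 tolerance = 1e-10)
  }

  # identical groups -> 0; swapped labels negate; zero pooled sd -> NA
  f <- make_xg(rbind(c(1, 2, 3)), rbind(c(1, 2, 3)))
  expect_equal(unname(t_statistic(f$x, f$groups)), 0)
  f2 <- make_xg(rbind(c(1, 1)), rbind(c(1, 1, 1)))
  expect_true(is.na(t_statistic(f2$x, f2$groups)))
})

test_that("copa_score standardizes by all-sample median/MAD", {
  f <- make_xg(rbind(c(1, 2, 3, 4, 5)), rbind(c(1, 2, 3, 4, 20)))
  # all-sample med 3, mad 1.4826; type-7 90th pct of standardized disease
  z <- (c(1, 2, 3, 4, 20) - 3) / 1.4826
  want <- z[4] + 0.6 * (z[5] - z[4])
  expect_equal(unname(copa_score(f$x, f$groups, r = 90)), want,
               tolerance = 1e-12)
  expect_equal(want, 7.1496, tolerance = 1e-4)

  # disease values all at the overall median -> 0
  f0 <- make_xg(rbind(c(1, 2, 3, 4, 5)), rbind(c(3, 3, 3)))
  expect_equal(unname(copa_score(f0$x, f0$groups)), 0)

  # a huge NORMAL value cannot push COPA above the standardized disease max
  fh <- make_xg(rbind(c(1, 2, 3, 1000)), rbind(c(2, 3, 4, 5)))
  med <- median(c(1, 2, 3, 1000, 2, 3, 4, 5))
  madv <- mad(c(1, 2, 3, 1000, 2, 3, 4, 5), constant = 1.4826)
  expect_lte(copa_score(fh$x, fh$groups, 95), (5 - med) / madv)

  # degenerate scale -> NA, invalid r rejected
  fc <- make_xg(rbind(rep(2, 4)), rbind(c(2, 2, 2, 9)))
  expect_true(is.na(copa_score(fc$x, fc$groups)))
  expect_error(copa_score(f$x, f$groups, r = 80), "75, 90 or 95")
})

test_that("os_score sums standardized disease values above the fence", {
  # chained through the cutoff and robust-scale oracles
  v1 <- c(2, 3, 4, 5); v2 <- c(2, 3, 4, 15)
  f <- make_xg(rbind(v1), rbind(v2))
  b <- oracle_cutoff(c(v1, v2))
  expect_gt(15, b)
  rs <- robust_center_scale(c(v1, v2))
  expect_equal(unname(os_score(f$x, f$groups)), (15 - rs$med) / rs$mad,
               tolerance = 1e-12)

  # no disease sample above the fence -> 0, even with an extreme normal
  fn <- make_xg(rbind(c(1, 2, 3, 50)), rbind(c(1, 2, 3, 4)))
  expect_equal(unname(os_score(fn$x, fn$groups)), 0)
})

test_that("ort_score centres per group and judges outliers from normals", {
  v1 <- c(1, 2, 3, 4, 5); v2 <- c(1, 2, 3, 4, 20)
  f <- make_xg(rbind(v1), rbind(v2))
  # b_normal = q75 + IQR of normals = 4 + 2 = 6 (type 7); R = {20};
  # pooled centred MAD = 1.4826 * median(2,1,0,1,2, 2,1,0,1,17)
  expect_equal(unname(ort_score(f$x, f$groups)), (20 - 3) / 1.4826,
               tolerance = 1e-12)

  # all disease below the normal fence -> 0
  f0 <- make_xg(rbind(c(1, 2, 3, 4, 5)), rbind(c(1, 2, 3)))
  expect_equal(unname(ort_score(f0$x, f0$groups)), 0)

  # scale equivariance: multiplying by c > 0 leaves ORT unchanged
  f2 <- make_xg(rbind(2 * v1), rbind(2 * v2))
  expect_equal(ort_score(f2$x, f2$groups), ort_score(f$x, f$groups),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("gti_group_score weighs outlier proportion by relative gap", {
  expect_equal(gti_group_score(c(1, 1, 1, 1, 9), 2), 70)
  expect_equal(gti_group_score(c(1, 2, 3), 5), 0)
  # strict inequality: values exactly at b never count
  expect_equal(gti_group_score(c(2, 2, 2), 2), 0)
  expect_equal(gti_group_score(c(1, NA, 9), outlier_cutoff(c(1, 9))),
               gti_group_score(c(1, 9), outlier_cutoff(c(1, 9))))
  expect_warning(res <- gti_group_score(c(1, 2), -1), "positive")
  expect_true(is.na(res))
  expect_error(gti_group_score(NA_real_, 2), "non-missing")
})

test_that("gti_score is the disease-minus-normal group index", {
  f <- make_xg(rbind(c(1, 1, 1, 1)), rbind(c(1, 1, 1, 9)))
  # b = 1 from all 8 values; disease outliers {9}
  expect_equal(unname(gti_score(f$x, f$groups)), 200)

  # no sample above b in either group -> 0
  f0 <- make_xg(rbind(c(1, 2, 3)), rbind(c(2, 3, 4)))
  b <- oracle_cutoff(c(1, 2, 3, 2, 3, 4))
  expect_gte(b, 4)
  expect_equal(unname(gti_score(f0$x, f0$groups)), 0)

  # label swap negates
  fswap <- make_xg(rbind(c(1, 1, 1, 9)), rbind(c(1, 1, 1, 1)))
  expect_equal(unname(gti_score(fswap$x, fswap$groups)), -200)

  # non-positive cut-off -> NA with a reason
  fneg <- make_xg(rbind(c(-5, -4, -3)), rbind(c(-5, -4, -3)))
  expect_lt(oracle_cutoff(c(-5, -4, -3, -5, -4, -3)), 0)
  sneg <- gti_score(fneg$x, fneg$groups)
  expect_true(is.na(sneg))
  expect_match(attr(sneg, "reason")[["g1"]], "b<=0")
})

test_that("score_all assembles per-method scores and deterministic ranks", {
  set.seed(301)
  f <- random_fixture(n_genes = 10, n1 = 6, n2 = 6)
  st <- score_all(f$x, f$groups)
  expect_s3_class(st, "ScoreTable")
  lab <- unname(f$groups$labels)
  for (m in c("gti", "copa", "os", "ort", "t")) {
    want <- vapply(seq_len(10), function(j)
      oracle_score(m, f$x[j, lab == 1], f$x[j, lab == 2]), 0)
    expect_equal(st[[paste0("score_", m)]], want, tolerance = 1e-10)
    r <- st[[paste0("rank_", m)]]
    expect_setequal(r[!is.na(r)], seq_len(sum(!is.na(r))))
    # rank 1 is the largest defined score
    expect_equal(which(r == 1L), which.max(st[[paste0("score_", m)]]))
  }

  # a missing cell restricts that gene to its informative samples
  x <- rbind(g1 = c(1, 2, 3, 4, 10, 20), g2 = c(1, 2, 3, 4, 10, 20))
  x[2, 1] <- NA
  xm <- expression_matrix(x, sample_ids = paste0("s", 1:6))
  g <- group_assignment(c(1, 1, 1, 2, 2, 2), sample_ids = colnames(xm))
  st2 <- score_all(xm, g, methods = "t")
  expect_equal(st2$score_t[2],
               oracle_t(c(2, 3), c(4, 10, 20)), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(st2$score_t[1], st2$score_t[2])))

  # ties broken lexicographically by gene id
  xt <- expression_matrix(rbind(zz = c(1, 2, 5, 6), aa = c(1, 2, 5, 6)),
                          sample_ids = paste0("s", 1:4))
  gt <- group_assignment(c(1, 1, 2, 2), sample_ids = colnames(xt))
  stt <- score_all(xt, gt, methods = "t")
  expect_equal(stt$rank_t, c(2L, 1L))  # aa before zz at equal scores

  # undefined genes flagged and ranked last (NA rank)
  xu <- expression_matrix(rbind(g1 = c(1, 2, 5, 6), g2 = c(3, 3, 3, 3)),
                          sample_ids = paste0("s", 1:4))
  stu <- score_all(xu, group_assignment(c(1, 1, 2, 2),
                                        sample_ids = colnames(xu)),
                   methods = c("t", "os"))
  expect_true(is.na(stu$score_t[2]))
  expect_true(is.na(stu$rank_t[2]))
  expect_match(stu$flags[2], "t")

  expect_error(score_all(f$x, f$groups, methods = character(0)),
               "no methods")
  expect_error(score_all(f$x, f$groups, methods = "copa2"), "unknown")
})
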