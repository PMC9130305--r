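test_that("two-set fractions obey inclusion-exclusion and sum to the combined R2_adj", {
  for (s in 1:10) {
    cl <- random_climate(40, seed = 100 + s)
    set.seed(200 + s)
    y <- drop(scale(0.5 * cl$bio1 + 0.3 * cl$bio12 + rnorm(40, 0, 2)))
    p <- partition_two(y, c("bio1", "bio6"), c("bio12", "bio15"), cl)
    r <- attr(p, "R2_adj")
    expect_equal(p$value[p$fraction == "unique_A"], unname(r["AB"] - r["B"]), tolerance = 1e-12)
    expect_equal(p$value[p$fraction == "unique_B"], unname(r["AB"] - r["A"]), tolerance = 1e-12)
    expect_equal(p$value[p$fraction == "shared"], unname(r["A"] + r["B"] - r["AB"]), tolerance = 1e-12)
    expect_equal(sum(p$value[p$fraction != "unexplained"]), unname(r["AB"]), tolerance = 1e-10)
    # matches an oracle that fits every sub-model from scratch
    ref <- oracle_partition_two(y, c("bio1", "bio6"), c("bio12", "bio15"), cl)
    expect_equal(p$value, unname(ref), tolerance = 1e-8)
  }
})

test_that("signal confined to one set leaves the other set's unique fraction near zero", {
  cl <- random_climate(200, seed = 7)   # independent columns by construction
  set.seed(8)
  y <- drop(scale(cl$bio1 + 0.5 * cl$bio1^2 / sd(cl$bio1)^2 + rnorm(200, 0, 0.5)))
  p <- partition_two(y, "bio1", "bio12", cl)
  expect_lt(abs(p$value[p$fraction == "unique_B"]), 0.02)
  expect_lt(abs(p$value[p$fraction == "shared"]), 0.02)
  expect_gt(p$value[p$fraction == "unique_A"], 0.5)
})

test_that("three-set fractions sum exactly and localize orthogonal signal", {
  for (s in 1:10) {
    cl <- random_climate(40, seed = 300 + s)
    set.seed(400 + s)
    y <- drop(scale(rnorm(40)))
    p <- partition_three(y, c("bio1", "bio12"), c("bio6", "bio14"),
                         c("bio4", "bio15"), cl)
    r <- attr(p, "R2_adj")
    expect_equal(sum(p$value[p$fraction != "unexplained"]), unname(r["ABC"]),
                 tolerance = 1e-10)
    expect_equal(sum(p$value), 1, tolerance = 1e-10)
  }
  # three exactly orthogonal single-variable sets contributing equally:
  # shared fractions vanish up to the adjusted-R2 correction
  set.seed(5)
  Q <- qr.Q(qr(scale(matrix(rnorm(300 * 3), 300), scale = FALSE)))
  cl <- random_climate(300, seed = 5)
  cl$bio1 <- Q[, 1]; cl$bio6 <- Q[, 2]; cl$bio4 <- Q[, 3]
  set.seed(6)
  # noise at 30% of each (unit-norm, mean-zero) component's scale
  y <- drop(scale(Q[, 1] + Q[, 2] + Q[, 3] + rnorm(300, 0, 0.3 / sqrt(299))))
  p <- partition_three(y, "bio1", "bio6", "bio4", cl, order = 1)
  uq <- p$value[grepl("^unique_", p$fraction)]
  expect_true(all(uq > 0.25))
  expect_lt(max(uq) - min(uq), 0.05)
  shared <- p$value[grepl("^shared_", p$fraction)]
  expect_true(all(abs(shared) < 0.01))
})

test_that("merging two sets reduces the three-set partition to the two-set one", {
  cl <- random_climate(50, seed = 11)
  set.seed(12)
  y <- drop(scale(cl$bio1 - 0.2 * cl$bio12 + rnorm(50, 2)))
  p3 <- partition_three(y, "bio1", "bio12", "bio15", cl)
  p2 <- partition_two(y, "bio1", c("bio12", "bio15"), cl)
  # unique_A in the merged two-set partition equals fraction a
  expect_equal(p2$value[p2$fraction == "unique_A"],
               p3$value[p3$fraction == "unique_A"], tolerance = 1e-10)
  # unique_B(two-set) = b + c + e (everything not touching A)
  expect_equal(p2$value[p2$fraction == "unique_B"],
               sum(p3$value[p3$fraction %in% c("unique_B", "unique_C", "shared_BC")]),
               tolerance = 1e-10)
})

test_that("disjointness of predictor sets is enforced", {
  cl <- random_climate(30, seed = 1)
  y <- drop(scale(rnorm(30)))
  expect_error(partition_two(y, c("bio1", "bio4"), c("bio4", "bio12"), cl), "disjoint")
  expect_error(partition_three(y, "bio1", "bio1", "bio4", cl), "disjoint")
})

test_that("fractions agree with vegan's variance partitioning", {
  skip_if_not_installed("vegan")
  cl <- random_climate(60, seed = 21)
  set.seed(22)
  y <- drop(scale(scale(cl$bio1) + 0.4 * scale(cl$bio12) + rnorm(60, 0, 1)))
  Xa <- build_design(cl, c("bio1", "bio1_sq"))[, 1:2]
  Xb <- build_design(cl, c("bio12", "bio12_sq"))[, 1:2]
  vp <- vegan::varpart(y, Xa, Xb)
  ours <- partition_two(y, "bio1", "bio12", cl)
  ref <- vp$part$indfract$Adj.R.squared  # [a]=X1|X2, [b]=X2|X1, [c]=shared, [d]
  expect_equal(ours$value[ours$fraction == "unique_A"], ref[1], tolerance = 1e-6)
  expect_equal(ours$value[ours$fraction == "unique_B"], ref[2], tolerance = 1e-6)
  expect_equal(ours$value[ours$fraction == "shared"], ref[3], tolerance = 1e-6)
  expect_equal(ours$value[ours$fraction == "unexplained"], ref[4], tolerance = 1e-6)
})
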