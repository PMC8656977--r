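test_that("single-DMU and single-ratio slices solve in closed form", {
  solo <- toy_panel(matrix(5), matrix(3))
  r <- solve_crs_input(solo, 1)
  expect_equal(r$theta, 1)
  expect_equal(unname(r$lambda[r$lambda > 1e-9]), 1, tolerance = 1e-9)
  expect_equal(solve_vrs_input(solo, 1)$theta, 1)

  # A(x=2,y=2), B(x=4,y=2): B contracts to A's ray under CRS and to A under VRS
  ab <- toy_panel(matrix(c(2, 4)), matrix(c(2, 2)), dmu = c("A", "B"))
  expect_equal(solve_crs_input(ab, "B")$theta, 0.5, tolerance = 1e-9)
  rv <- solve_vrs_input(ab, "B")
  expect_equal(rv$theta, 0.5, tolerance = 1e-9)
  expect_equal(rv$peers, "A")

  set.seed(21)
  for (k in 1:5) {
    n <- sample(3:10, 1)
    x <- runif(n, 1, 9); y <- runif(n, 1, 9)
    p <- toy_panel(matrix(x), matrix(y))
    th <- vapply(seq_len(n), function(j) solve_crs_input(p, j)$theta, numeric(1))
    expect_equal(th, ratio_oracle(x, y), tolerance = 1e-6)
  }
})

test_that("LP scores match basic-solution enumeration on small instances", {
  set.seed(33)
  for (k in 1:6) {
    n <- sample(4:6, 1)
    X <- matrix(runif(n * 2, 1, 10), n)
    Y <- matrix(runif(n, 1, 10), n)
    p <- toy_panel(X, Y)
    for (j in seq_len(n)) {
      expect_equal(solve_crs_input(p, j)$theta, enum_dea(X, Y, X[j, ], Y[j, ]),
                   tolerance = 1e-7)
      expect_equal(solve_vrs_input(p, j)$theta,
                   enum_dea(X, Y, X[j, ], Y[j, ], vrs = TRUE), tolerance = 1e-7)
    }
  }
})

test_that("scale efficiency decomposes printed scores and guards its domain", {
  expect_equal(scale_efficiency(1, 1), 1)
  expect_equal(round(scale_efficiency(0.5032, 0.6916), 4), 0.7276)
  expect_equal(round(scale_efficiency(0.5978, 1.0000), 4), 0.5978)
  expect_error(scale_efficiency(0.5, 0), "positive")
  expect_error(scale_efficiency(0.9, 0.5), "exceeds")
})

test_that("returns-to-scale classification follows the intensity-weight sum", {
  expect_equal(classify_rts(1.066), "decreasing")
  expect_equal(classify_rts(0.757), "increasing")
  expect_equal(classify_rts(1.000), "constant")
  expect_equal(classify_rts(c(1 + 1e-8, 1 - 1e-8)), c("constant", "constant"))
  expect_error(classify_rts(-0.1))
})

test_that("reference sets filter and order by intensity weight", {
  lam <- c(H1 = 0.6, H29 = 0.2, H5 = 1e-9)
  expect_equal(reference_set(lam), c("H1", "H29"))
  p <- generate_panel(synthetic_config(n_dmus = 12, n_years = 1, seed = 5))$panel
  eff <- dea_evaluate(p)
  for (i in seq_len(nrow(eff$results))) {
    peers <- strsplit(eff$results$peers[i], ";")[[1]]
    # peer consistency: every peer is itself CRS-efficient in the slice
    for (pe in peers)
      expect_equal(eff$results$crs[eff$results$dmu == pe], 1, tolerance = 1e-7)
  }
  for (d in eff$results$dmu[eff$results$crs > 1 - 1e-9])
    expect_equal(eff$results$peers[eff$results$dmu == d], d)
})

test_that("units invariance, monotonicity and VRS nesting hold", {
  set.seed(44)
  X <- matrix(rlnorm(8 * 3, 5, 0.5), 8)
  Y <- matrix(rlnorm(8 * 2, 8, 0.5), 8)
  p <- toy_panel(X, Y)
  base <- dea_evaluate(p)

  # multiply one input column and one output column by constants
  X2 <- X; X2[, 2] <- X2[, 2] * 37.5
  Y2 <- Y; Y2[, 1] <- Y2[, 1] * 0.004
  p2 <- toy_panel(X2, Y2)
  r2 <- dea_evaluate(p2)
  expect_lt(max(abs(base$results$crs - r2$results$crs)), 1e-8)
  expect_lt(max(abs(base$results$vrs - r2$results$vrs)), 1e-8)

  # adding a DMU never raises an incumbent's score
  Xp <- rbind(X, rlnorm(3, 5, 0.5)); Yp <- rbind(Y, rlnorm(2, 8, 0.5))
  rp <- dea_evaluate(toy_panel(Xp, Yp))
  expect_true(all(rp$results$crs[1:8] <= base$results$crs + 1e-8))

  expect_true(all(base$results$vrs >= base$results$crs - 1e-8))
  expect_true(all(base$results$se <= 1 + 1e-12))
})

test_that("a radially inflated clone of an efficient DMU scores exactly k", {
  g <- generate_panel(synthetic_config(n_dmus = 10, n_years = 1, seed = 8))
  p <- g$panel
  eff_dmu <- g$truth$dmu[g$truth$efficient][1]
  row <- as.data.frame(p[p$dmu == eff_dmu, ])
  for (k in c(0.3, 0.62, 0.95)) {
    clone <- row
    clone$dmu <- "CLONE"
    clone[, attr(p, "inputs")] <- clone[, attr(p, "inputs")] / k
    pc <- dmu_panel(rbind(as.data.frame(p), clone))
    expect_equal(solve_crs_input(pc, "CLONE")$theta, k, tolerance = 1e-6)
  }
})

test_that("evaluate_all recovers constructed efficiencies and degenerate slices", {
  ident <- toy_panel(matrix(rep(c(4, 7), each = 6), 6),
                     matrix(rep(c(3, 9), each = 6), 6))
  ri <- dea_evaluate(ident)
  expect_equal(ri$results$crs, rep(1, 6))
  expect_equal(ri$summary$mean[ri$summary$score == "crs"], 1)

  g <- generate_panel(synthetic_config(seed = 1))
  ev <- dea_evaluate(g$panel, year = 2017)
  tr <- g$truth[g$truth$year == 2017, ]
  m <- merge(ev$results, tr, by = "dmu")
  expect_lt(max(abs(m$crs - m$theta_true)), 1e-6)

  all_eff <- generate_panel(synthetic_config(n_dmus = 8, n_years = 1,
                                             frac_efficient = 1, seed = 3))
  expect_equal(dea_evaluate(all_eff$panel)$results$crs, rep(1, 8))
})

test_that("size-group means reproduce the printed group table", {
  gm <- size_group_means(load_fixture("scores_2019"), load_fixture("factors_2019"))
  expect_equal(gm$n, c(8, 10, 12, 9))
  expect_equal(round(gm$mean_crs[gm$group == "very_large"], 4), 0.6265)
  expect_equal(round(gm$mean_crs[gm$group == "large"], 4), 0.7713)
  expect_equal(gm$mean_crs[gm$group == "medium"], 0.7470, tolerance = 1e-4)
  expect_equal(gm$mean_se, c(0.9510, 0.9581, 0.9609, 0.8224), tolerance = 1e-4)
})

test_that("slack-maximizing second phase keeps the optimal score", {
  set.seed(55)
  X <- matrix(rlnorm(7 * 2, 4, 0.4), 7)
  Y <- matrix(rlnorm(7 * 2, 6, 0.4), 7)
  p <- toy_panel(X, Y)
  for (j in 1:7) {
    a <- solve_crs_input(p, j)
    b <- solve_crs_input(p, j, slack_max = TRUE)
    expect_equal(a$theta, b$theta, tolerance = 1e-8)
    expect_true(all(b$lambda >= -1e-9))
  }
})
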