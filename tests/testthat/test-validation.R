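test_that("RSD is the sample relative standard deviation and scale-invariant", {
  expect_equal(rsd(c(1, 1, 1)), 0)
  expect_equal(round(rsd(c(3.80, 3.85, 3.81, 3.73, 3.82)), 2), 1.17)
  expect_equal(rsd(c(8, 12)), sd(c(8, 12)) / 10 * 100)
  expect_equal(round(rsd(c(8, 12)), 2), 28.28)
  for (s in 1:10) {
    set.seed(s)
    v <- runif(6, 1, 10); lam <- runif(1, 0.1, 100)
    expect_equal(rsd(lam * v), rsd(v))
  }
  expect_error(rsd(5), ">= 2")
  expect_error(rsd(c(-1, 1)), "mean is zero")
})

test_that("recovery rate measures the found fraction of the spike", {
  expect_equal(recovery_rate(50, 100, 150), 100)
  expect_equal(recovery_rate(50, 100, 148), 98)
  expect_error(recovery_rate(1, 0, 2), "added")
  # exact 100% under the no-loss model for any spike size
  for (s in 1:10) {
    set.seed(s)
    orig <- runif(1, 1, 100); added <- runif(1, 0.1, 500)
    expect_equal(recovery_rate(orig, added, orig + added), 100)
  }
  # 1% measurement noise keeps 6-replicate mean recovery in [97, 103]
  means <- vapply(1:30, function(s) {
    set.seed(s)
    found <- 150 * (1 + rnorm(6, sd = 0.01))
    mean(recovery_rate(50, 100, found))
  }, numeric(1))
  expect_true(all(means >= 97 & means <= 103))
})

test_that("the precision suite flags, passes, and skips correctly", {
  out <- run_precision_suite(list(a = rep(5, 6), b = c(10, 10.1, 9.9,
                                                       10, 10, 10.05)))
  expect_equal(out$rsd_percent[out$analyte == "a"], 0)
  expect_true(all(out$pass))
  miss <- run_precision_suite(list(a = rep(5, 6), b = NULL))
  expect_true(is.na(miss$pass[miss$analyte == "b"]))
  bad <- run_precision_suite(list(a = c(1, 2)), threshold = 2)
  expect_false(bad$pass)
  # 1% relative noise, 6 replicates: median RSD sits in [0.4, 1.8]%
  meds <- vapply(1:20, function(s) {
    set.seed(s)
    out <- run_precision_suite(lapply(1:6, function(i)
      100 * (1 + rnorm(6, sd = 0.01))))
    median(out$rsd_percent)
  }, numeric(1))
  expect_gte(median(meds), 0.4)
  expect_lte(median(meds), 1.8)
})

test_that("RCF robustness summarises per-axis RSD and honours thresholds", {
  grid <- expand.grid(condition = c("c1", "c2", "c3"),
                      analyte = c("a", "b"))
  grid$axis <- "flow_rate"
  grid$rcf <- 2.5
  out <- rcf_robustness(grid)
  expect_equal(out$max_rsd_percent, 0)
  expect_true(all(out$summary$pass))
  # a 10% inflated condition must raise the fail flag
  grid2 <- grid
  grid2$rcf[grid2$condition == "c3" & grid2$analyte == "a"] <- 2.75
  out2 <- rcf_robustness(grid2)
  expect_false(out2$summary$pass[out2$summary$analyte == "a"])
  expect_true(out2$summary$pass[out2$summary$analyte == "b"])
  # single-condition axes are skipped with a warning
  grid3 <- rbind(grid, data.frame(condition = "only", analyte = c("a", "b"),
                                  axis = "temperature", rcf = 2.5))
  expect_warning(rcf_robustness(grid3), "skipped")
})

test_that("1% joint area perturbations keep RCF robustness under 2.27%", {
  # condition effects act jointly on all areas (with a small analyte-
  # specific residual), so the RCF ratio stays well inside the threshold
  axes <- list(instrument = 2, column = 3, flow_rate = 3, temperature = 3)
  ok <- vapply(1:100, function(s) {
    set.seed(s)
    grid <- do.call(rbind, lapply(names(axes), function(ax) {
      do.call(rbind, lapply(seq_len(axes[[ax]]), function(ci) {
        common <- 1 + rnorm(1, sd = 0.01)
        pert <- common * (1 + rnorm(5, sd = 0.0025))
        data.frame(axis = ax, condition = paste0(ax, ci),
                   analyte = paste0("an", 1:5),
                   rcf = c(3.8, 3.0, 0.39, 2.3, 2.4) *
                     (1 + rnorm(5, sd = 0.0025)) / pert * common)
      }))
    }))
    rcf_robustness(grid)$max_rsd_percent < 2.27
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("localization method comparison identifies the drift structure", {
  base <- c(ref = 10, a = 6, b = 25)
  mk_grid <- function(transform) do.call(rbind, lapply(1:4, function(i)
    data.frame(condition = paste0("c", i), analyte = names(base),
               retention_time = transform(base, i))))
  # pure clock-scale drift: the ratio is exactly invariant
  scales <- c(1, 1.05, 0.95, 1.1)
  g1 <- mk_grid(function(rt, i) rt * scales[i])
  out1 <- compare_localization_methods(g1, "ref")
  expect_true(all(out1$rsd_ratio_percent < 1e-10))
  expect_true(all(out1$rsd_difference_percent > 0))
  expect_true(all(out1$winner == "relative_retention"))
  # pure additive shift: the difference is exactly invariant
  shifts <- c(0, 0.3, -0.2, 0.5)
  g2 <- mk_grid(function(rt, i) rt + shifts[i])
  out2 <- compare_localization_methods(g2, "ref")
  expect_true(all(out2$rsd_difference_percent < 1e-10))
  expect_true(all(out2$winner == "retention_difference"))
  expect_error(compare_localization_methods(g2[g2$analyte != "ref", ],
                                            "ref"), "missing")
})

test_that("under mixed drift the ratio method wins in at least 90% of runs", {
  base <- c(ref = 10, a = 6, b = 25)
  wins <- vapply(1:100, function(s) {
    set.seed(s)
    g <- do.call(rbind, lapply(1:5, function(i) {
      sc <- 1 + rnorm(1, sd = 0.01)
      off <- rnorm(1, sd = 0.02)
      data.frame(condition = paste0("c", i), analyte = names(base),
                 retention_time = base * sc + off)
    }))
    out <- compare_localization_methods(g, "ref")
    all(out$rsd_ratio_percent < out$rsd_difference_percent)
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})
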