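test_that("ICERs classify the cost-effectiveness plane correctly", {
  r <- icer(100, 0.05)
  expect_equal(r$ratio, 2000)
  expect_equal(r$quadrant, "NE")
  expect_equal(r$classification, "ratio")
  d <- icer(-128, 0.0262)
  expect_lt(d$ratio, 0)
  expect_equal(d$classification, "dominant")
  expect_equal(d$quadrant, "SE")
  expect_equal(icer(0, 0.05)$ratio, 0)
  expect_equal(icer(0, 0.05)$classification, "dominant")
  expect_equal(icer(50, -0.01)$classification, "dominated")
  nr <- icer(50, 0)
  expect_true(is.na(nr$ratio))
  expect_equal(nr$classification, "no-ratio")
})

test_that("net monetary benefit obeys its identities", {
  expect_equal(nmb(130, 0.05, 0), -130)
  expect_equal(nmb(100, 0.05, 100 / 0.05), 0)  # break-even
  expect_equal(nmb(-128, 0.03, 20000), 728)
  expect_error(nmb(1, 1, -5), "nonnegative")
})

test_that("zero-variance data make every joint replicate the point estimate", {
  dat <- data.frame(arm = rep(c("intervention", "control"), each = 6),
                    cost = rep(c(100, 150), each = 6),
                    qaly = rep(c(0.4, 0.3), each = 6))
  reps <- bootstrap_joint(dat, B = 50, seed = 3)
  expect_equal(reps$replicates$delta_cost, rep(reps$delta_cost, 50))
  expect_equal(reps$replicates$delta_qaly, rep(reps$delta_qaly, 50))
  expect_equal(reps$delta_cost, -50)
  expect_equal(reps$delta_qaly, 0.1)
})

test_that("joint bootstrap is consistent for means and correlation", {
  set.seed(601)
  n <- 60
  sig <- matrix(c(400^2, 0.5 * 400 * 0.05, 0.5 * 400 * 0.05, 0.05^2), 2)
  draw <- function(mu) MASS::mvrnorm(n, mu, sig)
  xi <- draw(c(1000, 0.40)); xc <- draw(c(1100, 0.36))
  dat <- data.frame(arm = rep(c("intervention", "control"), each = n),
                    cost = c(xi[, 1], xc[, 1]), qaly = c(xi[, 2], xc[, 2]))
  reps <- bootstrap_joint(dat, B = 2000, seed = 4)
  # replicate means centre on the sample point estimates
  se_c <- sd(reps$replicates$delta_cost) / sqrt(2000)
  se_q <- sd(reps$replicates$delta_qaly) / sqrt(2000)
  expect_lt(abs(mean(reps$replicates$delta_cost) - reps$delta_cost), 3 * se_c)
  expect_lt(abs(mean(reps$replicates$delta_qaly) - reps$delta_qaly), 3 * se_q)
  # the replicate (cost, QALY) correlation tracks the plug-in value:
  # both arms share the within-person correlation of the data
  plug_in <- (cov(xi[, 1], xi[, 2]) / n + cov(xc[, 1], xc[, 2]) / n) /
    sqrt((var(xi[, 1]) / n + var(xc[, 1]) / n) *
         (var(xi[, 2]) / n + var(xc[, 2]) / n))
  expect_lt(abs(cor(reps$replicates$delta_cost,
                    reps$replicates$delta_qaly) - plug_in), 0.1)
})

test_that("acceptability curves hit their endpoint identities", {
  reps <- data.frame(delta_cost = c(-10, -5, 20, 35, -2),
                     delta_qaly = c(0.01, -0.02, 0.03, -0.01, 0.02))
  grid <- c(0, 500, 20000, 1e9)
  curve <- ceac(reps, grid)
  expect_equal(curve$p_intervention[1], mean(reps$delta_cost < 0))
  expect_equal(curve$p_intervention[length(grid)],
               mean(reps$delta_qaly > 0))
  expect_equal(curve$p_intervention + curve$p_control,
               rep(1, length(grid)))
  # full dominance: probability one everywhere
  dom <- data.frame(delta_cost = c(-3, -8), delta_qaly = c(0.01, 0.04))
  expect_true(all(ceac(dom, grid)$p_intervention == 1))
  # nondecreasing in lambda when every replicate gains QALYs
  pos <- data.frame(delta_cost = rnorm(200, 50, 100),
                    delta_qaly = abs(rnorm(200, 0.02, 0.02)))
  cv <- ceac(pos, seq(0, 50000, by = 1000))
  expect_true(all(diff(cv$p_intervention) >= 0))
})

test_that("the curve matches the closed-form bivariate-normal probability", {
  set.seed(602)
  mu <- c(cost = -100, qaly = 0.025)
  sig <- matrix(c(300^2, -0.3 * 300 * 0.025, -0.3 * 300 * 0.025, 0.025^2), 2)
  reps <- as.data.frame(MASS::mvrnorm(2000, mu, sig))
  names(reps) <- c("delta_cost", "delta_qaly")
  grid <- seq(0, 100000, by = 10000)
  curve <- ceac(reps, grid)
  analytic <- vapply(grid, function(l) {
    s <- sqrt(sig[1, 1] - 2 * l * sig[1, 2] + l^2 * sig[2, 2])
    pnorm((l * mu[2] - mu[1]) / s)
  }, numeric(1))
  mc_tol <- 3 * sqrt(pmax(analytic * (1 - analytic), 0.25 / 2000) / 2000)
  expect_true(all(abs(curve$p_intervention - analytic) <= mc_tol + 0.01))
})

test_that("seeded CEAC output is byte-stable", {
  ref <- ce_reference_cohort(seed = 9)
  dat <- data.frame(arm = ref$arm, cost = ref$cost_healthcare,
                    qaly = ref$qaly)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_ceac_csv(ceac(bootstrap_joint(dat, B = 500, seed = 10)), f1)
  write_ceac_csv(ceac(bootstrap_joint(dat, B = 500, seed = 10)), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("plane summaries partition replicates and match the curve", {
  set.seed(603)
  reps <- data.frame(delta_cost = rnorm(500, -100, 300),
                     delta_qaly = rnorm(500, 0.03, 0.03))
  ps <- ce_plane_summary(reps, threshold = 20000)
  expect_equal(sum(ps$quadrants), 1)
  expect_equal(ps$p_cost_effective,
               ceac(reps, 20000)$p_intervention)
  dom <- data.frame(delta_cost = c(-1, -2), delta_qaly = c(0.01, 0.02))
  expect_equal(unname(ce_plane_summary(dom)$quadrants["SE"]), 1)
})

test_that("run_cea ties the layers together reproducibly", {
  ref <- ce_reference_cohort(seed = 11)
  dat <- data.frame(arm = ref$arm, cost = ref$cost_healthcare,
                    qaly = ref$qaly)
  r1 <- run_cea(dat, B = 300, seed = 12)
  r2 <- run_cea(dat, B = 300, seed = 12)
  expect_identical(r1$ceac, r2$ceac)
  expect_equal(r1$plane$p_cost_effective,
               r1$ceac$p_intervention[r1$ceac$lambda == 20000])
  expect_equal(r1$icer$delta_cost, -122)  # 1198 - 1320 by construction
  expect_equal(r1$icer$delta_qaly, 0.03, tolerance = 1e-12)
})
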