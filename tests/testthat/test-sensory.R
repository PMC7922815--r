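# Panel aggregation, the omnibus ANOVA and the Spearman screen.

makeRatings <- function(scores, samples = names(scores)) {
  do.call(rbind, lapply(samples, function(s) {
    data.frame(assessor = sprintf("A%d", seq_along(scores[[s]])),
               replicate = 1L, sample = s, attribute = "roasted",
               score = scores[[s]])
  }))
}

test_that("intensity aggregation computes per-sample mean and sd", {
  r <- makeRatings(list(s1 = c(2, 3, 4), s2 = c(4, 4, 4)))
  prof <- aggregateIntensity(r, "roasted")
  expect_equal(prof$mean[prof$sample == "s1"], 3)
  expect_equal(prof$sd[prof$sample == "s1"], 1)
  expect_equal(prof$sd[prof$sample == "s2"], 0)
  expect_equal(prof$n, c(3L, 3L))
  expect_error(aggregateIntensity(r, "fruity"),
               class = "pyrasense_data_error")
})

test_that("one-way ANOVA matches the hand-computed decomposition", {
  r <- makeRatings(list(g1 = c(1, 1, 2, 2), g2 = c(6, 6, 7, 7)))
  out <- anovaBySample(r, "roasted")
  # between SS = 2*4*(2.25)^2... computed from the standard one-way
  # decomposition: means 1.5 and 6.5, grand 4, SSB = 4*2.5^2*2 = 50,
  # SSW = 4*0.25*2/... within each group sum((x-mean)^2)=1, SSW=2
  expect_equal(unname(out["F"]), (50 / 1) / (2 / 6))
  expect_equal(unname(out["df1"]), 1)
  expect_equal(unname(out["df2"]), 6)
  # cross-check against base aov on the same data
  ref <- summary(aov(score ~ factor(sample), data = r))[[1]]
  expect_equal(unname(out["F"]), ref$`F value`[1])
  expect_equal(unname(out["p"]), ref$`Pr(>F)`[1])
})

test_that("ANOVA guards degenerate designs", {
  r1 <- makeRatings(list(g1 = c(1, 2, 3)))
  expect_error(anovaBySample(r1, "roasted"),
               class = "pyrasense_design_error")
  r2 <- makeRatings(list(g1 = c(2, 2), g2 = c(5, 5)))
  expect_error(anovaBySample(r2, "roasted"),
               class = "pyrasense_degenerate_variance")
})

test_that("null panels give F near 1 and large p on average", {
  set.seed(31)
  ps <- replicate(200, {
    r <- makeRatings(list(a = rnorm(6, 4, 0.5), b = rnorm(6, 4, 0.5),
                          c = rnorm(6, 4, 0.5)))
    r$score <- pmin(pmax(r$score, 0), 7)
    anovaBySample(r, "roasted")["p"]
  })
  expect_equal(mean(ps < 0.05), 0.05, tolerance = 0.5)
  expect_gt(median(ps), 0.3)
})

test_that("Spearman rho matches the classical formula and the oracle", {
  set.seed(12)
  x <- rnorm(6); y <- rnorm(6)  # tie-free
  res <- pyrasense:::.spearman(x, y)
  d <- rank(x) - rank(y)
  expect_equal(res$rho, 1 - 6 * sum(d^2) / (6 * 35), tolerance = 1e-12)
  oracle <- permSpearmanOracle(x, y)
  expect_equal(res$pOne, oracle$pOne, tolerance = 1e-12)
  expect_equal(res$pTwo, oracle$pTwo, tolerance = 1e-12)
  # invariance under strictly monotone transforms
  res2 <- pyrasense:::.spearman(exp(3 * x), y^3 + 5 * y)
  expect_equal(res2$rho, res$rho)
})

test_that("the screen flags perfect monotone links and not anti-monotone", {
  conc <- rbind(up = 1:11, down = 11:1, null = rep(5, 11))
  colnames(conc) <- sprintf("s%02d", 1:11)
  intensity <- setNames(seq(1, 6, length.out = 11), colnames(conc))
  out <- spearmanScreen(conc, intensity)
  expect_equal(out$rho[out$compound == "up"], 1)
  expect_true(out$significant[out$compound == "up"])
  expect_equal(out$rho[out$compound == "down"], -1)
  expect_false(out$significant[out$compound == "down"])
  expect_true(out$degenerate[out$compound == "null"])
  expect_false(out$significant[out$compound == "null"])
  edges <- attr(out, "edges")
  expect_equal(edges$compound, "up")
  expect_equal(edges$weight, 1)
})

test_that("the screen needs at least 4 shared samples", {
  conc <- matrix(1:3, 1, 3, dimnames = list("c", c("a", "b", "c")))
  expect_error(spearmanScreen(conc, c(a = 1, b = 2, c = 3)),
               class = "pyrasense_insufficient_data")
})

test_that("stronger planted correlations are detected more often", {
  base <- c(x = 120, y = 45)
  cfgHi <- studyConfig(loadings = c(x = loadingForCorrelation(0.8)),
                       baseConcentration = base)
  cfgLo <- studyConfig(loadings = c(x = loadingForCorrelation(0.2)),
                       baseConcentration = base)
  hits <- function(cfg, seeds) {
    mean(vapply(seeds, function(s) {
      sim <- simulateConcentrationTable(cfg, seed = s)
      out <- spearmanScreen(sim$concentration, sim$intensity)
      out$significant[out$compound == "x"]
    }, logical(1)))
  }
  seeds <- 1:200
  expect_gt(hits(cfgHi, seeds), hits(cfgLo, seeds))
})
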