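test_that("pearson matches the product-moment formula and its contracts", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  # hand computation: deviations (-1,0,1) and (-1,1,0) give r = 0.5
  expect_equal(pearson(c(1, 2, 3), c(1, 3, 2)), 0.5)
  # affine invariance up to sign
  set.seed(1); z <- rnorm(20)
  expect_equal(pearson(z, -3 * z + 7), -1)
  expect_error(pearson(1:3, 1:4), "length")
  expect_error(pearson(1:2, 1:2), "at least 3")
  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
})

test_that("heritability is 1 with zero within-accession noise and ~0 under pure noise", {
  tab <- data.frame(accession = rep(letters[1:5], each = 3),
                    depth50_cm = rep(c(5, 8, 11, 14, 17), each = 3))
  h <- broad_sense_heritability(tab, "depth50_cm")
  expect_equal(h$H2, 1)

  set.seed(2)
  tab2 <- data.frame(accession = rep(sprintf("a%02d", 1:40), each = 10),
                     depth50_cm = 10 + rnorm(400))
  h2 <- broad_sense_heritability(tab2, "depth50_cm")
  expect_lt(h2$H2, 0.25)

  expect_error(broad_sense_heritability(
    data.frame(accession = "a", depth50_cm = 1:3)), "2 accessions")
})

test_that("heritability recovers the simulated variance ratio", {
  # 60 accessions x 3 replicates, V_G = 3, V_E = 1: analytic H2 = 0.75
  set.seed(101)
  ests <- replicate(50, {
    g <- rnorm(60, sd = sqrt(3))
    tab <- data.frame(accession = rep(sprintf("a%02d", 1:60), each = 3),
                      depth50_cm = rep(g, each = 3) + rnorm(180, sd = 1))
    broad_sense_heritability(tab, "depth50_cm")$H2
  })
  expect_equal(mean(ests), 0.75, tolerance = 0.1 / 0.75)
})

test_that("heritability is invariant to affine trait rescaling", {
  set.seed(3)
  tab <- data.frame(accession = rep(letters[1:10], each = 3),
                    depth50_cm = rnorm(30, 10, 2))
  h_cm <- broad_sense_heritability(tab, "depth50_cm")$H2
  tab$depth50_cm <- tab$depth50_cm * 10 + 4  # cm -> mm with offset
  expect_equal(broad_sense_heritability(tab, "depth50_cm")$H2, h_cm)
})

test_that("one-way ANOVA F statistic behaves at the extremes", {
  same <- list(c(1, 2, 3), c(1, 2, 3))
  res <- oneway_anova(same)
  expect_equal(res$F, 0)
  expect_equal(res$p_value, 1)

  far <- list(c(1, 2, 3), c(101, 102, 103))
  expect_lt(oneway_anova(far)$p_value, 0.001)

  # shift invariance
  set.seed(4)
  gs <- lapply(1:3, function(i) rnorm(8))
  expect_equal(oneway_anova(gs)$F,
               oneway_anova(lapply(gs, function(v) v + 100))$F)

  # agrees with stats::aov on the same data
  y <- unlist(gs); g <- factor(rep(1:3, each = 8))
  ref <- summary(stats::aov(y ~ g))[[1]]
  expect_equal(oneway_anova(gs)$F, ref[["F value"]][1])
  expect_equal(oneway_anova(gs)$p_value, ref[["Pr(>F)"]][1])

  expect_error(oneway_anova(list(1:3)), "2 groups")
  expect_error(oneway_anova(list(1:3, 5)), ">= 2 values")
})

test_that("Steel-Dwass reduces to the rank-sum test at k = 2", {
  set.seed(5)
  x <- rnorm(15); y <- rnorm(15, 0.8)
  sd_res <- steel_dwass(list(a = x, b = y))
  # independent reference: two-sided normal-approximation rank-sum
  N <- 30; W <- sum(rank(c(x, y))[1:15])
  z <- (W - 15 * 31 / 2) / sqrt(15 * 15 * 31 / 12)
  p_ref <- 2 * pnorm(-abs(z))
  expect_equal(sd_res$p_value, p_ref, tolerance = 0.01)
  expect_equal(abs(sd_res$statistic), abs(z), tolerance = 1e-8)
})

test_that("Steel-Dwass gives p ~ 1 for identical groups and a full pair table", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  res <- steel_dwass(g)
  expect_equal(nrow(res), 3L)
  expect_true(all(res$p_value > 0.95))
  expect_error(steel_dwass(list(a = 1:3)), "2 groups")
})

test_that("clustering separates constructed clouds and is order-invariant", {
  set.seed(6)
  centers <- list(c(5, 3), c(15, 4), c(10, 12))
  tab <- do.call(rbind, lapply(1:3, function(k)
    data.frame(accession = sprintf("c%d_%02d", k, 1:8),
               depth50_cm = centers[[k]][1] + rnorm(8, sd = 0.2),
               width50_cm = centers[[k]][2] + rnorm(8, sd = 0.2))))
  cl <- cluster_accessions(tab, k = 3)
  truth <- rep(1:3, each = 8)
  # perfect agreement up to label permutation
  expect_equal(length(unique(paste(cl$labels, truth))), 3L)

  perm <- tab[sample(nrow(tab)), ]
  cl2 <- cluster_accessions(perm, k = 3)
  expect_identical(cl2$labels[names(cl$labels)], cl$labels)

  # k = n: every accession its own cluster
  cln <- cluster_accessions(tab, k = nrow(tab))
  expect_equal(length(unique(cln$labels)), nrow(tab))
  expect_error(cluster_accessions(tab, k = 100), "exceeds")
})

test_that("Steel-Dwass controls the family-wise error under the null", {
  set.seed(7)
  k <- 4; n <- 15
  fwer <- mean(replicate(500, {
    groups <- lapply(1:k, function(i) rnorm(n))
    any(steel_dwass(groups)$p_value < 0.05)
  }))
  expect_lte(fwer, 0.07)
})
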