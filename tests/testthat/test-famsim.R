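test_that("a two-haplotype pool carries its single mutation at frequency 1/2", {
  set.seed(51)
  # smallest admissible pool: H = 4; a site hitting a tip branch has
  # frequency 1/4, the two-tip branch 1/2 -- always strictly inside (0, 1)
  pool <- coalescent_pool(4, 5)
  expect_true(all(pool$maf > 0 & pool$maf < 1))
  expect_equal(dim(pool$pool), c(4, 5))
  expect_true(all(pool$pool %in% 0:1))
})

test_that("pools are reproducible under a fixed seed", {
  set.seed(52); a <- coalescent_pool(100, 20)
  set.seed(52); b <- coalescent_pool(100, 20)
  expect_identical(a$pool, b$pool)
})

test_that("the site-frequency spectrum is neutral (~ 1/i) and rare-heavy", {
  set.seed(53)
  # one site per pool: sites on a shared genealogy are correlated, so the
  # goodness-of-fit draws each site from an independent tree
  H <- 100
  counts <- vapply(1:2000, function(i) sum(coalescent_pool(H, 1)$pool),
                   numeric(1))
  # E(# sites at derived count i) proportional to 1/i
  bins <- c(1, 2, 3, 5, 10, 20, H)  # [1,2) [2,3) [3,5) [5,10) [10,20) [20,H)
  obs <- table(cut(counts, breaks = bins, right = FALSE))
  expected <- vapply(seq_len(length(bins) - 1), function(k) {
    sum(1 / seq(bins[k], bins[k + 1] - 1))
  }, numeric(1))
  gof <- chisq.test(as.numeric(obs), p = expected / sum(expected))
  expect_gt(gof$p.value, 0.001)

  # folded spectrum: MAF < 1% class outweighs any higher 1%-wide class
  set.seed(54)
  big <- coalescent_pool(1000, 100)
  maf <- pmin(big$maf, 1 - big$maf)
  lowest <- mean(maf < 0.01)
  higher <- vapply(1:49, function(k) mean(maf >= k / 100 & maf < (k + 1) / 100),
                   numeric(1))
  expect_gt(lowest, 0)
  expect_true(all(lowest >= higher))
})

test_that("family simulation has the right census and Mendelian structure", {
  set.seed(55)
  pool <- coalescent_pool(500, 20)
  sim <- simulate_families(pool, 50)
  expect_equal(nrow(sim$ped), 600)
  expect_equal(sum(is_founder(sim$ped)), 200)
  expect_equal(dim(sim$hap), c(600, 20))
  expect_equal(nrow(famada:::mendel_warn(sim$hap, sim$ped)), 0)
})

test_that("founder allele frequencies track the pool frequencies", {
  set.seed(56)
  pool <- coalescent_pool(400, 30)
  agg <- rep(0, 30); ndraw <- 0
  for (i in 1:20) {
    sim <- simulate_families(pool, 10)
    fdr <- which(is_founder(sim$ped))
    agg <- agg + colSums(sim$hap$h1[fdr, ] + sim$hap$h2[fdr, ])
    ndraw <- ndraw + 2 * length(fdr)
  }
  fhat <- agg / ndraw
  se <- sqrt(pool$maf * (1 - pool$maf) / ndraw)
  expect_true(all(abs(fhat - pool$maf) < 5 * pmax(se, 0.005)))
})

test_that("founder draws respect the replacement contract", {
  set.seed(57)
  pool <- coalescent_pool(100, 10)
  expect_error(simulate_families(pool, 20), "without replacement")
  sim <- simulate_families(pool, 20, replace = TRUE)
  expect_equal(nrow(sim$ped), 240)
})

test_that("GRR from PAR matches the closed form and its monotonicity", {
  expect_equal(grr_from_par(0.01, 0.01), 0.01 / (0.01 * 0.99) + 1,
               tolerance = 1e-12)
  expect_equal(grr_from_par(0.01, 0.01), 2.01010101010101, tolerance = 1e-10)
  expect_equal(grr_from_par(0, 0.1), 1)
  expect_gt(grr_from_par(0.02, 0.001), grr_from_par(0.02, 0.1))
  g <- grr_from_par(c(0.01, 0.02, 0.05), 0.05)
  expect_true(all(diff(g) > 0))
  expect_error(grr_from_par(1, 0.1), "par")
  expect_error(grr_from_par(0.1, 0), "maf")
})

test_that("penetrance is multiplicative on the baseline and clamps at 1", {
  # one causal site with GRR = 2 at maf 0.25 (par = 0.2 gives exactly 2)
  model <- disease_model(maf = c(0.25), causal_sites = 1L, par_per_site = 0.2,
                         baseline_penetrance = 0.05)
  expect_equal(model$grr, 2, tolerance = 1e-12)

  # carriers of 0/1/2 causal alleles have penetrance 0.05/0.10/0.20
  hap <- haplotype_set(matrix(c(0L, 1L, 1L), 3, 1),
                       matrix(c(0L, 0L, 1L), 3, 1))
  set.seed(58)
  n <- 2e4
  hapN <- haplotype_set(matrix(rep(c(0L, 1L, 1L), n), ncol = 1),
                        matrix(rep(c(0L, 0L, 1L), n), ncol = 1))
  y <- dichotomous_trait(hapN, model)
  rate <- as.numeric(tapply(y, rep(c(0, 1, 2), n), mean))
  expect_true(all(abs(rate - c(0.05, 0.10, 0.20)) < 0.012))

  # no causal site: disease rate is the baseline penetrance
  null_model <- disease_model(maf = 0.25, causal_sites = integer(0))
  y0 <- dichotomous_trait(hapN, null_model)
  expect_lt(abs(mean(y0) - 0.05), 3 * sqrt(0.05 * 0.95 / (3 * n)))
})

test_that("QTL calibration delivers the requested variance explained", {
  set.seed(59)
  n <- 1e5
  p <- 0.3
  x1 <- rbinom(n, 1, p); x2 <- rbinom(n, 1, p)
  hap <- haplotype_set(matrix(as.integer(x1), n, 1),
                       matrix(as.integer(x2), n, 1))
  model <- qtl_model(maf = p, causal_sites = 1L, h2_per_site = 0.006)
  y <- continuous_trait(hap, model)
  r2 <- summary(lm(y ~ I(x1 + x2)))$r.squared
  expect_lt(abs(r2 - 0.006), 0.002)

  # null model: Y ~ Normal(100, 100)
  null_m <- qtl_model(maf = p, causal_sites = integer(0))
  y0 <- continuous_trait(hap, null_m)
  expect_lt(abs(mean(y0) - 100), 0.15)
  expect_lt(abs(var(y0) - 100), 2)

  # additive effect scales as sqrt(h2 * V): quadrupling the variance share
  # doubles a, up to the small change in the total-variance budget V
  m1 <- qtl_model(maf = p, causal_sites = 1L, h2_per_site = 0.001)
  m4 <- qtl_model(maf = p, causal_sites = 1L, h2_per_site = 0.004)
  expect_equal(m4$a / m1$a, 2 * sqrt((1 - 0.001) / (1 - 0.004)),
               tolerance = 1e-10)
  expect_equal(m4$a^2 * (1 - 0.004) / (m1$a^2 * (1 - 0.001)), 4,
               tolerance = 1e-10)
})

test_that("trait models reject infeasible configurations", {
  expect_error(disease_model(maf = rep(0.2, 5), causal_sites = 10L), "exceeds")
  expect_error(qtl_model(maf = rep(0.2, 5), causal_sites = 1L,
                         h2_per_site = 1.2), "below 1")
  expect_error(disease_model(maf = c(0, 0.2), causal_sites = 1L,
                             total_par = 0.05), "monomorphic")
})
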