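test_that("the hand-written likelihood matches the binomial pmf product", {
  set.seed(71)
  for (i in 1:100) {
    cr <- sample(5:60, 1); cs <- sample(0:cr, 1)
    lr <- sample(5:60, 1); ls <- sample(0:lr, 1)
    tab <- contingency_table(cs, cr, ls, lr)
    pc <- runif(1); pl <- runif(1)
    expect_equal(presence_likelihood(tab, pc, pl),
                 dbinom(cs, cr, pc) * dbinom(ls, lr, pl),
                 tolerance = 1e-12)
  }
})

test_that("likelihood boundary conventions: zero and one probabilities", {
  tab <- contingency_table(15, 53, 0, 47)
  # pl = 0 with LS = 0: the lesion factor is (1-0)^47 * 0^0 = 1
  expect_equal(presence_likelihood(tab, 0.3, 0),
               dbinom(15, 53, 0.3), tolerance = 1e-12)
  # pc = 1 with CS < CR: impossible data, likelihood 0
  expect_equal(presence_likelihood(tab, 1, 0.1), 0)
})

test_that("the posterior normalises and matches Beta conjugate marginals", {
  tab <- contingency_table(15, 53, 0, 47)
  post <- presence_posterior(tab, resolution = 1001)
  expect_equal(sum(post$density), 1, tolerance = 1e-9)

  # uniform-prior MAP equals the MLE within one grid step
  marg_c <- rowSums(post$density)
  expect_lt(abs(post$p[which.max(marg_c)] - 15 / 53), 1.5 / 1001)

  # conjugacy: marginal means equal Beta(CS+1, CR-CS+1) / Beta(LS+1, ...)
  mean_c <- sum(post$p * marg_c)
  mean_l <- sum(post$p * colSums(post$density))
  expect_equal(mean_c, 16 / 55, tolerance = 1e-3)
  expect_equal(mean_l, 1 / 49, tolerance = 1e-3)

  # grid refinement shrinks the conjugacy error
  err_at <- function(res) {
    p2 <- presence_posterior(tab, resolution = res)
    abs(sum(p2$p * rowSums(p2$density)) - 16 / 55)
  }
  expect_lt(err_at(2001), err_at(501) + 1e-12)
})

test_that("tail probabilities respect symmetry and the half-mass tie rule", {
  # exchangeable table: P(PC > PL) is exactly 1/2
  tab <- contingency_table(3, 10, 3, 10)
  post <- presence_posterior(tab, resolution = 501)
  expect_equal(prob_greater(post, 1), 0.5, tolerance = 1e-12)

  # P(PC > PL) + P(PL > PC) = 1 under the half-mass convention
  tab2 <- contingency_table(12, 40, 5, 30)
  post2 <- presence_posterior(tab2, resolution = 501)
  swapped <- post2
  swapped$density <- t(post2$density)
  expect_equal(prob_greater(post2, 1) + prob_greater(swapped, 1), 1,
               tolerance = 1e-9)

  expect_error(prob_greater(post2, -1), "non-negative")
})

test_that("Wald statistics reproduce the published values", {
  spatial <- wald_statistic(contingency_table(15, 53, 0, 47))
  expect_equal(round(as.numeric(spatial), 3), 4.574)
  expect_equal(attr(spatial, "diff_proportion"), 15 / 53)

  nonspatial <- wald_statistic(contingency_table(16, 53, 13, 47))
  expect_equal(round(as.numeric(nonspatial), 2), 0.28)

  # equal proportions give zero
  expect_equal(as.numeric(wald_statistic(contingency_table(10, 20, 10, 20))), 0)
  # degenerate but equal: zero by convention
  expect_equal(as.numeric(wald_statistic(contingency_table(0, 5, 0, 7))), 0)
  # degenerate and unequal: signed infinity
  expect_equal(as.numeric(wald_statistic(contingency_table(5, 5, 0, 7))), Inf)
})

test_that("Barnard's test handles degenerate and published tables", {
  # identical observed proportions: p = 1
  b0 <- barnard_test(contingency_table(0, 5, 0, 5))
  expect_equal(b0$p_two_sided, 1.0)

  bs <- barnard_test(contingency_table(15, 53, 0, 47))
  expect_lte(bs$p_two_sided, 0.001)
  expect_equal(round(bs$wald, 3), 4.574)

  bn <- barnard_test(contingency_table(16, 53, 13, 47))
  expect_gt(bn$p_two_sided, 0.5)  # the null is clearly not rejected
})

test_that("Barnard's p is invariant under swapping groups, with sign-flipped Wald", {
  tab <- contingency_table(12, 30, 4, 25)
  swp <- contingency_table(4, 25, 12, 30)
  a <- barnard_test(tab, nuisance_grid = 501)
  b <- barnard_test(swp, nuisance_grid = 501)
  expect_equal(a$p_two_sided, b$p_two_sided, tolerance = 1e-12)
  expect_equal(a$wald, -b$wald, tolerance = 1e-12)
})

test_that("Barnard's p matches a Monte-Carlo tail probability at the maximising nuisance", {
  set.seed(72)
  wald_ref <- function(cs, cr, ls, lr) {
    p1 <- cs / cr; p2 <- ls / lr
    se <- sqrt(p1 * (1 - p1) / cr + p2 * (1 - p2) / lr)
    d <- p1 - p2
    ifelse(se == 0, ifelse(d == 0, 0, Inf), abs(d) / se)
  }
  for (i in 1:5) {
    cr <- sample(8:30, 1); cs <- sample(0:cr, 1)
    lr <- sample(8:30, 1); ls <- sample(0:lr, 1)
    tab <- contingency_table(cs, cr, ls, lr)
    res <- barnard_test(tab)
    n_mc <- 1e5
    sim_cs <- rbinom(n_mc, cr, res$nuisance_at_max)
    sim_ls <- rbinom(n_mc, lr, res$nuisance_at_max)
    tail_mc <- mean(wald_ref(sim_cs, cr, sim_ls, lr) >=
                      abs(res$wald) - 1e-12)
    mc_sd <- sqrt(tail_mc * (1 - tail_mc) / n_mc)
    expect_lt(abs(res$p_two_sided - tail_mc), 3 * mc_sd + 1e-6)
  }
})
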