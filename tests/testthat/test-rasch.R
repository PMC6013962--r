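test_that("preference probability follows the logistic law on the extended reals", {
  expect_equal(prob_prefer_own(1.3, 1.3), 0.5)          # fifty-fifty at equality
  expect_equal(prob_prefer_own(log(3), 0), 0.75)
  expect_equal(prob_prefer_own(Inf, 0), 1)
  expect_equal(prob_prefer_own(-Inf, 3), 0)
  expect_equal(prob_prefer_own(0, -Inf), 1)
  expect_equal(logit_prefer_own(2, 0.5), 1.5)

  # complementarity and strict monotonicity in theta - beta
  set.seed(3)
  th <- rnorm(50, sd = 3); be <- rnorm(50, sd = 3)
  expect_equal(prob_prefer_own(th, be) + prob_prefer_own(be, th), rep(1, 50))
  eta <- sort(th - be)
  expect_true(all(diff(prob_prefer_own(eta, 0)) > 0))

  # translation invariance
  expect_equal(prob_prefer_own(th + 2.7, be + 2.7), prob_prefer_own(th, be))
})

test_that("response matrices validate entries and store raw scores", {
  Y <- rbind(c(1, 0, 1), c(0, 0, 0))
  rm_ <- response_matrix(Y, persons = c("a", "b"), items = c("i1", "i2", "i3"))
  expect_equal(unname(rm_$raw_scores), c(2L, 0L))
  expect_error(response_matrix(rbind(c(1, 2))), "0 or 1")
  expect_error(response_matrix(rbind(c(1, NA))), "missing")
  expect_error(response_matrix(Y, items = c("x", "x", "y")), "unique")
})

test_that("conditional log-likelihood matches closed forms and pattern enumeration", {
  # one person, two equally valued items, one of two r = 1 patterns
  d <- response_matrix(matrix(c(1, 0), 1))
  expect_equal(conditional_loglik(d, c(0, 0)), log(0.5))

  # extreme-score persons contribute nothing
  d0 <- response_matrix(rbind(c(1, 1, 1), c(0, 0, 0)))
  expect_equal(conditional_loglik(d0, c(-1, 0, 2)), 0)

  # random small data against per-pattern enumeration
  set.seed(11)
  for (rep in 1:5) {
    I <- sample(3:5, 1)
    beta <- rnorm(I)
    Y <- matrix(rbinom(8 * I, 1, 0.5), 8, I)
    d <- response_matrix(Y)
    keep <- rowSums(Y) > 0 & rowSums(Y) < I
    ll_oracle <- sum(vapply(which(keep), function(p) {
      oracle_pattern_loglik(Y[p, ], beta)
    }, numeric(1)))
    expect_equal(conditional_loglik(d, beta), ll_oracle, tolerance = 1e-10)
  }
})

test_that("conditional likelihood depends on the data only through sufficient statistics", {
  # same item margins and score distribution, different joint patterns
  A <- response_matrix(rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)))
  B <- response_matrix(rbind(c(1, 0, 1, 0), c(0, 1, 0, 1)))
  beta <- c(-0.8, 0.2, 0.1, 0.5)
  expect_equal(conditional_loglik(A, beta), conditional_loglik(B, beta))

  # permuting persons with equal raw scores changes nothing
  set.seed(4)
  Y <- matrix(rbinom(60, 1, 0.5), 12, 5)
  d1 <- response_matrix(Y)
  r <- rowSums(Y)
  swap <- which(r == r[1])
  expect_gt(length(swap), 1L)
  Y2 <- Y; Y2[swap[1:2], ] <- Y[swap[2:1], ]
  b <- rnorm(5)
  expect_equal(conditional_loglik(response_matrix(Y2), b),
               conditional_loglik(d1, b))
})

test_that("CML estimates solve the estimating equations and respect symmetry", {
  sim <- sim_rm(c(-1, 0, 1), P = 80, seed = 21)
  fit <- fit_rasch_cml(sim$data)
  expect_true(fit$converged)
  expect_equal(sum(fit$beta), 0, tolerance = 1e-10)

  # score-equation residuals: observed vs expected conditional item margins
  work <- fit$data_used
  resid <- maprmod:::.cml_eval(fit$beta, table(rowSums(work$Y)),
                               colSums(work$Y))$score
  expect_lt(max(abs(resid)), 1e-8)

  # two identical response columns get identical estimates
  Y <- sim$data$Y
  Y2 <- cbind(Y, Y[, 2])
  colnames(Y2) <- c("i1", "i2", "i3", "i2copy")
  fit2 <- fit_rasch_cml(response_matrix(Y2))
  expect_equal(unname(fit2$beta["i2"]), unname(fit2$beta["i2copy"]),
               tolerance = 1e-9)
})

test_that("CML estimates match a dense grid search of the conditional likelihood", {
  sim <- sim_rm(c(-0.7, 0.2, 0.5), P = 60, seed = 33)
  fit <- fit_rasch_cml(sim$data)
  grid <- oracle_grid_rasch3(sim$data)
  expect_lt(max(abs(fit$beta - grid)), 2e-3)
})

test_that("item-anchored fits shift the scale without changing differences", {
  sim <- sim_rm(c(-1, -0.2, 0.6, 1.1), P = 150, seed = 8)
  f_sum <- fit_rasch_cml(sim$data)
  f_anchor <- fit_rasch_cml(sim$data, anchor = "item", anchor_item = "I2")
  expect_equal(unname(f_anchor$beta["I2"]), 0)
  expect_equal(diff(f_sum$beta), diff(f_anchor$beta), tolerance = 1e-9)
  expect_equal(unname(f_anchor$se_beta["I2"]), 0, tolerance = 1e-12)
  expect_equal(f_sum$log_cl, f_anchor$log_cl)
})

test_that("extreme-score persons are excluded and constant items dropped with a warning", {
  sim <- sim_rm(c(-1, 0, 1), P = 100, seed = 13)
  fit0 <- fit_rasch_cml(sim$data)

  # appending all-1 and all-0 persons must not move the estimates
  Y <- rbind(sim$data$Y, rep(1L, 3), rep(0L, 3))
  fit1 <- fit_rasch_cml(response_matrix(Y))
  expect_equal(fit1$beta, fit0$beta, tolerance = 1e-9)
  expect_equal(fit1$n_persons_used, fit0$n_persons_used)

  # a constant column is dropped, with a warning naming it
  Y2 <- cbind(sim$data$Y, allzero = 0L)
  expect_warning(fit2 <- fit_rasch_cml(response_matrix(Y2)), "allzero")
  expect_identical(fit2$dropped_items, "allzero")
  expect_equal(fit2$beta, fit0$beta, tolerance = 1e-9)
})

test_that("ill-conditioned matrices are refused with a witness partition", {
  # nobody prefers own over items 3 or 4 while judging 1 or 2 better than
  # own, so no response separates {3,4} from {1,2} in the required
  # direction; columns are non-constant and no score is extreme
  Y <- rbind(c(1, 1, 1, 0), c(1, 1, 0, 1), c(1, 0, 0, 0), c(0, 1, 0, 0))
  colnames(Y) <- paste0("I", 1:4)
  expect_error(fit_rasch_cml(response_matrix(Y)), "ill-conditioned.*I3")
})

test_that("person ML estimates solve the score equation with the information-based se", {
  pf <- fit_persons_ml(setNames(5L, "p"), rep(0, 10))
  expect_equal(pf$theta, 0, tolerance = 1e-9)
  expect_equal(pf$se_theta, 1 / sqrt(10 * 0.25), tolerance = 1e-9)

  pf2 <- fit_persons_ml(1L, c(-1, 1))
  expect_equal(pf2$theta, 0, tolerance = 1e-9)

  beta <- c(-1, 0, 1)
  pf3 <- fit_persons_ml(2L, beta)
  expect_equal(pf3$theta, oracle_bisect_theta(2, beta), tolerance = 1e-7)
  p <- plogis(pf3$theta - beta)
  expect_equal(pf3$se_theta, 1 / sqrt(sum(p * (1 - p))))

  # extreme scores: flagged, infinite point values
  pf4 <- fit_persons_ml(c(0L, 3L, 2L), beta)
  expect_identical(pf4$extreme, c(TRUE, TRUE, FALSE))
  expect_identical(pf4$theta[1:2], c(-Inf, Inf))

  # theta strictly increasing in the raw score; se bounded below
  beta5 <- c(-2, -1, 0, 1, 2)
  pf5 <- fit_persons_ml(1:4, beta5)
  expect_true(all(diff(pf5$theta) > 0))
  expect_true(all(pf5$se_theta >= 1 / sqrt(0.25 * 5) - 1e-12))
})

test_that("parameter recovery: centered estimates approach the generating values", {
  truth <- c(-2, -1, 0, 1, 2)
  sim <- sim_rm(truth, P = 2000, seed = 1)
  fit <- fit_rasch_cml(sim$data)
  expect_lt(max(abs(fit$beta - truth)), 0.15)
})
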