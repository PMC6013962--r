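test_that("Andersen test bookkeeping: statistic non-negative, df = (G-1)(I-1)", {
  sim <- sim_rm(seq(-2, 2, length.out = 9), P = 400, seed = 31)
  at <- andersen_test(sim$data)
  expect_length(at$items_used, 9L)
  expect_equal(at$df, 8L)                       # two groups, 9 items
  expect_gte(at$statistic, 0)
  expect_true(at$p_value >= 0 && at$p_value <= 1)

  at3 <- andersen_test(sim$data, split = "tertile")
  expect_equal(at3$df, 2L * (length(at3$items_used) - 1L))

  # invariant to relabeling of the groups
  r <- rowSums(sim$data$Y)
  g <- ifelse(r <= median(r), "A", "B")
  at_a <- andersen_test(sim$data, groups = g)
  at_b <- andersen_test(sim$data, groups = ifelse(g == "A", "zzz", "aaa"))
  expect_equal(at_a$statistic, at_b$statistic)
  expect_equal(at_a$statistic, at$statistic)
})

test_that("Andersen test drops items constant within a score group from all groups", {
  # item D is constant inside each score group (0 among low scorers, 1 among
  # high scorers) though mixed overall
  Y <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0),
             c(1, 1, 0, 1), c(1, 0, 1, 1), c(0, 1, 1, 1))
  d <- response_matrix(Y, items = c("A", "B", "C", "D"))
  expect_message(at <- andersen_test(d), "constant within")
  expect_false("D" %in% at$items_used)
  expect_true("D" %in% at$dropped_items)
  expect_equal(at$df, 2L)
})

test_that("nested LR test: df bookkeeping and saturated equivalence", {
  sim <- sim_rm(c(0.6, -2, -1.2, -0.5, 0.3, 1), P = 300, seed = 23)
  sys <- classification_system(c(a = 3, b = 2))
  items <- c("11", "21", "31", "12", "22", "32")
  d <- response_matrix(sim$data$Y, items = items)
  rf <- fit_rasch_cml(d)
  lf <- fit_mapr_cml(d, system = sys)
  lt <- lr_test_nested(rf, lf)
  expect_equal(lt$df, (6L - 1L) - 3L)
  expect_gte(lt$statistic, 0)

  # saturated design: identical models, statistic ~ 0
  W <- rbind(0, diag(5)); colnames(W) <- paste0("d", 2:6)
  lf_sat <- fit_mapr_cml(d, design = W)
  lt_sat <- lr_test_nested(rf, lf_sat)
  expect_lt(lt_sat$statistic, 1e-6)
  expect_equal(lt_sat$df, 0L)

  # refusing fits from different data
  sim2 <- sim_rm(c(0.6, -2, -1.2, -0.5, 0.3, 1), P = 300, seed = 24)
  rf2 <- fit_rasch_cml(response_matrix(sim2$data$Y, items = items))
  expect_error(lr_test_nested(rf2, lf), "same response matrix")
})

test_that("well-conditioning check agrees with bipartition enumeration", {
  # all-zero column: ill-conditioned, witness isolates the item
  Y <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  wc <- check_well_conditioned(response_matrix(Y, items = c("a", "b", "c")))
  expect_false(wc$well_conditioned)
  expect_true("c" %in% wc$witness$set2 || identical(wc$witness$set1, "c"))

  # both mixed patterns present: well conditioned
  Y2 <- rbind(c(1, 0), c(0, 1))
  expect_true(check_well_conditioned(response_matrix(Y2))$well_conditioned)

  # random matrices against the brute-force oracle
  set.seed(41)
  for (rep in 1:60) {
    I <- sample(3:6, 1)
    P <- sample(4:10, 1)
    Y <- matrix(rbinom(P * I, 1, runif(1, 0.25, 0.75)), P, I)
    if (all(rowSums(Y) %in% c(0, I))) next
    d <- response_matrix(Y)
    expect_identical(check_well_conditioned(d)$well_conditioned,
                     oracle_well_conditioned(Y))
  }
})

test_that("the witness of an ill-conditioned matrix is a genuine violation", {
  Y <- rbind(c(1, 1, 1, 0), c(1, 1, 0, 1), c(1, 0, 0, 0), c(0, 1, 0, 0))
  d <- response_matrix(Y, items = paste0("I", 1:4))
  wc <- check_well_conditioned(d)
  expect_false(wc$well_conditioned)
  s1 <- match(wc$witness$set1, d$items)
  s2 <- match(wc$witness$set2, d$items)
  # no person has a 1 on set1 together with a 0 on set2
  viol <- apply(Y, 1, function(y) any(y[s1] == 1) && any(y[s2] == 0))
  expect_false(any(viol))

  # removing the witness items leaves a well-conditioned submatrix here
  d2 <- response_matrix(Y[, s2, drop = FALSE])
  expect_true(check_well_conditioned(d2)$well_conditioned)
})

test_that("Guttman scalogram counts deviations from the ideal staircase", {
  # perfect Guttman data: nested response sets, no misfit
  Y <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0))
  sg <- guttman_scalogram(response_matrix(Y))
  expect_equal(sg$misfit_count, 0L)

  # one row deviating by a swapped pair: two misfit cells at the swap
  Y2 <- rbind(c(1, 1, 0), c(0, 1, 1))
  sg2 <- guttman_scalogram(response_matrix(Y2))
  expect_equal(sg2$misfit_count, 2L)
  expect_setequal(sg2$misfits$col, c(2L, 3L))
  expect_equal(unique(sg2$misfits$row), 2L)

  # count invariant to permuting the input rows/columns
  set.seed(43)
  Y3 <- matrix(rbinom(48, 1, 0.5), 8, 6)
  base_count <- guttman_scalogram(response_matrix(Y3))$misfit_count
  for (rep in 1:5) {
    Yp <- Y3[sample(8), sample(6)]
    expect_equal(guttman_scalogram(response_matrix(Yp))$misfit_count, base_count)
  }
})

test_that("person-item map reports the share of pairs with theta above beta", {
  beta <- c(-3, -2.5, -2)
  theta <- c(0, 0.5, 1, 2)
  pim <- person_item_map(beta, theta)
  expect_equal(pim$frac_theta_above_beta, 1)
  expect_equal(min(pim$breaks), -3)
  expect_equal(max(pim$breaks), 2)
  expect_equal(sum(pim$counts), 4L)

  # symmetric configuration: half the pairs above
  pim2 <- person_item_map(c(-1, 1), c(-1, 1) + c(1e-9, -1e-9))
  expect_equal(pim2$frac_theta_above_beta, 0.5)
})

test_that("iterative witness removal reaches a well-conditioned submatrix", {
  Y <- rbind(c(1, 1, 1, 0), c(1, 1, 0, 1), c(1, 0, 0, 0), c(0, 1, 0, 0))
  d <- response_matrix(Y, items = paste0("I", 1:4))
  red <- make_well_conditioned(d)
  expect_true(check_well_conditioned(red$data)$well_conditioned)
  expect_setequal(red$dropped_items, c("I3", "I4"))
  expect_setequal(red$data$items, c("I1", "I2"))

  # well-conditioned data keep their full item set (only extreme-score
  # persons are filtered, as in estimation)
  sim <- sim_rm(c(-1, 0, 1), P = 60, seed = 71)
  red2 <- make_well_conditioned(sim$data)
  expect_identical(red2$data$items, sim$data$items)
  expect_length(red2$dropped_items, 0L)
})
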