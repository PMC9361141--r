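test_that("permuted blocks balance arms within every stratum", {
  roster <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:8),
    sex = rep("female", 8), baseline_isi = rep(10, 8)
  )
  alloc <- stratified_block_randomize(roster, seed = 1)
  expect_equal(sum(alloc$arm == "SPA"), 4)
  expect_equal(sum(alloc$arm == "control"), 4)
  # every complete block of 4 holds exactly 2 of each arm
  for (b in unique(alloc$block_index)) {
    blk <- alloc$arm[alloc$block_index == b]
    expect_equal(sum(blk == "SPA"), 2)
  }
  # partial block: 6 participants differ by at most 2
  alloc6 <- stratified_block_randomize(roster[1:6, ], seed = 9)
  expect_lte(abs(diff(table(alloc6$arm))), 2)
})

test_that("randomization is a pure function of roster order and seed", {
  set.seed(77)
  roster <- tibble::tibble(
    participant_id = sprintf("p%03d", 1:40),
    sex = sample(c("female", "male"), 40, replace = TRUE),
    baseline_isi = sample(0:28, 40, replace = TRUE)
  )
  a1 <- stratified_block_randomize(roster, seed = 123)
  a2 <- stratified_block_randomize(roster, seed = 123)
  expect_identical(a1, a2)
  a3 <- stratified_block_randomize(roster, seed = 124)
  expect_false(identical(a1$arm, a3$arm))
  # relabeling participants (same arrival order, same strata) keeps arms
  relabeled <- roster
  relabeled$participant_id <- sprintf("q%03d", 1:40)
  a4 <- stratified_block_randomize(relabeled, seed = 123)
  expect_equal(a4$arm, a1$arm)
  # stratum-wise imbalance bounded by block_size/2 per partial block
  tab <- table(a1$stratum, a1$arm)
  expect_true(all(abs(tab[, "SPA"] - tab[, "control"]) <= 2))
  expect_error(stratified_block_randomize(roster), "seed")
})

test_that("sample size matches the closed form and its monotonicities", {
  expect_equal(required_sample_size(1.3, 2.3), 50L)
  expect_equal(required_sample_size(1, 1), 16L)  # 2*(1.96+0.8416)^2 = 15.7
  closed <- function(delta, sd, alpha = 0.05, power = 0.8) {
    ceiling(2 * (qnorm(1 - alpha / 2) + qnorm(power))^2 * sd^2 / delta^2)
  }
  grid <- expand.grid(delta = c(0.5, 1, 1.3, 2), sd = c(1, 2.3, 4))
  for (i in seq_len(nrow(grid))) {
    expect_equal(required_sample_size(grid$delta[i], grid$sd[i]),
                 as.integer(closed(grid$delta[i], grid$sd[i])))
  }
  n <- vapply(c(2, 1.3, 0.8, 0.4, 0.2), required_sample_size,
              integer(1), sd = 2.3)
  expect_true(all(diff(n) > 0))  # grows without bound as delta shrinks
  expect_true(all(diff(vapply(1:4, function(s)
    required_sample_size(1.3, s), integer(1))) > 0))
})

test_that("attrition inflation uses the multiplicative convention", {
  expect_equal(inflate_for_attrition(100, 0.20), 120L)
  expect_equal(inflate_for_attrition(100, 0), 100L)
  expect_equal(inflate_for_attrition(101, 0.20), 122L)  # ceil(121.2)
})

test_that("Pearson chi-square equals the brute-force oracle on small tables", {
  # proportional table -> exactly zero
  prop <- outer(c(10, 20), c(3, 7)) / 10
  expect_equal(pearson_chi_square(prop)$statistic, 0)
  # random tables up to 4x4, n <= 50: compare against the independent
  # textbook double loop and stats::chisq.test without correction
  set.seed(31)
  for (i in 1:30) {
    r <- sample(2:4, 1); cc <- sample(2:4, 1)
    tab <- matrix(stats::rmultinom(1, sample(20:50, 1),
                                   rep(1, r * cc))[, 1], nrow = r)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    res <- pearson_chi_square(tab)
    brute <- 0
    for (a in seq_len(r)) for (b in seq_len(cc)) {
      e <- sum(tab[a, ]) * sum(tab[, b]) / sum(tab)
      brute <- brute + (tab[a, b] - e)^2 / e
    }
    expect_equal(res$statistic, brute)
    expect_equal(res$df, (r - 1) * (cc - 1))
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p_value, unname(ref$p.value))
  }
  expect_error(pearson_chi_square(matrix(c(0, 0, 3, 4), 2)), "positive")
})

test_that("published baseline tables reproduce their printed statistics", {
  expect_equal(
    round(pearson_chi_square(trial_fixture("table1-isi8-alcohol"))$statistic,
          2), 6.81)
  expect_equal(pearson_chi_square(trial_fixture("table1-isi8-alcohol"))$df, 2)
  expect_equal(
    round(pearson_chi_square(trial_fixture("table1-isi8-smoking"))$statistic,
          2), 3.90)
  expect_equal(
    round(pearson_chi_square(
      trial_fixture("table1-isi8-sleep-aid"))$statistic, 2), 5.85)
})

test_that("change-score comparison handles shifts and degenerate spread", {
  x <- c(-2, -1, 0, 1, 2)
  same <- two_sample_t_change(x, x)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)
  # constant shift with zero within-group variance
  shifted <- two_sample_t_change(rep(3, 5), rep(1, 5))
  expect_equal(shifted$difference, 2)
  expect_equal(shifted$p_value, 0)
  expect_error(two_sample_t_change(1, c(1, 2)), "at least 2")
  # agrees with stats::t.test on ordinary data
  set.seed(8)
  a <- rnorm(30, -2.2, 4.3); b <- rnorm(28, -1.5, 4.7)
  res <- two_sample_t_change(a, b)
  ref <- t.test(a, b)
  expect_equal(res$p_value, ref$p.value)
  expect_equal(res$conf_int, unname(ref$conf.int))
})

test_that("CONSORT accounting derives dropout rates and guards counts", {
  res <- consort_accounting(
    applied = 215, eligible = 118,
    allocated = c(SPA = 62, control = 56),
    dropouts = c(SPA = 2, control = 0)
  )
  expect_equal(unname(res$dropout_rate["SPA"]), 3.2)
  expect_equal(unname(res$dropout_rate["control"]), 0.0)
  expect_equal(unname(res$analyzed["SPA"]), 60)
  expect_equal(res$flow$n[res$flow$stage == "analyzed.SPA"], 60)
  expect_error(
    consort_accounting(100, 100, c(SPA = 50, control = 50),
                       c(SPA = 51, control = 0)),
    "exceed"
  )
})
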