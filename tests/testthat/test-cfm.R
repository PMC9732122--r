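cro_cfm <- cfm_params("Crocosphaera", pmax = 2.04, m = 1.70)
cya_cfm <- cfm_params("Cyanothece", pmax = 3.09, m = 2.02)

test_that("growth law evaluates its limits and interior points", {
  expect_equal(growth_rate(cya_cfm, 0), -2.02)
  expect_equal(growth_rate(cya_cfm, 1), 3.09 - 2.02)
  expect_equal(growth_rate(cya_cfm, 0.3), 3.09 * 0.3 - 2.02)  # -1.093
  expect_error(growth_rate(cya_cfm, 1.2), class = "dzd_domain_error")
  expect_error(growth_rate(cya_cfm, -0.1), class = "dzd_domain_error")
})

test_that("growth is exactly linear in fN", {
  set.seed(5)
  f1 <- runif(50); f2 <- runif(50)
  expect_equal(growth_rate(cro_cfm, f1) + growth_rate(cro_cfm, f2),
               2 * growth_rate(cro_cfm, (f1 + f2) / 2),
               tolerance = 1e-14)
})

test_that("analytic crossover matches the measured-budget parameterization", {
  cx <- crossover_fN(cro_cfm, cya_cfm)
  expect_equal(cx$status, "crossover")
  expect_equal(cx$fN, (2.02 - 1.70) / (3.09 - 2.04), tolerance = 1e-12)
  expect_equal(cx$fN, 0.3048, tolerance = 1e-3)
  # brute-force sign change on a 1e-4 grid
  grid <- seq(0, 1, by = 1e-4)
  d <- growth_rate(cro_cfm, grid) - growth_rate(cya_cfm, grid)
  flip <- grid[which(diff(sign(d)) != 0)[1]]
  expect_lt(abs(cx$fN - flip), 1e-4 + 1e-12)
})

test_that("degenerate parameter pairs are classified", {
  expect_equal(crossover_fN(cro_cfm, cro_cfm)$status, "identical")
  parallel <- crossover_fN(cfm_params("a", 2, 1), cfm_params("b", 2, 1.5))
  expect_equal(parallel$status, "absent")
  outside <- crossover_fN(cfm_params("a", 1, 0.1), cfm_params("b", 2, 5))
  expect_equal(outside$status, "absent")
})

test_that("competition grid winner map has one transition at the crossover", {
  res <- run_competition(cro_cfm, cya_cfm, n_grid = 201L)
  runs <- rle(res$winner)
  expect_identical(runs$values[runs$values != "tie"],
                   c("Crocosphaera", "Cyanothece"))
  expect_lte(length(runs$values), 3L)  # at most one tie point between them
  cx <- attr(res, "crossover")
  switch_i <- max(which(res$winner == "Crocosphaera"))
  expect_lt(abs(res$fN[switch_i] - cx$fN), 1 / 200 + 1e-12)
})

test_that("identical species tie everywhere", {
  res <- run_competition(cro_cfm, cfm_params("clone", 2.04, 1.70),
                         n_grid = 21L)
  expect_true(all(res$winner == "tie"))
})

test_that("physiology-derived parameters preserve the measured ordering", {
  rep <- noise_free_report()
  params <- lapply(rep$physiology, cfm_from_physiology)
  expect_equal(params[[1]]$pmax, 2.04, tolerance = 1e-6)
  expect_equal(params[[1]]$m, 0.51 + 1.19, tolerance = 1e-6)
  expect_equal(params[[2]]$pmax, 3.09, tolerance = 1e-6)
  expect_equal(params[[2]]$m, 1.10 + 0.92, tolerance = 1e-6)
  expect_gt(params[[2]]$pmax, params[[1]]$pmax)
  expect_gt(params[[2]]$m, params[[1]]$m)
})
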