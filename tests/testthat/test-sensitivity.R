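test_that("the default perturbation grid spans the prescribed range", {
  g <- perturbation_grid()
  expect_length(g, 61)
  expect_equal(min(g), 0.001)
  expect_equal(max(g), 1000)
  expect_true(1 %in% g)
  expect_true(all(diff(g) > 0))
  expect_error(perturbation_grid(-1, 10), "grid_min")
})

test_that("curve summaries break ties toward the smallest perturbation", {
  fac <- c(0.01, 0.1, 1, 10, 100)
  flat <- glusim:::summarize_curve(fac, rep(0.4, 5), 0.4)
  expect_equal(flat$max_sensitivity, 0)
  expect_equal(flat$scale_factor, 1)
  tie <- glusim:::summarize_curve(fac, c(0.5, 0.4, 0.4, 0.5, 0.4), 0.4)
  expect_equal(tie$scale_factor, 10)  # 10 beats 0.01 in log distance
  s <- glusim:::summarize_curve(fac, c(0.4, 0.4, 0.10, 0.4, 0.134), 0.10)
  expect_equal(s$max_sensitivity, 3)
  expect_equal(s$scale_factor, 0.1)  # tie among {0.01, 0.1, 10}: log-nearest 1
})

test_that("yield 0.10 improving to 0.134 gives sensitivity 0.34", {
  s <- glusim:::summarize_curve(c(1, 1000), c(0.10, 0.134), 0.10)
  expect_equal(s$max_sensitivity, 0.34)
  expect_equal(s$scale_factor, 1000)
})

test_that("summarize_curve matches dense brute force on unimodal curves", {
  # closed-form unimodal yield in log-factor space
  g <- function(f) 0.3 + 0.1 * exp(-(log10(f) - 0.7)^2)
  grid <- perturbation_grid(points = 61)
  s <- glusim:::summarize_curve(as.numeric(grid), g(as.numeric(grid)), g(1))
  dense <- 10^seq(-3, 3, length.out = 10000)
  i <- which.max(g(dense))
  expect_equal((max(g(dense)) - g(1)) / g(1), s$max_sensitivity,
               tolerance = 1e-3)
  # argmax within one grid step (grid step = 0.1 decades)
  expect_lt(abs(log10(s$scale_factor) - log10(dense[i])), 0.1 + 1e-9)
})

toy <- NULL
toy_cfg <- sim_config(t_end = 60, output_interval = 10, rel_tol = 1e-9,
                      abs_tol = 1e-13, yield_basis = "titer")

test_that("sweep of the expression toy matches the closed-form yield", {
  toy <<- expression_toy()
  grid <- perturbation_grid(0.01, 100, points = 9)
  res <- sweep_gene(toy$network, flat_profile(60), toy_cfg, "prodA", grid)
  expected <- toy$yield_fn(as.numeric(grid), 60)
  expect_equal(res$curve$yield, expected, tolerance = 1e-6)
  # brute force on the closed form over a dense grid
  dense <- 10^seq(-2, 2, length.out = 10000)
  yd <- toy$yield_fn(dense, 60)
  bf_sens <- (max(yd) - toy$yield_fn(1, 60)) / toy$yield_fn(1, 60)
  expect_equal(res$max_sensitivity, bf_sens, tolerance = 1e-3)
  expect_lt(abs(log10(res$scale_factor) - log10(dense[which.max(yd)])),
            0.5 + 1e-9)  # within one grid step of the 9-point grid
})

test_that("a unit with no catalytic role yields a flat curve", {
  res <- sweep_gene(toy$network, flat_profile(60), toy_cfg, "nullB",
                    perturbation_grid(0.01, 100, points = 5))
  expect_equal(res$max_sensitivity, 0, tolerance = 1e-9)
  expect_equal(res$scale_factor, 1)
})

test_that("reported best yield is reproduced at the reported scale factor", {
  grid <- perturbation_grid(0.1, 10, points = 5)
  res <- sweep_gene(toy$network, flat_profile(60), toy_cfg, "prodA", grid)
  best <- max(res$curve$yield)
  re <- yield_metric(glusim::simulate(
    apply_copy_factor(toy$network, "prodA", res$scale_factor),
    flat_profile(60), toy_cfg))
  expect_equal(re, best, tolerance = 1e-12)
})

test_that("grid refinement never lowers the maximum sensitivity", {
  coarse <- perturbation_grid(0.01, 100, points = 5)
  fine <- perturbation_grid(0.01, 100, points = 13)  # superset of coarse
  expect_true(all(round(log10(as.numeric(coarse)), 9) %in%
                    round(log10(as.numeric(fine)), 9)))
  rc <- sweep_gene(toy$network, flat_profile(60), toy_cfg, "prodA", coarse)
  rf <- sweep_gene(toy$network, flat_profile(60), toy_cfg, "prodA", fine)
  expect_gte(rf$max_sensitivity, rc$max_sensitivity - 1e-12)
})

test_that("rank_all orders units by maximum sensitivity", {
  rk <- rank_all(toy$network, flat_profile(60), toy_cfg,
                 perturbation_grid(0.1, 10, points = 5))
  expect_s3_class(rk, "ranking_table")
  expect_equal(rk$rank, 1:2)
  expect_equal(rk$unit[1], "prodA")  # only prodA affects yield
  expect_gt(rk$max_sensitivity[1], 0)
  expect_equal(rk$max_sensitivity[2], 0, tolerance = 1e-9)
})

test_that("dose-response ratios are exactly 1 at factor 1", {
  dr <- dose_response(toy$network, flat_profile(60), toy_cfg, "prodA",
                      perturbation_grid(0.1, 10, points = 3),
                      observables = c("GLUxt", "P"))
  row1 <- dr[dr$factor == 1, ]
  expect_equal(row1$GLUxt, 1)
  expect_equal(row1$P, 1)
  expect_true(all(diff(dr$P) > 0))  # more dosage, more protein
  expect_error(dose_response(toy$network, flat_profile(60), toy_cfg,
                             "prodA", perturbation_grid(points = 3),
                             observables = "NOPE"), "NOPE")
})

test_that("snapshots at factor 1 return unit ratios everywhere defined", {
  snap <- snapshot_relative_changes(toy$network, flat_profile(60), toy_cfg,
                                    "prodA", 1)
  defined <- !is.na(snap$ratios)
  expect_true(all(abs(snap$ratios[defined] - 1) < 1e-12))
  expect_error(snapshot_relative_changes(toy$network, flat_profile(60),
                                         toy_cfg, "prodA", -2), "> 0")
})
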