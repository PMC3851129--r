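test_that("growth profiles derive mu from the biomass table", {
  gp <- growth_profile(c(0, 100, 200), c(1, 2, 2))
  expect_equal(unname(growth_at(gp, 0)["mu"]), 0.01)   # slope 0.01 / X 1
  expect_equal(unname(growth_at(gp, 150)["mu"]), 0)    # flat segment
  expect_equal(unname(growth_at(gp, 500)["X"]), 2)     # clamped
  expect_error(growth_profile(c(0, 0), c(1, 1)), "increasing")
  expect_error(growth_profile(c(0, 1), c(0, 1)), "> 0")
})

test_that("sim_config validates the output grid", {
  expect_error(sim_config(t_end = 840, output_interval = 13), "divide")
  cfg <- sim_config()
  expect_equal(cfg$t_end, 840)
  expect_equal(cfg$output_interval, 5)
})

test_that("the default grid has 169 output points with no drift", {
  tc <- ref_baseline()
  expect_length(tc$time, 169)
  expect_equal(tc$time, seq(0, 840, by = 5))
})

test_that("an empty system stays identically zero", {
  sp <- species_table(c("A", "B"), "metabolite", conc = 0)
  net <- build_network(model_definition(
    sp, list(reaction("r", c(A = -1, B = 1),
                      rate_law("mass_action", 1, c(A = 1))))))
  tc <- glusim::simulate(net, flat_profile(), sim_config(t_end = 100,
                                                         output_interval = 10))
  expect_true(all(tc$states == 0))
})

test_that("a closed toy network conserves total mass", {
  net <- closed_toy()
  tc <- glusim::simulate(net, flat_profile(X = 1e-12),
                         sim_config(t_end = 500, output_interval = 25,
                                    rel_tol = 1e-8, abs_tol = 1e-12))
  totals <- colSums(tc$states[c("A", "B", "C"), ])
  expect_lt(max(abs(totals - totals[1])) / totals[1], 1e-6)
})

test_that("assemble_odes reports derivatives, fluxes, and growth", {
  net <- closed_toy()
  f <- assemble_odes(net, flat_profile())
  d <- f(0, c(A = 2, B = 0.5, C = 0.1))
  expect_named(d, c("A", "B", "C"))
  expect_equal(sum(d), 0)  # closed network
  fl <- attr(d, "flux")
  expect_named(fl, c("ab", "bc"))
  # derivative equals S %*% v
  expect_equal(as.numeric(d), unname(drop(net$S %*% fl)))
  # fluxes agree with the reference R rate-law implementation
  v_ab <- mm_rate(net$reactions[["ab"]]$rate_law, 1, c(A = 2, B = 0.5))
  expect_equal(unname(fl["ab"]), v_ab, tolerance = 1e-12)
})

test_that("a numerically-found steady state has near-zero derivative", {
  # open chain: source -> M -> sink reaches steady state M* = k_in/k_out
  sp <- rbind(species_table("SRC", "boundary", conc = 2),
              species_table("M", "metabolite", conc = 0),
              species_table("SNK", "metabolite", "extracellular", conc = 0))
  rxs <- list(
    reaction("in", c(SRC = -1, M = 1), rate_law("mass_action", 0.3,
                                                c(SRC = 1))),
    reaction("out", c(M = -1, SNK = 1), rate_law("mass_action", 0.1,
                                                 c(M = 1))))
  net <- build_network(model_definition(sp, rxs))
  tc <- glusim::simulate(net, flat_profile(), sim_config(t_end = 400,
                                                         output_interval = 50))
  expect_equal(unname(tc$states["M", 9]), 6, tolerance = 1e-5)
  f <- assemble_odes(net, flat_profile())
  d <- f(400, tc$states[, 9])
  expect_lt(abs(d[["M"]]), 1e-6)
})

test_that("profiles shorter than the horizon are rejected", {
  net <- closed_toy()
  expect_error(glusim::simulate(net, growth_profile(c(0, 100), c(1, 1)),
                                sim_config(t_end = 840)),
               "does not cover")
})

test_that("no intracellular pool drops below tolerance on the reference run", {
  tc <- ref_baseline()
  expect_gt(min(tc$states), -100 * 1e-9)
})

test_that("knockout silences a unit and is idempotent with a warning", {
  ref <- ref_model()
  net <- ref$network
  expect_error(knockout(net, "nosuchgene"), "nosuchgene")
  net2 <- knockout(net, "pykF")
  i <- match("pykF", vapply(net2$genes, `[[`, "", "id"))
  expect_true(net2$genes[[i]]$knocked_out)
  expect_equal(net2$genes[[i]]$copy_factor, 0)
  expect_equal(net2$species$conc[net2$species$id == "PYKF"], 0)
  expect_warning(net3 <- knockout(net2, "pykF"), "already")
  expect_identical(net2, net3)
})

test_that("sucAB deletion leaves zero KGDH flux at all output times", {
  tc <- ref_baseline()
  expect_true(all(tc$fluxes["kgdh", ] == 0))
})

test_that("apply_copy_factor is exact at 1 and validates input", {
  ref <- ref_model()
  expect_error(apply_copy_factor(ref$network, "pykF", 0), "positive")
  expect_error(apply_copy_factor(ref$network, "nope", 2), "nope")
  n1 <- apply_copy_factor(ref$network, "pykF", 1)
  expect_identical(n1, ref$network)
})

test_that("yield metrics follow the molar and titer definitions", {
  # two-way split: 40% of consumed substrate becomes product
  sp <- rbind(species_table(c("GLCxt", "GLUxt", "W"), "metabolite",
                            "extracellular", conc = c(20, 0, 0)))
  rxs <- list(
    reaction("p", c(GLCxt = -1, GLUxt = 1),
             rate_law("mass_action", 0.04, c(GLCxt = 1))),
    reaction("w", c(GLCxt = -1, W = 1),
             rate_law("mass_action", 0.06, c(GLCxt = 1))))
  net <- build_network(model_definition(sp, rxs))
  tc <- glusim::simulate(net, flat_profile(),
                         sim_config(t_end = 100, output_interval = 10,
                                    rel_tol = 1e-9, abs_tol = 1e-12))
  expect_equal(yield_metric(tc), 0.4, tolerance = 1e-7)
  expect_equal(yield_metric(tc, basis = "titer"),
               unname(tc$states["GLUxt", 11]))
  # full conversion gives yield 1
  net1 <- build_network(model_definition(sp, rxs[1]))
  tc1 <- glusim::simulate(net1, flat_profile(),
                          sim_config(t_end = 100, output_interval = 10))
  expect_equal(yield_metric(tc1), 1, tolerance = 1e-6)
  # nothing consumed: undefined yield
  net0 <- build_network(model_definition(sp))
  tc0 <- glusim::simulate(net0, flat_profile(),
                          sim_config(t_end = 50, output_interval = 10))
  expect_error(yield_metric(tc0), "consumed")
})

test_that("baseline glutamate accumulates monotonically after a lag", {
  tc <- ref_baseline()
  glu <- tc$states["GLUxt", ]
  expect_true(all(diff(glu[20:169]) > 0))
  expect_gt(glu[169], 10)
})
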