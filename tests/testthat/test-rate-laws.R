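test_that("irreversible MM rates follow the saturation-product convention", {
  law <- rate_law("irreversible_mm", kcat = 10, Km = c(S = 0.5))
  expect_equal(mm_rate(law, 0.5, c(S = 0)), 0)
  expect_equal(mm_rate(law, 0.5, c(S = 0.5)), 2.5)  # half saturation
  # two substrates: product of independent saturation terms
  law2 <- rate_law("irreversible_mm", kcat = 10, Km = c(S1 = 0.5, S2 = 2))
  expect_equal(mm_rate(law2, 0.5, c(S1 = 0.5, S2 = 2)), 10 * 0.5 * 0.25)
  expect_equal(mm_rate(law2, 0.5, c(S1 = 0.5, S2 = 0)), 0)
})

test_that("inhibition multiplies the rate hyperbolically", {
  law <- rate_law("irreversible_mm", kcat = 10, Km = c(S = 0.5),
                  inhibitors = data.frame(species = "I", Ki = 2))
  expect_equal(mm_rate(law, 0.5, c(S = 0.5, I = 0)), 2.5)
  expect_equal(mm_rate(law, 0.5, c(S = 0.5, I = 2)), 1.25)
  expect_equal(inhibition_factor(0, 3), 1)
  expect_equal(inhibition_factor(3, 3), 0.5)
  expect_equal(inhibition_factor(27, 3), 0.1)  # 1/(1+9)
  expect_error(inhibition_factor(1, -1), "Ki")
})

test_that("inhibition_factor is strictly decreasing and bounded", {
  x <- sort(runif(50, 0, 100))
  f <- inhibition_factor(x, 2.5)
  expect_true(all(diff(f) < 0))
  expect_true(all(f > 0 & f <= 1))
})

test_that("reversible MM vanishes at equilibrium and respects direction", {
  law <- rate_law("reversible_mm", kcat = 10, Km = c(S = 0.5),
                  Km_products = c(P = 1), Keq = 4)
  # at P/S = Keq the net rate is zero
  expect_equal(mm_rate(law, 1, c(S = 1, P = 4)), 0)
  expect_gt(mm_rate(law, 1, c(S = 1, P = 1)), 0)
  expect_lt(mm_rate(law, 1, c(S = 1, P = 8)), 0)
})

test_that("mm_rate is monotone in substrate and enzyme concentration", {
  law <- rate_law("irreversible_mm", kcat = 7, Km = c(S = 1.3))
  s <- seq(0, 10, length.out = 40)
  v <- vapply(s, function(x) mm_rate(law, 0.2, c(S = x)), 0)
  expect_true(all(diff(v) >= 0))
  e <- seq(0, 5, length.out = 20)
  ve <- vapply(e, function(x) mm_rate(law, x, c(S = 2)), 0)
  expect_true(all(diff(ve) >= 0))
})

test_that("rate law constructors validate their inputs", {
  expect_error(rate_law("irreversible_mm", kcat = -1, Km = c(S = 1)), "kcat")
  expect_error(rate_law("irreversible_mm", kcat = 1, Km = c(S = -2)), "Km")
  expect_error(rate_law("reversible_mm", kcat = 1, Km = c(S = 1)), "Keq")
  expect_error(mm_rate(rate_law("irreversible_mm", 1, c(S = 1)), 1,
                       c(X = 2)), "missing concentration")
  expect_error(mm_rate(rate_law("irreversible_mm", 1, c(S = 1)), 1,
                       c(S = -1)), ">= 0")
})

test_that("modification cycle fluxes conserve target + modified form", {
  cyc <- modification_cycle("ICD", "ICDP", "ICDK", k_kin = 5, k_phos = 2,
                            Km_target = 0.1, Km_modified = 0.1,
                            kinase_inhibitor = "3PG", Ki_inh = 1)
  for (pg in c(0, 0.5, 3, 50)) {
    fl <- modification_fluxes(cyc, c(ICD = 0.3, ICDP = 0.2, ICDK = 0.1,
                                     `3PG` = pg))
    d_target <- fl[["phosphatase"]] - fl[["kinase"]]
    d_mod <- fl[["kinase"]] - fl[["phosphatase"]]
    expect_equal(d_target + d_mod, 0)
  }
})

test_that("full kinase inhibition drives the cycle to the unmodified state", {
  cyc <- modification_cycle("T", "TP", "K", k_kin = 5, k_phos = 2,
                            kinase_inhibitor = "I", Ki_inh = 1)
  fl <- modification_fluxes(cyc, c(T = 0.5, TP = 0.5, K = 0.1, I = 1e9))
  expect_lt(fl[["kinase"]], 1e-8)
  expect_gt(fl[["phosphatase"]], 0)
})

test_that("symmetric first-order cycle balances at the analytic fraction", {
  # k_kin = k_phos, inhibitor at Ki halves the kinase: steady state has
  # kinase flux = phosphatase flux at unmodified fraction 2/3
  cyc <- modification_cycle("T", "TP", "K", k_kin = 4, k_phos = 4,
                            kinase_inhibitor = "I", Ki_inh = 2)
  st <- c(T = 2 / 3, TP = 1 / 3, K = 0.1, I = 2)
  fl <- modification_fluxes(cyc, st)
  expect_equal(fl[["kinase"]], fl[["phosphatase"]])
  # no inhibitor, symmetric rates: balance at equal pools
  cyc0 <- modification_cycle("T", "TP", "K", k_kin = 4, k_phos = 4,
                             Km_target = 0.5, Km_modified = 0.5)
  fl0 <- modification_fluxes(cyc0, c(T = 1, TP = 1, K = 0.1))
  expect_equal(fl0[["kinase"]], fl0[["phosphatase"]])
})
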