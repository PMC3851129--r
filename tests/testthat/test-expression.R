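mach <- machinery_profile(mu = c(0, 0.01, 0.02), RNAP = c(1, 2, 4),
                          ribosome = c(2, 6, 10), K_RNAP = 1, K_ribo = 2)

test_that("machinery interpolation hits knots, midpoints, and clamps", {
  expect_equal(machinery_at(mach, 0.01), c(RNAP = 2, ribosome = 6))
  expect_equal(machinery_at(mach, 0.005), c(RNAP = 1.5, ribosome = 4))
  expect_equal(machinery_at(mach, 0.5), c(RNAP = 4, ribosome = 10))
  expect_equal(machinery_at(mach, 0), c(RNAP = 1, ribosome = 2))
  expect_error(machinery_profile(numeric(), numeric(), numeric(), 1, 1),
               "empty")
  expect_error(machinery_profile(c(0, 0.01), c(2, 1), c(1, 2), 1, 1),
               "non-decreasing")
})

unit <- gene_unit("g", "P", promoter_conc = 1e-4, k_tx = 8, mRNA_deg = 0.2,
                  k_tl = 30, protein_deg = 0.01)

test_that("transcription is linear in gene dosage", {
  r1 <- transcription_rate(unit, RNAP_conc = 2)
  u0 <- unit; u0$copy_factor <- 0
  expect_equal(transcription_rate(u0, 2), 0)
  u2 <- unit; u2$copy_factor <- 2
  expect_equal(transcription_rate(u2, 2), 2 * r1)
  u10 <- unit; u10$copy_factor <- 10
  expect_equal(transcription_rate(u10, 2), 10 * r1)
})

test_that("a repressor at its binding constant halves transcription", {
  reg <- data.frame(tf = "R", mode = "repressor", K_bind = 0.5)
  ur <- gene_unit("g2", "P", 1e-4, k_tx = 8, mRNA_deg = 0.2, k_tl = 30,
                  protein_deg = 0.01, regulators = reg)
  free <- transcription_rate(unit, 2)
  expect_equal(transcription_rate(ur, 2, tf_concs = list(R = 0.5)), free / 2)
  # effector that inactivates the repressor restores transcription
  reg2 <- data.frame(tf = "R", mode = "repressor", K_bind = 0.5,
                     effector = "E", effector_mode = "inactivates",
                     K_eff = 0.1)
  ur2 <- gene_unit("g3", "P", 1e-4, k_tx = 8, mRNA_deg = 0.2, k_tl = 30,
                   protein_deg = 0.01, regulators = reg2)
  lo <- transcription_rate(ur2, 2, list(R = 0.5), list(E = 0))
  hi <- transcription_rate(ur2, 2, list(R = 0.5), list(E = 100))
  expect_equal(lo, free / 2)
  expect_gt(hi, 0.99 * free)
})

test_that("translation saturates in ribosome level and is shared by operons", {
  expect_equal(translation_rate(unit, 0, 5), 0)
  expect_equal(translation_rate(unit, 0.3, 1e9, K_ribo = 2), 30 * 0.3,
               tolerance = 1e-8)
  op <- gene_unit("op", c("P1", "P2"), 1e-4, k_tx = 8, mRNA_deg = 0.2,
                  k_tl = 30, protein_deg = 0.01)
  st <- c(mRNA_op = 0.2, P1 = 1, P2 = 3)
  d <- expression_odes(op, st, mu = 0.01, machinery = mach)
  # both member proteins receive the same synthesis term
  syn <- d$proteins + (0.01 + 0.01) * st[c("P1", "P2")]
  expect_equal(unname(syn[1]), unname(syn[2]))
})

test_that("expression derivatives follow synthesis minus loss", {
  st <- c(mRNA_g = 0.1, P = 2)
  d <- expression_odes(unit, st, mu = 0.005, machinery = mach)
  m <- machinery_at(mach, 0.005)
  tx <- transcription_rate(unit, m[["RNAP"]], K_RNAP = 1)
  tl <- translation_rate(unit, 0.1, m[["ribosome"]], K_ribo = 2)
  expect_equal(d$mRNA, tx - (0.2 + 0.005) * 0.1)
  expect_equal(unname(d$proteins["P"]), tl - (0.01 + 0.005) * 2)
  # quiescent state: no synthesis, no degradation, no growth
  uq <- gene_unit("q", "P", promoter_conc = 0, k_tx = 0, mRNA_deg = 0,
                  k_tl = 0, protein_deg = 0)
  dq <- expression_odes(uq, c(mRNA_q = 0, P = 0), 0, mach)
  expect_equal(dq$mRNA, 0)
  expect_equal(unname(dq$proteins["P"]), 0)
})

test_that("steady-state protein level is proportional to copy factor", {
  # closed form: p_ss = k_tl sat(ribo) m_ss / (pdeg + mu), with
  # m_ss = k_tx prom cf sat(RNAP) / (mdeg + mu) -- linear in cf
  mu <- 0.004
  m <- machinery_at(mach, mu)
  p_ss <- function(cf) {
    u <- unit; u$copy_factor <- cf
    m_ss <- transcription_rate(u, m[["RNAP"]], K_RNAP = 1) /
      (u$mRNA_deg + mu)
    translation_rate(u, m_ss, m[["ribosome"]], K_ribo = 2) /
      (u$protein_deg + mu)
  }
  expect_equal(p_ss(10) / p_ss(1), 10, tolerance = 1e-12)
  expect_equal(p_ss(0.001) / p_ss(1), 0.001, tolerance = 1e-12)
})
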