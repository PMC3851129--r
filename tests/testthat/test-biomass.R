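# independent least-squares oracle for branch combination: solve the
# stacked system (one identity block per route) by QR
combine_oracle <- function(routes, target) {
  exprs <- lapply(routes, function(st) -st[setdiff(names(st), target)])
  species <- unique(unlist(lapply(exprs, names)))
  A <- do.call(rbind, rep(list(diag(length(species))), length(exprs)))
  b <- unlist(lapply(exprs, function(e) {
    v <- setNames(numeric(length(species)), species)
    v[names(e)] <- e
    v
  }), use.names = FALSE)
  setNames(qr.solve(qr(A), b), species)
}

test_that("the two S7P-forming routes combine to the printed coefficients", {
  routes <- list(c(E4P = -1, F6P = -1, GA3P = 1, S7P = 1),
                 c(X5P = -1, R5P = -1, GA3P = 1, S7P = 1))
  bc <- combine_branch_routes(routes, "S7P")
  expect_equal(bc$coefficients[c("E4P", "GA3P", "R5P", "F6P", "X5P")],
               c(E4P = 0.5, GA3P = -1, R5P = 0.5, F6P = 0.5, X5P = 0.5))
})

test_that("single routes and symmetric multi-route systems behave", {
  one <- combine_branch_routes(list(c(A = -1, B = 1)), "B")
  expect_equal(one$coefficients, c(A = 1))
  three <- combine_branch_routes(list(c(A = -1, T = 1), c(B = -1, T = 1),
                                      c(C = -1, T = 1)), "T")
  expect_equal(three$coefficients, c(A = 1, B = 1, C = 1) / 3)
  expect_error(combine_branch_routes(list(), "T"), "empty")
  expect_error(combine_branch_routes(list(c(A = -1, T = 2)), "T"),
               "exactly one unit")
})

test_that("branch combination agrees with the least-squares oracle", {
  set.seed(42)
  pool <- paste0("M", 1:6)
  for (rep in 1:20) {
    nroutes <- sample(2:4, 1)
    routes <- lapply(seq_len(nroutes), function(i) {
      k <- sample(2:4, 1)
      st <- setNames(round(runif(k, -3, 3), 2), sample(pool, k))
      st <- st[st != 0]
      c(st, TGT = 1)
    })
    bc <- combine_branch_routes(routes, "TGT")
    oracle <- combine_oracle(routes, "TGT")
    oracle <- oracle[oracle != 0]
    expect_equal(bc$coefficients[sort(names(bc$coefficients))],
                 oracle[sort(names(oracle))], tolerance = 1e-10)
  }
})

test_that("precursor table validation enforces the revised sign semantics", {
  good <- ref_biomass_table()
  expect_equal(nrow(validate_precursor_table(good)), 0)
  bad_fum <- good
  bad_fum$coefficient[bad_fum$species == "FUM"] <- -0.1
  v <- validate_precursor_table(bad_fum)
  expect_equal(nrow(v), 1)
  expect_equal(v$species, "FUM")
  no_s7p <- good[good$species != "S7P", ]
  v2 <- validate_precursor_table(no_s7p)
  expect_true(any(grepl("branch-point", v2$message)))
  # pre-revision pattern: negative OAA and FUM both flagged
  pre <- good
  pre$coefficient[pre$species %in% c("OAA", "FUM")] <- -0.5
  expect_equal(sort(validate_precursor_table(pre)$species), c("FUM", "OAA"))
})

test_that("side-reaction stoichiometries match the revised equations", {
  eqA <- side_reaction_stoich("eqA")
  expect_equal(eqA[["CO2"]], 4)
  expect_equal(eqA[["NADH"]], 6)
  expect_equal(eqA[["NAD"]], -6)
  expect_equal(eqA[["FADH"]], 2)
  expect_equal(eqA[["ATP"]], 2)
  expect_equal(eqA[["ADP"]], -2)
  expect_equal(eqA[["Pi"]], -2)
  expect_equal(eqA[["ARGSUC"]], -1)
  expect_equal(eqA[["ARG"]], 1)
  eqB <- side_reaction_stoich("eqB")
  expect_equal(unname(eqB[c("SAICAR", "AICAR", "CO2", "NADH")]),
               c(-1, 1, 4, 6))
  gly <- side_reaction_stoich("glycogen")
  expect_equal(gly[["G6P"]], -8)
  expect_equal(gly[["ATP"]], -8)
  expect_equal(gly[["GLYCOGEN"]], 1)
})

test_that("apply_side_reactions installs the stoichiometry columns", {
  sp <- species_table(c("ARGSUC", "ARG", "SAICAR", "AICAR", "CO2", "NAD",
                        "NADH", "FAD", "FADH", "ADP", "Pi", "ATP", "G6P",
                        "GLYCOGEN"), "metabolite", conc = 1)
  net <- build_network(model_definition(sp))
  net2 <- apply_side_reactions(net)
  expect_equal(net2$S["CO2", "eqA"], 4)
  expect_equal(net2$S["NADH", "eqA"], 6)
  expect_equal(net2$S["G6P", "glycogen"], -8)
  expect_equal(net2$S["ATP", "glycogen"], -8)
  # missing cofactors are reported
  small <- build_network(model_definition(
    species_table(c("ARGSUC", "ARG"), "metabolite", conc = 1)))
  expect_error(apply_side_reactions(small, "eqA"), "missing species")
})

test_that("biomass drains scale with coefficient, growth rate, and density", {
  tb <- data.frame(species = c("A", "B"), coefficient = c(1, -0.5))
  expect_equal(biomass_drain(tb, 0, 5), c(A = 0, B = 0))
  expect_equal(biomass_drain(tb, 0.01, 1), c(A = 0.01, B = -0.005))
  expect_equal(biomass_drain(tb, 0.01, 2), 2 * biomass_drain(tb, 0.01, 1))
  expect_error(biomass_drain(tb, -1, 1), ">= 0")
})
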