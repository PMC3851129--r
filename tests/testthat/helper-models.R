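# Shared fixtures, built in code.

# cache expensive objects across test files within one run
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

ref_model <- function() cached("ref", build_reference_model())

# fast solver settings used for reference-model runs in tests; yield on
# the titer basis, which is what the reference sensitivity analysis uses
ref_cfg <- function(...) sim_config(rel_tol = 1e-4, abs_tol = 1e-9,
                                    yield_basis = "titer", ...)

ref_baseline <- function() cached("ref_tc", {
  ref <- ref_model()
  glusim::simulate(ref$network, ref$profile, ref_cfg())
})

# three-species closed chain A <-> B <-> C with mass conservation
closed_toy <- function(kab = 0.2, kbc = 0.1) {
  sp <- species_table(c("A", "B", "C"), role = "metabolite",
                      conc = c(2, 0.5, 0.1))
  rxs <- list(
    reaction("ab", c(A = -1, B = 1),
             rate_law("reversible_mm", kab, Km = c(A = 1),
                      Km_products = c(B = 1), Keq = 2)),
    reaction("bc", c(B = -1, C = 1),
             rate_law("reversible_mm", kbc, Km = c(B = 1),
                      Km_products = c(C = 1), Keq = 0.5)))
  build_network(model_definition(sp, rxs))
}

flat_profile <- function(t_end = 2000, X = 1)
  growth_profile(c(0, t_end), c(X, X))

# linear expression toy with closed-form yield curve: one gene unit makes
# protein P catalysing GLCxt -> GLUxt (mass action); no degradation, mu=0,
# so m(t) = a f t, p(t) = b f t^2/2 and
# titer(T) = M0 (1 - exp(-kcat b f T^3 / 6)).
expression_toy <- function(M0 = 10, k_tx = 0.02, prom = 1e-3, k_tl = 0.05,
                           kcat = 5) {
  sp <- rbind(
    species_table("GLCxt", "metabolite", "extracellular", conc = M0),
    species_table("GLUxt", "metabolite", "extracellular", conc = 0),
    species_table(c("P", "Q"), "protein", conc = 0),
    species_table(c("mRNA_prodA", "mRNA_nullB"), "mRNA", conc = 0))
  rxs <- list(reaction("conv", c(GLCxt = -1, GLUxt = 1),
                       rate_law("mass_action", kcat, Km = c(GLCxt = 1)),
                       catalyst = "P"))
  genes <- list(
    gene_unit("prodA", "P", promoter_conc = prom, k_tx = k_tx,
              mRNA_deg = 0, k_tl = k_tl, protein_deg = 0),
    gene_unit("nullB", "Q", promoter_conc = prom, k_tx = k_tx,
              mRNA_deg = 0, k_tl = k_tl, protein_deg = 0))
  mach <- machinery_profile(0, 1, 1, K_RNAP = 1, K_ribo = 1)
  net <- build_network(model_definition(sp, rxs, genes = genes,
                                        machinery = mach))
  # closed-form titer: sat(RNAP) = sat(ribo) = 1/2 at these settings
  a <- k_tx * prom * 0.5
  b <- k_tl * 0.5 * a
  yield_fn <- function(f, T) M0 * (1 - exp(-kcat * b * f * T^3 / 6))
  list(network = net, yield_fn = yield_fn, M0 = M0)
}
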