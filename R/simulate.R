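#' Prescribed fed-batch growth profile
#'
#' Biomass density X(t) is an input of the simulation (growth is
#' prescribed, not emergent): the specific growth rate is derived as
#' `mu(t) = X'(t)/X(t)` from the piecewise-linear interpolant of the
#' table and clamped at 0 where the profile is flat or decreasing.
#'
#' @param t time knots (min), strictly increasing.
#' @param X biomass density at each knot (g dry weight / L), `> 0`.
#' @return an object of class `growth_profile`.
#' @export
growth_profile <- function(t, X) {
  stopifnot(length(t) == length(X), length(t) >= 1)
  if (is.unsorted(t, strictly = TRUE))
    stop("profile times must be strictly increasing", call. = FALSE)
  if (any(X <= 0)) stop("biomass density must be > 0", call. = FALSE)
  structure(list(t = as.numeric(t), X = as.numeric(X)),
            class = "growth_profile")
}

#' Biomass density and specific growth rate at a time point
#' @param profile a [growth_profile()].
#' @param t time (min); clamped to the table range.
#' @return named vector `c(X = , mu = )`.
#' @export
growth_at <- function(profile, t) {
  stopifnot(inherits(profile, "growth_profile"))
  k <- length(profile$t)
  if (k == 1L || t >= profile$t[k])
    return(c(X = profile$X[if (t >= profile$t[k]) k else 1], mu = 0))
  tt <- max(t, profile$t[1])
  i <- findInterval(tt, profile$t, rightmost.closed = TRUE)
  slope <- (profile$X[i + 1] - profile$X[i]) / (profile$t[i + 1] - profile$t[i])
  X <- profile$X[i] + slope * (tt - profile$t[i])
  c(X = X, mu = max(slope / X, 0))
}

#' Simulation configuration
#'
#' @param t_end simulation horizon (min); the fermentation default is 840.
#' @param output_interval output grid spacing (min); must divide `t_end`.
#'   Default 5, giving 169 output points over the default horizon.
#' @param rel_tol,abs_tol integrator tolerances.
#' @param max_steps integration step budget before aborting.
#' @param yield_basis `"molar"` (mol product per mol substrate consumed,
#'   the default) or `"titer"` (final product concentration).
#' @param feed_rate constant substrate feed (mM/min) active on
#'   `[0, feed_end]`; 0 disables feeding.
#' @param feed_end end of the feeding window (min).
#' @param feed_species species receiving the feed.
#' @param drain_eps half-saturation (mM) of the hyperbolic switch that
#'   shuts biomass drains off as a precursor pool empties; 0 recovers
#'   strictly linear drains.
#' @param seed reserved for stochastic extensions; unused by the
#'   deterministic solver.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(t_end = 840, output_interval = 5,
                       rel_tol = 1e-6, abs_tol = 1e-9,
                       max_steps = 2000000L,
                       yield_basis = c("molar", "titer"),
                       feed_rate = 0, feed_end = 0,
                       feed_species = "GLCxt", drain_eps = 3e-4,
                       seed = NULL) {
  stopifnot(t_end > 0, output_interval > 0, rel_tol > 0, abs_tol > 0)
  if (abs(t_end / output_interval - round(t_end / output_interval)) > 1e-9)
    stop("output_interval must divide t_end", call. = FALSE)
  structure(list(t_end = t_end, output_interval = output_interval,
                 rel_tol = rel_tol, abs_tol = abs_tol,
                 max_steps = as.integer(max_steps),
                 yield_basis = match.arg(yield_basis),
                 feed_rate = feed_rate, feed_end = feed_end,
                 feed_species = feed_species, drain_eps = drain_eps,
                 seed = seed),
            class = "sim_config")
}

# Flatten a validated network + profile into the index-vector layout the
# compiled engine consumes (0-based indices, CSR pointers).
compile_network <- function(network, profile, config = sim_config()) {
  sp <- network$species
  idx <- function(ids) {
    i <- match(ids, sp$id)
    if (anyNA(i)) stop("unresolved species: ",
                       paste(ids[is.na(i)], collapse = ", "), call. = FALSE)
    i - 1L
  }
  csr <- function(lst) {
    lens <- vapply(lst, length, 0L)
    list(ptr = as.integer(c(0L, cumsum(lens))),
         val = if (sum(lens)) unlist(lst, use.names = FALSE) else numeric())
  }

  rxs <- network$reactions
  law_code <- c(irreversible_mm = 0L, reversible_mm = 1L, mass_action = 2L)
  sub_idx <- lapply(rxs, function(r) idx(names(r$rate_law$Km)))
  sub_km <- lapply(rxs, function(r) unname(as.numeric(r$rate_law$Km)))
  prod_idx <- lapply(rxs, function(r) idx(names(r$rate_law$Km_products)))
  prod_km <- lapply(rxs, function(r) unname(as.numeric(r$rate_law$Km_products)))
  inh_idx <- lapply(rxs, function(r)
    if (is.null(r$rate_law$inhibitors)) integer()
    else idx(r$rate_law$inhibitors$species))
  inh_ki <- lapply(rxs, function(r)
    if (is.null(r$rate_law$inhibitors)) numeric()
    else as.numeric(r$rate_law$inhibitors$Ki))
  st_idx <- lapply(rxs, function(r) idx(names(r$stoichiometry)))
  st_coef <- lapply(rxs, function(r) unname(as.numeric(r$stoichiometry)))

  genes <- network$genes
  regs <- lapply(genes, function(g)
    if (is.null(g$regulators))
      data.frame(tf = character(), mode = character(), K_bind = numeric(),
                 effector = character(), effector_mode = character(),
                 K_eff = numeric())
    else g$regulators)

  mach <- network$machinery
  if (length(genes) && is.null(mach))
    stop("a machinery profile is required when gene units are present",
         call. = FALSE)
  if (is.null(mach))
    mach <- list(table = data.frame(mu = 0, RNAP = 0, ribosome = 0),
                 K_RNAP = 1, K_ribo = 1)

  bm <- network$biomass
  if (!is.null(bm)) {
    keep <- !sp$constant[match(bm$species, sp$id)]  # boundary never drained
    bm <- bm[keep, , drop = FALSE]
  }

  feed_idx <- -1L
  if (config$feed_rate > 0) feed_idx <- idx(config$feed_species)

  si <- csr(sub_idx); sk <- csr(sub_km)
  pi_ <- csr(prod_idx); pk <- csr(prod_km)
  ii <- csr(inh_idx); ik <- csr(inh_ki)
  ti <- csr(st_idx); tc <- csr(st_coef)
  gp <- csr(lapply(genes, function(g) idx(g$member_proteins)))
  gr_tf <- csr(lapply(regs, function(r) idx(r$tf)))
  gr_eff <- csr(lapply(regs, function(r) {
    if (!nrow(r)) return(integer())
    out <- rep(-1L, nrow(r))
    has <- !is.na(r$effector)
    out[has] <- idx(r$effector[has])
    out
  }))

  list(
    y0 = sp$conc,
    species = sp$id,
    constant = as.integer(sp$constant),
    dilute = as.integer(sp$compartment == "intracellular" & !sp$constant),
    rx_law = unname(law_code[vapply(rxs, function(r) r$rate_law$form, "")]),
    rx_kcat = vapply(rxs, function(r) r$rate_law$kcat, 0),
    rx_keq = vapply(rxs, function(r)
      if (is.na(r$rate_law$Keq)) 1 else r$rate_law$Keq, 0),
    rx_cat = vapply(rxs, function(r)
      if (is.na(r$catalyst)) -1L else idx(r$catalyst), 0L),
    sub_ptr = si$ptr, sub_idx = as.integer(si$val), sub_km = sk$val,
    prod_ptr = pi_$ptr, prod_idx = as.integer(pi_$val), prod_km = pk$val,
    inh_ptr = ii$ptr, inh_idx = as.integer(ii$val), inh_ki = ik$val,
    st_ptr = ti$ptr, st_idx = as.integer(ti$val), st_coef = tc$val,
    cy_t = vapply(network$cycles, function(c) idx(c$target), 0L),
    cy_m = vapply(network$cycles, function(c) idx(c$modified_form), 0L),
    cy_c = vapply(network$cycles, function(c) idx(c$converter), 0L),
    cy_inh = vapply(network$cycles, function(c)
      if (is.na(c$kinase_inhibitor)) -1L else idx(c$kinase_inhibitor), 0L),
    cy_kkin = vapply(network$cycles, `[[`, 0, "k_kin"),
    cy_kphos = vapply(network$cycles, `[[`, 0, "k_phos"),
    cy_kmt = vapply(network$cycles, `[[`, 0, "Km_target"),
    cy_kmm = vapply(network$cycles, `[[`, 0, "Km_modified"),
    cy_ki = vapply(network$cycles, function(c)
      if (is.na(c$Ki_inh)) 1 else c$Ki_inh, 0),
    g_mrna = vapply(genes, function(g) idx(g$mRNA), 0L),
    g_prom = vapply(genes, `[[`, 0, "promoter_conc"),
    g_cf = vapply(genes, `[[`, 0, "copy_factor"),
    g_ktx = vapply(genes, `[[`, 0, "k_tx"),
    g_mdeg = vapply(genes, `[[`, 0, "mRNA_deg"),
    g_ktl = vapply(genes, `[[`, 0, "k_tl"),
    g_pdeg = vapply(genes, `[[`, 0, "protein_deg"),
    gp_ptr = gp$ptr, gp_idx = as.integer(gp$val),
    gr_ptr = gr_tf$ptr, gr_tf = as.integer(gr_tf$val),
    gr_mode = as.integer(unlist(lapply(regs, function(r)
      as.integer(r$mode == "activator")), use.names = FALSE) %||% integer()),
    gr_eff = as.integer(gr_eff$val),
    gr_effmode = as.integer(unlist(lapply(regs, function(r)
      as.integer(!is.na(r$effector_mode) & r$effector_mode == "activates")),
      use.names = FALSE) %||% integer()),
    gr_K = unlist(lapply(regs, function(r) as.numeric(r$K_bind)),
                  use.names = FALSE) %||% numeric(),
    gr_keff = unlist(lapply(regs, function(r)
      ifelse(is.na(r$K_eff), 1, r$K_eff)), use.names = FALSE) %||% numeric(),
    mach_mu = mach$table$mu, mach_rnap = mach$table$RNAP,
    mach_ribo = mach$table$ribosome,
    k_rnap = mach$K_RNAP, k_ribo = mach$K_ribo,
    prof_t = profile$t, prof_x = profile$X,
    bm_idx = if (is.null(bm)) integer() else idx(bm$species),
    bm_coef = if (is.null(bm)) numeric() else as.numeric(bm$coefficient),
    bm_eps = config$drain_eps,
    feed_idx = feed_idx, feed_rate = config$feed_rate,
    feed_end = config$feed_end)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Assemble the full ODE derivative function
#'
#' Combines reaction fluxes, modification cycles, the expression layer,
#' biomass drains, feeding, and growth dilution into a single derivative
#' function of `(t, state)`, backed by the compiled engine.
#'
#' @param network a validated `reaction_network`.
#' @param profile a [growth_profile()] covering the simulation horizon.
#' @param biomass_table optional precursor table overriding the one in
#'   the network.
#' @param config a [sim_config()] (used for feed settings).
#' @return a function `f(t, state)` returning the named derivative
#'   vector, with the per-reaction flux vector attached as attribute
#'   `"flux"`.
#' @export
assemble_odes <- function(network, profile, biomass_table = NULL,
                          config = sim_config()) {
  if (!is.null(biomass_table)) network$biomass <- biomass_table
  cm <- compile_network(network, profile, config)
  ids <- network$species$id
  rids <- vapply(network$reactions, `[[`, "", "id")
  function(t, state) {
    y <- if (!is.null(names(state))) state[ids] else state
    out <- .engine_rhs(cm, t, as.numeric(y))
    d <- setNames(out$dy, ids)
    attr(d, "flux") <- setNames(out$flux, rids)
    attr(d, "mu") <- out$mu
    attr(d, "X") <- out$X
    d
  }
}

#' Simulate a network over the fermentation horizon
#'
#' Integrates the assembled ODE system with the adaptive L-stable
#' Rosenbrock solver and samples states and reaction fluxes on the
#' uniform output grid.
#'
#' @param network a validated `reaction_network`.
#' @param profile a [growth_profile()]; must cover `[0, t_end]`.
#' @param config a [sim_config()].
#' @return an object of class `glusim_timecourse` with elements `time`,
#'   `states` (species x time), `fluxes` (reaction x time), `config`,
#'   and solver statistics.
#' @export
simulate <- function(network, profile, config = sim_config()) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(profile, "growth_profile"),
            inherits(config, "sim_config"))
  if (max(profile$t) < config$t_end)
    stop("growth profile (to t=", max(profile$t),
         ") does not cover the simulation horizon t_end=", config$t_end,
         call. = FALSE)
  times <- seq(0, config$t_end, by = config$output_interval)
  cm <- compile_network(network, profile, config)
  out <- .engine_simulate(cm, times, config$rel_tol, config$abs_tol,
                          config$max_steps)
  states <- out$states
  dimnames(states) <- list(network$species$id, NULL)
  fluxes <- out$fluxes
  rids <- vapply(network$reactions, `[[`, "", "id")
  if (length(rids)) {
    fluxes <- fluxes[seq_along(rids), , drop = FALSE]
    dimnames(fluxes) <- list(rids, NULL)
  }
  neg <- which(states < -100 * config$abs_tol, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative concentration beyond tolerance for species: ",
         paste(unique(rownames(states)[neg[, 1]]), collapse = ", "),
         call. = FALSE)
  structure(list(time = times, states = states, fluxes = fluxes,
                 config = config, nsteps = out$nsteps,
                 nreject = out$nreject),
            class = "glusim_timecourse")
}

#' @export
print.glusim_timecourse <- function(x, ...) {
  cat("<glusim_timecourse> ", nrow(x$states), " species x ",
      length(x$time), " time points (0..", max(x$time), " min), ",
      x$nsteps, " solver steps\n", sep = "")
  invisible(x)
}

#' Remove a gene unit from the network
#'
#' Models a gene deletion: the unit's transcription is silenced
#' (`copy_factor = 0`), and the member proteins, the mRNA, and any
#' modified forms produced from the members start at zero, so every
#' reaction they catalyse carries zero flux.  Knocking out an already
#' removed unit is a warning no-op.
#'
#' @param network a `reaction_network`.
#' @param gene_unit_id id of the unit to remove.
#' @return the modified network.
#' @export
knockout <- function(network, gene_unit_id) {
  i <- match(gene_unit_id, gene_ids(network))
  if (is.na(i)) stop("unknown gene unit: ", gene_unit_id, call. = FALSE)
  g <- network$genes[[i]]
  if (g$knocked_out) {
    warning("gene unit ", gene_unit_id, " is already knocked out",
            call. = FALSE)
    return(network)
  }
  g$knocked_out <- TRUE
  g$copy_factor <- 0
  network$genes[[i]] <- g
  zero <- c(g$member_proteins, g$mRNA)
  for (cy in network$cycles)
    if (cy$target %in% g$member_proteins) zero <- c(zero, cy$modified_form)
  network$species$conc[network$species$id %in% zero] <- 0
  network
}

#' Scale a gene unit's copy number
#'
#' Multiplies the unit's copy factor (dosage acts at transcription
#' initiation); nothing else in the network changes.
#'
#' @param network a `reaction_network`.
#' @param gene_unit_id id of the unit.
#' @param factor positive multiplier X/X0.
#' @return the modified network.
#' @export
apply_copy_factor <- function(network, gene_unit_id, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0)
    stop("copy factor must be a single positive number", call. = FALSE)
  i <- match(gene_unit_id, gene_ids(network))
  if (is.na(i)) stop("unknown gene unit: ", gene_unit_id, call. = FALSE)
  network$genes[[i]]$copy_factor <- network$genes[[i]]$copy_factor * factor
  network
}

#' Glutamate yield of a simulated run
#'
#' Molar yield (the default): product secreted over substrate consumed,
#' `Y = (GLUxt(t_end) - GLUxt(0)) / (GLCxt(0) + fed - GLCxt(t_end))`.
#' Titer basis: final extracellular product concentration.
#'
#' @param tc a `glusim_timecourse`.
#' @param basis `"molar"` or `"titer"`; defaults to the basis recorded in
#'   the run's configuration.
#' @param substrate,product extracellular species ids.
#' @param fed additional substrate supplied during the run (mM), added to
#'   the consumption denominator.
#' @return the yield Y (dimensionless for molar basis, mM for titer).
#' @export
yield_metric <- function(tc, basis = NULL, substrate = "GLCxt",
                         product = "GLUxt", fed = NULL) {
  stopifnot(inherits(tc, "glusim_timecourse"))
  basis <- basis %||% tc$config$yield_basis
  if (is.null(fed))
    fed <- tc$config$feed_rate * min(tc$config$feed_end, max(tc$time))
  nt <- length(tc$time)
  if (basis == "titer") return(unname(tc$states[product, nt]))
  consumed <- tc$states[substrate, 1] + fed - tc$states[substrate, nt]
  if (consumed <= 0)
    stop("yield undefined: no ", substrate, " consumed over the run",
         call. = FALSE)
  unname((tc$states[product, nt] - tc$states[product, 1]) / consumed)
}
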