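#' Moore-Penrose pseudoinverse via SVD
#' @param A numeric matrix.
#' @param tol singular-value cutoff relative to the largest.
#' @return the pseudoinverse of `A`.
#' @keywords internal
pinv <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Combine branch-point routes into a single balance expression
#'
#' A metabolite formed by several reactions (a branch point, e.g. S7P in
#' the pentose-phosphate pathway) has one balance expression per route.
#' This operation combines them into a single expression
#' `1 target = sum(c_k * species_k)` by the minimum-norm (pseudoinverse)
#' solution of the stacked route system, which for independent routes
#' equals the unweighted average of the per-route expressions; this is
#' why branch-point coefficients are generally not integers.
#'
#' @param routes list of named stoichiometry vectors, each a reaction
#'   producing exactly one unit of `target` (coefficient +1; negative =
#'   consumed).
#' @param target species id produced by every route.
#' @return object of class `branch_combination` with the combined
#'   coefficient map (named vector over the union of non-target species;
#'   positive = consumed to make one target).
#' @export
combine_branch_routes <- function(routes, target) {
  if (!length(routes)) stop("empty route list", call. = FALSE)
  exprs <- lapply(seq_along(routes), function(i) {
    st <- routes[[i]]
    if (is.null(names(st))) stop("routes must be named vectors", call. = FALSE)
    if (is.na(st[target]) || st[target] != 1)
      stop("route ", i, " does not produce exactly one unit of ", target,
           call. = FALSE)
    # 1 target = -sum(other coefficients * species)
    -st[setdiff(names(st), target)]
  })
  species <- unique(unlist(lapply(exprs, names)))
  k <- length(species)
  R <- length(exprs)
  # stacked system: one identity block per route, right-hand side the
  # per-route expression vectors; minimum-norm least squares via pinv
  A <- do.call(rbind, rep(list(diag(k)), R))
  b <- unlist(lapply(exprs, function(e) {
    v <- setNames(numeric(k), species)
    v[names(e)] <- e
    v
  }), use.names = FALSE)
  coef <- drop(pinv(A) %*% b)
  names(coef) <- species
  structure(list(target = target, routes = routes,
                 coefficients = coef[coef != 0]),
            class = "branch_combination")
}

#' Canonical side-reaction stoichiometries of the biomass model
#'
#' The rewritten arginine-pathway step (`eqA`, argininosuccinate to
#' arginine with the released fumarate fully oxidised through the TCA
#' cycle), the analogous purine-pathway step (`eqB`, SAICAR to AICAR),
#' and glycogen synthesis (8 G6P + 8 ATP per glycogen unit).
#'
#' @param id one of `"eqA"`, `"eqB"`, `"glycogen"`.
#' @return named stoichiometry vector (negative = consumed per unit flux).
#' @export
side_reaction_stoich <- function(id = c("eqA", "eqB", "glycogen")) {
  id <- match.arg(id)
  switch(id,
    eqA = c(ARGSUC = -1, ARG = 1, CO2 = 4, NAD = -6, NADH = 6,
            FAD = -2, FADH = 2, ADP = -2, Pi = -2, ATP = 2),
    eqB = c(SAICAR = -1, AICAR = 1, CO2 = 4, NAD = -6, NADH = 6,
            FAD = -2, FADH = 2, ADP = -2, Pi = -2, ATP = 2),
    glycogen = c(G6P = -8, ATP = -8, ADP = 8, GLYCOGEN = 1))
}

#' Install the biomass side reactions into a network
#'
#' Appends the `eqA`, `eqB` and glycogen stoichiometries (see
#' [side_reaction_stoich()]) as mass-action reactions and rebuilds the
#' stoichiometric matrix.
#'
#' @param network a `reaction_network`.
#' @param which subset of side reactions to install.
#' @param k named or scalar mass-action rate constants (1/min); the
#'   defaults keep the fluxes small relative to central metabolism.
#' @return the network with reactions `eqA`/`eqB`/`glycogen` installed.
#' @export
apply_side_reactions <- function(network, which = c("eqA", "eqB", "glycogen"),
                                 k = c(eqA = 1e-4, eqB = 1e-4,
                                       glycogen = 1e-4)) {
  stopifnot(inherits(network, "reaction_network"))
  k <- rep_len(k, length(which))
  names(k) <- which
  rxs <- network$reactions
  for (id in which) {
    st <- side_reaction_stoich(id)
    missing <- setdiff(names(st), network$species$id)
    if (length(missing))
      stop("side reaction ", id, " references missing species: ",
           paste(missing, collapse = ", "), call. = FALSE)
    driver <- names(st)[st < 0][1]  # first consumed species drives the rate
    rxs[[id]] <- reaction(id, st,
                          rate_law("mass_action", kcat = k[[id]],
                                   Km = setNames(1, driver)))
  }
  build_network(model_definition(network$species, rxs, network$cycles,
                                 network$genes, network$machinery,
                                 network$biomass))
}

#' Validate a biomass precursor table
#'
#' Checks the sign semantics required after the model revision (OAA and
#' FUM must be consumed, i.e. positive) and the presence of branch-point
#' key substances (S7P by default) among the table entries.  Violations
#' are returned as data, not raised as errors.
#'
#' @param table data frame with columns `species` and `coefficient`
#'   (mmol per g dry biomass).
#' @param positive_required species whose coefficients must be positive.
#' @param branch_required branch-point key substances that must appear.
#' @return data frame of violations (columns `rule`, `species`,
#'   `message`); zero rows when the table is accepted.
#' @export
validate_precursor_table <- function(table,
                                     positive_required = c("OAA", "FUM"),
                                     branch_required = "S7P") {
  stopifnot(is.data.frame(table),
            all(c("species", "coefficient") %in% names(table)))
  v <- list()
  for (sp in positive_required) {
    i <- match(sp, table$species)
    if (is.na(i))
      v[[length(v) + 1L]] <- data.frame(
        rule = "positive_coefficient", species = sp,
        message = paste0(sp, " absent from precursor table"))
    else if (table$coefficient[i] <= 0)
      v[[length(v) + 1L]] <- data.frame(
        rule = "positive_coefficient", species = sp,
        message = paste0(sp, " coefficient must be positive (got ",
                         signif(table$coefficient[i], 6), ")"))
  }
  for (sp in branch_required)
    if (!sp %in% table$species)
      v[[length(v) + 1L]] <- data.frame(
        rule = "branch_point_present", species = sp,
        message = paste0("branch-point key substance absent: ", sp))
  if (!length(v))
    return(data.frame(rule = character(), species = character(),
                      message = character()))
  do.call(rbind, v)
}

#' Biomass precursor drain rates
#'
#' Growth removes precursors in proportion to the composition table:
#' `drain_i = coefficient_i * mu * X * volume_factor`, in mM/min on a
#' 1 L culture-volume basis (mmol/g * 1/min * g/L = mM/min).  Negative
#' coefficients add to the pool.
#'
#' @param table precursor table (columns `species`, `coefficient`).
#' @param mu specific growth rate (1/min), `>= 0`.
#' @param X biomass density (g dry weight / L), `>= 0`.
#' @param volume_factor unit conversion multiplier (default 1 = 1 L basis).
#' @return named vector of drain rates (mM/min); positive values are
#'   removed from the corresponding pool.
#' @export
biomass_drain <- function(table, mu, X, volume_factor = 1) {
  if (mu < 0 || X < 0) stop("mu and X must be >= 0", call. = FALSE)
  setNames(table$coefficient * mu * X * volume_factor, table$species)
}
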