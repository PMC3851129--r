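#' Interpolate machinery levels at a growth rate
#'
#' Piecewise-linear interpolation of RNA polymerase and ribosome
#' concentrations within the table range, clamped at the endpoints
#' outside it.
#'
#' @param profile a [machinery_profile()].
#' @param mu specific growth rate (1/min), `>= 0`.
#' @return named numeric vector `c(RNAP = , ribosome = )`.
#' @export
machinery_at <- function(profile, mu) {
  stopifnot(inherits(profile, "machinery_profile"))
  if (!is.finite(mu) || mu < 0) stop("mu must be >= 0", call. = FALSE)
  tb <- profile$table
  if (nrow(tb) == 1L)
    return(c(RNAP = tb$RNAP[1], ribosome = tb$ribosome[1]))
  mu <- min(max(mu, tb$mu[1]), tb$mu[nrow(tb)])
  c(RNAP = approx(tb$mu, tb$RNAP, xout = mu)$y,
    ribosome = approx(tb$mu, tb$ribosome, xout = mu)$y)
}

regulator_occupancy <- function(regulators, tf_concs, effector_concs) {
  if (is.null(regulators) || nrow(regulators) == 0L) return(1)
  occ <- 1
  for (i in seq_len(nrow(regulators))) {
    r <- regulators[i, ]
    tf <- tf_concs[[r$tf]]
    if (is.null(tf)) stop("unresolved transcription factor: ", r$tf,
                          call. = FALSE)
    if (!is.na(r$effector)) {
      e <- effector_concs[[r$effector]]
      if (is.null(e)) stop("unresolved effector: ", r$effector, call. = FALSE)
      tf <- if (r$effector_mode == "activates") tf * e / (r$K_eff + e)
            else tf * r$K_eff / (r$K_eff + e)
    }
    occ <- occ * if (r$mode == "activator") tf / (r$K_bind + tf)
                 else r$K_bind / (r$K_bind + tf)
  }
  occ
}

#' mRNA synthesis rate of a gene unit
#'
#' `rate = k_tx * promoter_conc * copy_factor * sat(RNAP) * prod(occupancy)`
#' where `sat` is hyperbolic in the RNAP level and each regulator
#' contributes a single-site hyperbolic occupancy of its (effector-
#' modulated) active TF concentration.
#'
#' @param unit a [gene_unit()].
#' @param RNAP_conc RNA polymerase concentration.
#' @param tf_concs,effector_concs named lists/vectors of TF and effector
#'   concentrations.
#' @param K_RNAP RNAP half-saturation constant.
#' @return d\[mRNA\]/dt synthesis term (model units/min).
#' @export
transcription_rate <- function(unit, RNAP_conc, tf_concs = list(),
                               effector_concs = list(), K_RNAP = 1) {
  stopifnot(inherits(unit, "gene_unit"))
  sat <- RNAP_conc / (K_RNAP + RNAP_conc)
  unit$k_tx * unit$promoter_conc * unit$copy_factor * sat *
    regulator_occupancy(unit$regulators, tf_concs, effector_concs)
}

#' Protein synthesis rate of a gene unit
#'
#' `rate = k_tl * mRNA * sat(ribosome)`; every member protein of an
#' operon receives the identical synthesis term.
#'
#' @param unit a [gene_unit()].
#' @param mRNA_conc mRNA concentration, `>= 0`.
#' @param ribosome_conc ribosome concentration.
#' @param K_ribo ribosome half-saturation constant.
#' @return per-protein synthesis term (model units/min).
#' @export
translation_rate <- function(unit, mRNA_conc, ribosome_conc, K_ribo = 1) {
  stopifnot(inherits(unit, "gene_unit"))
  if (mRNA_conc < 0) stop("mRNA concentration must be >= 0", call. = FALSE)
  unit$k_tl * mRNA_conc * ribosome_conc / (K_ribo + ribosome_conc)
}

#' Expression derivatives of one gene unit
#'
#' Synthesis minus first-order degradation and growth dilution:
#' `d[mRNA]/dt = tx - (mRNA_deg + mu) * mRNA`,
#' `d[p]/dt = tl - (protein_deg + mu) * p` for each member protein.
#'
#' @param unit a [gene_unit()].
#' @param state named concentrations containing the unit's mRNA, member
#'   proteins, and any regulator TFs/effectors.
#' @param mu specific growth rate (1/min).
#' @param machinery a [machinery_profile()].
#' @return named list with elements `mRNA` (scalar derivative) and
#'   `proteins` (named vector of member-protein derivatives).
#' @export
expression_odes <- function(unit, state, mu, machinery) {
  mach <- machinery_at(machinery, mu)
  tx <- transcription_rate(unit, mach[["RNAP"]], as.list(state),
                           as.list(state), K_RNAP = machinery$K_RNAP)
  m <- state[[unit$mRNA]]
  tl <- translation_rate(unit, m, mach[["ribosome"]], K_ribo = machinery$K_ribo)
  dm <- tx - (unit$mRNA_deg + mu) * m
  dp <- vapply(unit$member_proteins, function(p)
    tl - (unit$protein_deg + mu) * state[[p]], numeric(1))
  list(mRNA = dm, proteins = dp)
}
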