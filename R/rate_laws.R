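#' Construct a rate law
#'
#' A rate law describes the kinetics of one reaction.  Three forms are
#' supported:
#' \describe{
#'   \item{`irreversible_mm`}{Michaelis-Menten with independent saturation
#'     per substrate: \eqn{v = k_{cat} E \prod_i S_i/(K_{m,i}+S_i)}.}
#'   \item{`reversible_mm`}{Keq-scaled net rate in the convenience-kinetics
#'     style, Haldane-consistent with a concentration-units equilibrium
#'     constant: \eqn{v = k_{cat} E (f - r) / (d_S + d_P - 1)} with
#'     \eqn{f = \prod S_i/K_{m,i}},
#'     \eqn{r = \prod P_j / (K_{eq} \prod K_{m,i})},
#'     \eqn{d_S = \prod (1 + S_i/K_{m,i})},
#'     \eqn{d_P = \prod (1 + P_j/K_{m,j})}, so the net rate vanishes
#'     exactly when \eqn{\prod P / \prod S = K_{eq}}.}
#'   \item{`mass_action`}{\eqn{v = k E \prod_i S_i} (enzyme factor dropped
#'     when the reaction is uncatalysed); used for export steps.}
#' }
#' Every form is multiplied by one hyperbolic (noncompetitive-style)
#' inhibition factor \eqn{1/(1 + I/K_i)} per listed inhibitor.
#'
#' @param form one of `"irreversible_mm"`, `"reversible_mm"`, `"mass_action"`.
#' @param kcat turnover number (1/min); the bare rate constant for
#'   mass-action laws.
#' @param Km named numeric vector of substrate Michaelis constants (mM);
#'   names are substrate species ids.  Ignored for mass-action laws except
#'   that its names declare the substrates.
#' @param Km_products named numeric vector of product Michaelis constants
#'   (reversible form only).
#' @param Keq equilibrium constant (reversible form only).
#' @param inhibitors data frame with columns `species`, `Ki` and optionally
#'   `mode` (only `"noncompetitive"` is implemented).
#' @return an object of class `rate_law`.
#' @export
rate_law <- function(form = c("irreversible_mm", "reversible_mm", "mass_action"),
                     kcat, Km = numeric(), Km_products = numeric(),
                     Keq = NA_real_, inhibitors = NULL) {
  form <- match.arg(form)
  if (!is.numeric(kcat) || length(kcat) != 1L || !is.finite(kcat) || kcat <= 0)
    stop("kcat must be a single positive number", call. = FALSE)
  if (length(Km) && (is.null(names(Km)) || any(!nzchar(names(Km)))))
    stop("Km must be a named vector (names are substrate ids)", call. = FALSE)
  if (form != "mass_action" && any(Km <= 0))
    stop("all Km values must be > 0", call. = FALSE)
  if (form == "reversible_mm") {
    if (!is.finite(Keq) || Keq <= 0)
      stop("reversible_mm requires a positive Keq", call. = FALSE)
    if (!length(Km_products) || is.null(names(Km_products)) ||
        any(Km_products <= 0))
      stop("reversible_mm requires named positive Km_products", call. = FALSE)
  }
  if (!is.null(inhibitors)) {
    stopifnot(is.data.frame(inhibitors),
              all(c("species", "Ki") %in% names(inhibitors)))
    if (any(inhibitors$Ki <= 0))
      stop("all Ki must be > 0", call. = FALSE)
  }
  structure(list(form = form, kcat = kcat, Km = Km,
                 Km_products = Km_products, Keq = Keq,
                 inhibitors = inhibitors),
            class = "rate_law")
}

#' Hyperbolic inhibition factor
#'
#' Multiplier \eqn{1/(1 + c/K_i)} applied to a reaction rate; equals 1
#' with no inhibitor and decreases monotonically toward 0.
#'
#' @param conc inhibitor concentration (mM), `>= 0`.
#' @param Ki inhibition constant (mM), `> 0`.
#' @return dimensionless multiplier in (0, 1].
#' @export
inhibition_factor <- function(conc, Ki) {
  if (any(!is.finite(Ki)) || any(Ki <= 0))
    stop("Ki must be > 0", call. = FALSE)
  if (any(conc < 0)) stop("inhibitor concentration must be >= 0", call. = FALSE)
  1 / (1 + conc / Ki)
}

#' Evaluate a rate law
#'
#' Reference (pure R) implementation of the reaction flux; the compiled
#' engine re-implements the same conventions and is cross-checked against
#' this function in the test suite.
#'
#' @param law a [rate_law()].
#' @param enzyme_conc catalyst concentration (mM); use 1 for uncatalysed
#'   mass-action steps.
#' @param substrate_concs named numeric vector covering every substrate
#'   (and, for reversible laws, product) referenced by the law; inhibitor
#'   concentrations are also looked up here.
#' @return flux in mM/min.
#' @export
mm_rate <- function(law, enzyme_conc, substrate_concs) {
  stopifnot(inherits(law, "rate_law"))
  if (!is.finite(enzyme_conc) || enzyme_conc < 0)
    stop("enzyme concentration must be >= 0", call. = FALSE)
  need <- names(law$Km)
  if (law$form == "reversible_mm") need <- c(need, names(law$Km_products))
  if (!is.null(law$inhibitors)) need <- c(need, law$inhibitors$species)
  missing <- setdiff(need, names(substrate_concs))
  if (length(missing))
    stop("missing concentration for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(substrate_concs[need] < 0))
    stop("concentrations must be >= 0", call. = FALSE)

  v <- switch(law$form,
    irreversible_mm = {
      s <- substrate_concs[names(law$Km)]
      law$kcat * enzyme_conc * prod(s / (law$Km + s))
    },
    reversible_mm = {
      s <- substrate_concs[names(law$Km)] / law$Km
      p <- substrate_concs[names(law$Km_products)]
      den <- prod(1 + s) + prod(1 + p / law$Km_products) - 1
      law$kcat * enzyme_conc *
        (prod(s) - prod(p) / (law$Keq * prod(law$Km))) / den
    },
    mass_action = {
      s <- if (length(law$Km)) substrate_concs[names(law$Km)] else numeric()
      law$kcat * enzyme_conc * prod(s)
    })
  if (!is.null(law$inhibitors))
    v <- v * prod(inhibition_factor(substrate_concs[law$inhibitors$species],
                                    law$inhibitors$Ki))
  unname(v)
}

#' Covalent modification cycle
#'
#' A two-state phosphorylation cycle run by one bifunctional converter
#' enzyme: the kinase activity converts the target to its (inactive)
#' modified form, the phosphatase activity reverses it.  The kinase flux
#' carries a hyperbolic inhibition term for a metabolite effector (in the
#' glutamate model: 3-phosphoglycerate inhibiting the AceK kinase acting on
#' isocitrate dehydrogenase).  The two fluxes conserve target + modified.
#'
#' @param target species id of the active (unmodified) protein.
#' @param modified_form species id of the inactive modified protein.
#' @param converter species id of the bifunctional kinase/phosphatase.
#' @param k_kin,k_phos catalytic constants (1/min).
#' @param Km_target,Km_modified saturation constants (mM); `Inf` selects a
#'   first-order (linear) dependence on the respective pool.
#' @param kinase_inhibitor species id inhibiting the kinase arm, or `NA`.
#' @param Ki_inh inhibition constant (mM) for the kinase inhibitor.
#' @return an object of class `modification_cycle`.
#' @export
modification_cycle <- function(target, modified_form, converter,
                               k_kin, k_phos,
                               Km_target = Inf, Km_modified = Inf,
                               kinase_inhibitor = NA_character_,
                               Ki_inh = NA_real_) {
  stopifnot(k_kin > 0, k_phos > 0)
  if (!is.na(kinase_inhibitor) && (!is.finite(Ki_inh) || Ki_inh <= 0))
    stop("Ki_inh must be > 0 when a kinase inhibitor is given", call. = FALSE)
  structure(list(target = target, modified_form = modified_form,
                 converter = converter, k_kin = k_kin, k_phos = k_phos,
                 Km_target = Km_target, Km_modified = Km_modified,
                 kinase_inhibitor = kinase_inhibitor, Ki_inh = Ki_inh),
            class = "modification_cycle")
}

#' Kinase and phosphatase fluxes of a modification cycle
#'
#' @param cycle a [modification_cycle()].
#' @param concs named concentrations covering target, modified form,
#'   converter, and the kinase inhibitor if present.
#' @return named numeric vector `c(kinase = , phosphatase = )` in mM/min.
#' @export
modification_fluxes <- function(cycle, concs) {
  stopifnot(inherits(cycle, "modification_cycle"))
  need <- c(cycle$target, cycle$modified_form, cycle$converter)
  if (!is.na(cycle$kinase_inhibitor)) need <- c(need, cycle$kinase_inhibitor)
  missing <- setdiff(need, names(concs))
  if (length(missing))
    stop("missing concentration for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  conv <- concs[[cycle$converter]]
  tgt <- concs[[cycle$target]]
  mod <- concs[[cycle$modified_form]]
  inh <- if (is.na(cycle$kinase_inhibitor)) 1 else
    inhibition_factor(concs[[cycle$kinase_inhibitor]], cycle$Ki_inh)
  satt <- if (is.finite(cycle$Km_target)) tgt / (cycle$Km_target + tgt) else tgt
  satm <- if (is.finite(cycle$Km_modified)) mod / (cycle$Km_modified + mod) else mod
  c(kinase = cycle$k_kin * conv * inh * satt,
    phosphatase = cycle$k_phos * conv * satm)
}
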