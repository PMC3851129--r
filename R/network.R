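#' Declare a species table
#'
#' @param id character vector of unique species ids (e.g. `"G6P"`,
#'   `"ICD"`, `"GLUxt"`).
#' @param role one of `"metabolite"`, `"protein"`, `"mRNA"`, `"boundary"`
#'   per species.  Boundary species are clamped at their initial
#'   concentration and are never drained by biomass.
#' @param compartment `"intracellular"` or `"extracellular"`.  Only
#'   intracellular, non-constant pools are diluted by growth.
#' @param conc initial concentration (mM; proteins and mRNA in model
#'   concentration units on the same scale).
#' @param constant logical; clamp the species even if its role is not
#'   `"boundary"` (used for enzymes kept outside the expression layer).
#' @return data frame with one row per species.
#' @export
species_table <- function(id, role, compartment = "intracellular",
                          conc = 0, constant = FALSE) {
  n <- length(id)
  df <- data.frame(id = as.character(id),
                   role = rep_len(role, n),
                   compartment = rep_len(compartment, n),
                   conc = rep_len(as.numeric(conc), n),
                   constant = rep_len(as.logical(constant), n),
                   stringsAsFactors = FALSE)
  bad <- setdiff(df$role, c("metabolite", "protein", "mRNA", "boundary"))
  if (length(bad)) stop("unknown species role: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(df$compartment, c("intracellular", "extracellular"))
  if (length(bad)) stop("unknown compartment: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(df$conc < 0)) stop("initial concentrations must be >= 0", call. = FALSE)
  if (anyDuplicated(df$id))
    stop("duplicate species id: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "), call. = FALSE)
  df$constant <- df$constant | df$role == "boundary"
  df
}

#' Declare a reaction
#'
#' @param id unique reaction id.
#' @param stoichiometry named numeric vector, species -> signed
#'   coefficient (negative = consumed).
#' @param rate_law a [rate_law()].
#' @param catalyst protein species id, or `NA` for uncatalysed steps.
#' @return an object of class `reaction`.
#' @export
reaction <- function(id, stoichiometry, rate_law, catalyst = NA_character_) {
  stopifnot(inherits(rate_law, "rate_law"))
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
    stop("stoichiometry must be a named vector", call. = FALSE)
  if (any(stoichiometry == 0))
    stop("zero stoichiometric coefficients are not allowed", call. = FALSE)
  structure(list(id = id, stoichiometry = stoichiometry,
                 catalyst = catalyst, rate_law = rate_law),
            class = "reaction")
}

#' Declare a gene-expression unit
#'
#' One transcription unit (gene or operon).  All member proteins share a
#' single mRNA species and a single copy factor; the copy factor
#' multiplies the promoter term at transcription initiation, so gene
#' dosage acts on mRNA synthesis.
#'
#' @param id gene or operon name (e.g. `"epd_pgk"`, `"aceBAK"`).
#' @param member_proteins character vector of protein species ids.
#' @param promoter_conc promoter concentration (model units).
#' @param copy_factor dimensionless dosage multiplier X/X0 (baseline 1).
#' @param k_tx transcription rate constant (1/min).
#' @param mRNA_deg mRNA degradation rate (1/min).
#' @param k_tl translation rate constant per protein (1/min).
#' @param protein_deg protein degradation rate (1/min).
#' @param regulators `NULL` or a data frame with columns `tf`, `mode`
#'   (`"activator"`/`"repressor"`), `K_bind`, and optionally `effector`,
#'   `effector_mode` (`"activates"`/`"inactivates"` the TF), `K_eff`.
#' @param mRNA mRNA species id; defaults to `"mRNA_<id>"`.
#' @return an object of class `gene_unit`.
#' @export
gene_unit <- function(id, member_proteins, promoter_conc, copy_factor = 1,
                      k_tx, mRNA_deg, k_tl, protein_deg,
                      regulators = NULL, mRNA = paste0("mRNA_", id)) {
  if (!is.numeric(copy_factor) || copy_factor < 0)
    stop("copy_factor must be >= 0", call. = FALSE)
  stopifnot(promoter_conc >= 0, k_tx >= 0, mRNA_deg >= 0, k_tl >= 0,
            protein_deg >= 0, length(member_proteins) >= 1)
  if (!is.null(regulators)) {
    stopifnot(is.data.frame(regulators),
              all(c("tf", "mode", "K_bind") %in% names(regulators)))
    if (!all(regulators$mode %in% c("activator", "repressor")))
      stop("regulator mode must be activator or repressor", call. = FALSE)
    if (is.null(regulators$effector)) regulators$effector <- NA_character_
    if (is.null(regulators$effector_mode))
      regulators$effector_mode <- NA_character_
    if (is.null(regulators$K_eff)) regulators$K_eff <- NA_real_
    has_eff <- !is.na(regulators$effector)
    if (any(has_eff & (!regulators$effector_mode %in%
                         c("activates", "inactivates") |
                       !is.finite(regulators$K_eff) | regulators$K_eff <= 0)))
      stop("regulator effectors need effector_mode and positive K_eff",
           call. = FALSE)
  }
  structure(list(id = id, member_proteins = member_proteins, mRNA = mRNA,
                 promoter_conc = promoter_conc, copy_factor = copy_factor,
                 k_tx = k_tx, mRNA_deg = mRNA_deg, k_tl = k_tl,
                 protein_deg = protein_deg, regulators = regulators,
                 knocked_out = FALSE),
            class = "gene_unit")
}

#' Machinery profile: RNAP and ribosome levels versus growth rate
#'
#' @param mu specific growth rates (1/min), strictly increasing.
#' @param RNAP,ribosome machinery concentrations at each `mu`;
#'   non-decreasing in `mu`.
#' @param K_RNAP,K_ribo half-saturation constants of the hyperbolic
#'   machinery saturation terms used in transcription and translation.
#' @return an object of class `machinery_profile`.
#' @export
machinery_profile <- function(mu, RNAP, ribosome, K_RNAP, K_ribo) {
  if (!length(mu)) stop("machinery table must not be empty", call. = FALSE)
  stopifnot(length(RNAP) == length(mu), length(ribosome) == length(mu),
            K_RNAP > 0, K_ribo > 0)
  if (is.unsorted(mu, strictly = TRUE))
    stop("mu knots must be strictly increasing", call. = FALSE)
  if (is.unsorted(RNAP) || is.unsorted(ribosome))
    stop("RNAP and ribosome must be non-decreasing in mu", call. = FALSE)
  structure(list(table = data.frame(mu = mu, RNAP = RNAP, ribosome = ribosome),
                 K_RNAP = K_RNAP, K_ribo = K_ribo),
            class = "machinery_profile")
}

#' Assemble a model definition
#'
#' Bundles the declarative parts of a model prior to [build_network()].
#'
#' @param species a [species_table()].
#' @param reactions list of [reaction()] objects.
#' @param cycles list of [modification_cycle()] objects.
#' @param genes list of [gene_unit()] objects.
#' @param machinery a [machinery_profile()] (or `NULL` for models without
#'   an expression layer).
#' @param biomass data frame with columns `species`, `coefficient`
#'   (mmol per g dry biomass; positive = consumed for growth), or `NULL`.
#' @return an object of class `glusim_model_def`.
#' @export
model_definition <- function(species, reactions = list(), cycles = list(),
                             genes = list(), machinery = NULL,
                             biomass = NULL) {
  structure(list(species = species, reactions = reactions, cycles = cycles,
                 genes = genes, machinery = machinery, biomass = biomass),
            class = "glusim_model_def")
}

#' Build and validate a reaction network
#'
#' Resolves every cross-reference in a model definition, assembles the
#' stoichiometric matrix (species x reactions), and returns the validated
#' network.  Building is deterministic: identical definitions yield
#' identical networks.
#'
#' @param def a [model_definition()] (or a parsed model file from
#'   [read_model()]).
#' @return an object of class `reaction_network` with elements `species`,
#'   `reactions`, `cycles`, `genes`, `machinery`, `biomass` and the
#'   stoichiometric matrix `S`.
#' @export
build_network <- function(def) {
  stopifnot(inherits(def, "glusim_model_def"))
  sp <- def$species
  ids <- sp$id

  resolve <- function(ref, what, where) {
    bad <- setdiff(ref[!is.na(ref)], ids)
    if (length(bad))
      stop("unresolved ", what, " in ", where, ": ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
  }

  rids <- unname(vapply(def$reactions, `[[`, "", "id"))
  names(def$reactions) <- rids
  if (anyDuplicated(rids))
    stop("duplicate reaction id: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "), call. = FALSE)

  S <- matrix(0, nrow = length(ids), ncol = length(rids),
              dimnames = list(ids, rids))
  for (j in seq_along(def$reactions)) {
    rx <- def$reactions[[j]]
    resolve(names(rx$stoichiometry), "species", paste0("reaction ", rx$id))
    resolve(rx$catalyst, "catalyst", paste0("reaction ", rx$id))
    law <- rx$rate_law
    resolve(names(law$Km), "substrate", paste0("reaction ", rx$id))
    resolve(names(law$Km_products), "product", paste0("reaction ", rx$id))
    if (!is.null(law$inhibitors))
      resolve(law$inhibitors$species, "inhibitor", paste0("reaction ", rx$id))
    kinds <- sign(rx$stoichiometry)
    if (!(any(kinds < 0) && any(kinds > 0)) && length(rx$stoichiometry) > 1)
      warning("reaction ", rx$id,
              " has no consumed or no produced species", call. = FALSE)
    S[names(rx$stoichiometry), j] <- rx$stoichiometry
  }

  for (cy in def$cycles) {
    resolve(c(cy$target, cy$modified_form, cy$converter),
            "species", paste0("cycle ", cy$target, "<->", cy$modified_form))
    if (!is.na(cy$kinase_inhibitor))
      resolve(cy$kinase_inhibitor, "kinase inhibitor",
              paste0("cycle ", cy$target))
  }

  gids <- unname(vapply(def$genes, `[[`, "", "id"))
  names(def$genes) <- gids
  if (anyDuplicated(gids))
    stop("duplicate gene unit id: ",
         paste(unique(gids[duplicated(gids)]), collapse = ", "), call. = FALSE)
  for (g in def$genes) {
    resolve(c(g$member_proteins, g$mRNA), "species",
            paste0("gene unit ", g$id))
    if (!is.null(g$regulators)) {
      resolve(g$regulators$tf, "transcription factor",
              paste0("gene unit ", g$id))
      resolve(g$regulators$effector, "effector", paste0("gene unit ", g$id))
    }
  }

  if (!is.null(def$biomass))
    resolve(def$biomass$species, "biomass precursor", "biomass table")

  net <- structure(list(species = sp, reactions = def$reactions,
                        cycles = def$cycles, genes = def$genes,
                        machinery = def$machinery, biomass = def$biomass,
                        S = S),
                   class = "reaction_network")
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", nrow(x$species), " species, ",
      length(x$reactions), " reactions, ", length(x$cycles), " cycles, ",
      length(x$genes), " gene units\n", sep = "")
  invisible(x)
}

gene_ids <- function(network) vapply(network$genes, `[[`, "", "id")

get_gene <- function(network, id) {
  i <- match(id, gene_ids(network))
  if (is.na(i)) stop("unknown gene unit: ", id, call. = FALSE)
  network$genes[[i]]
}
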