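# Model definition file format
# ----------------------------
# Line-oriented structured text with six sections.  "#" starts a comment,
# blank lines are ignored.  Units: mM, minutes, litres, g dry cell weight.
#
# [species]    id role compartment conc constant(0/1)
# [reactions]  id law kcat catalyst keq | substrates | products |
#              inhibitors | stoichiometry
#              lists are comma-separated id:value pairs ("-" when empty);
#              catalyst "-" for uncatalysed steps; keq "-" unless
#              reversible_mm
# [cycles]     target modified converter k_kin k_phos Km_t Km_m
#              inhibitor Ki     (Km "inf" selects first-order; "-" = none)
# [genes]      id mRNA promoter copy_factor k_tx mRNA_deg k_tl
#              protein_deg ko(0/1) | proteins | regulators
#              regulators: tf:mode:K[:effector:effmode:Keff], ";"-separated
# [machinery]  first row "sat K_RNAP K_ribo", then rows "mu RNAP ribosome"
# [biomass]    species coefficient_mmol_per_g

num <- function(x, line) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) stop("line ", line, ": expected a number, got '", x, "'",
                     call. = FALSE)
  v
}

parse_pairs <- function(x, line) {
  if (x == "-") return(numeric())
  parts <- strsplit(strsplit(x, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("line ", line, ": malformed id:value pair in '", x, "'",
                     call. = FALSE)
  setNames(num(vapply(parts, `[[`, "", 2L), line),
           vapply(parts, `[[`, "", 1L))
}

#' Read a model definition file
#'
#' Parses the structured-text model format (sections `[species]`,
#' `[reactions]`, `[cycles]`, `[genes]`, `[machinery]`, `[biomass]`; see
#' the package README for the grammar) into a [model_definition()].
#' Errors carry the offending line number.
#'
#' @param path file path.
#' @return a `glusim_model_def`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readLines(path)
  txt <- sub("#.*$", "", raw)
  keep <- which(nzchar(trimws(txt)))
  section <- NA_character_
  sp <- list(); rx <- list(); cy <- list(); gn <- list()
  mach_rows <- list(); mach_k <- NULL; bm <- list()
  sp_lines <- integer()

  for (i in keep) {
    line <- trimws(txt[i])
    if (grepl("^\\[", line)) {
      section <- sub("^\\[(.*)\\]$", "\\1", line)
      if (!section %in% c("species", "reactions", "cycles", "genes",
                          "machinery", "biomass"))
        stop("line ", i, ": unknown section [", section, "]", call. = FALSE)
      next
    }
    if (is.na(section))
      stop("line ", i, ": content before any section header", call. = FALSE)
    if (section == "species") {
      f <- strsplit(line, "\\s+")[[1]]
      if (length(f) != 5L)
        stop("line ", i, ": species rows need 5 fields", call. = FALSE)
      sp[[length(sp) + 1L]] <- data.frame(
        id = f[1], role = f[2], compartment = f[3],
        conc = num(f[4], i), constant = num(f[5], i) != 0)
      sp_lines <- c(sp_lines, i)
    } else if (section == "reactions") {
      seg <- trimws(strsplit(line, "|", fixed = TRUE)[[1]])
      if (length(seg) != 5L)
        stop("line ", i, ": reaction rows need 5 '|' segments", call. = FALSE)
      f <- strsplit(seg[1], "\\s+")[[1]]
      if (length(f) != 5L)
        stop("line ", i, ": reaction head needs 5 fields", call. = FALSE)
      keq <- if (f[5] == "-") NA_real_ else num(f[5], i)
      subs <- parse_pairs(seg[2], i)
      prods <- parse_pairs(seg[3], i)
      inh <- parse_pairs(seg[4], i)
      st <- parse_pairs(seg[5], i)
      law <- rate_law(f[2], kcat = num(f[3], i), Km = subs,
                      Km_products = prods, Keq = keq,
                      inhibitors = if (length(inh))
                        data.frame(species = names(inh), Ki = unname(inh)))
      rx[[length(rx) + 1L]] <- reaction(
        f[1], st, law, catalyst = if (f[4] == "-") NA_character_ else f[4])
    } else if (section == "cycles") {
      f <- strsplit(line, "\\s+")[[1]]
      if (length(f) != 9L)
        stop("line ", i, ": cycle rows need 9 fields", call. = FALSE)
      cy[[length(cy) + 1L]] <- modification_cycle(
        f[1], f[2], f[3], k_kin = num(f[4], i), k_phos = num(f[5], i),
        Km_target = if (f[6] == "inf") Inf else num(f[6], i),
        Km_modified = if (f[7] == "inf") Inf else num(f[7], i),
        kinase_inhibitor = if (f[8] == "-") NA_character_ else f[8],
        Ki_inh = if (f[9] == "-") NA_real_ else num(f[9], i))
    } else if (section == "genes") {
      seg <- trimws(strsplit(line, "|", fixed = TRUE)[[1]])
      if (length(seg) != 3L)
        stop("line ", i, ": gene rows need 3 '|' segments", call. = FALSE)
      f <- strsplit(seg[1], "\\s+")[[1]]
      if (length(f) != 9L)
        stop("line ", i, ": gene head needs 9 fields", call. = FALSE)
      regs <- NULL
      if (seg[3] != "-") {
        items <- strsplit(seg[3], ";", fixed = TRUE)[[1]]
        parts <- strsplit(items, ":", fixed = TRUE)
        if (any(!lengths(parts) %in% c(3L, 6L)))
          stop("line ", i, ": regulators need 3 or 6 ':' fields",
               call. = FALSE)
        regs <- do.call(rbind, lapply(parts, function(pp)
          data.frame(tf = pp[1], mode = pp[2], K_bind = num(pp[3], i),
                     effector = if (length(pp) == 6L) pp[4] else NA,
                     effector_mode = if (length(pp) == 6L) pp[5] else NA,
                     K_eff = if (length(pp) == 6L) num(pp[6], i) else NA)))
      }
      g <- gene_unit(f[1], strsplit(seg[2], ",", fixed = TRUE)[[1]],
                     promoter_conc = num(f[3], i),
                     copy_factor = num(f[4], i), k_tx = num(f[5], i),
                     mRNA_deg = num(f[6], i), k_tl = num(f[7], i),
                     protein_deg = num(f[8], i), regulators = regs,
                     mRNA = f[2])
      g$knocked_out <- num(f[9], i) != 0
      gn[[length(gn) + 1L]] <- g
    } else if (section == "machinery") {
      f <- strsplit(line, "\\s+")[[1]]
      if (f[1] == "sat") {
        mach_k <- c(num(f[2], i), num(f[3], i))
      } else {
        if (length(f) != 3L)
          stop("line ", i, ": machinery rows need 3 fields", call. = FALSE)
        mach_rows[[length(mach_rows) + 1L]] <- num(f, i)
      }
    } else if (section == "biomass") {
      f <- strsplit(line, "\\s+")[[1]]
      if (length(f) != 2L)
        stop("line ", i, ": biomass rows need 2 fields", call. = FALSE)
      bm[[length(bm) + 1L]] <- data.frame(species = f[1],
                                          coefficient = num(f[2], i))
    }
  }

  if (!length(sp)) stop("model file has no [species] section", call. = FALSE)
  spdf <- do.call(rbind, sp)
  if (anyDuplicated(spdf$id)) {
    dup <- spdf$id[duplicated(spdf$id)][1]
    stop("duplicate species id '", dup, "' (lines ",
         paste(sp_lines[spdf$id == dup], collapse = ", "), ")",
         call. = FALSE)
  }
  mach <- NULL
  if (length(mach_rows)) {
    m <- do.call(rbind, mach_rows)
    if (is.null(mach_k)) mach_k <- c(1, 1)
    mach <- machinery_profile(m[, 1], m[, 2], m[, 3],
                              K_RNAP = mach_k[1], K_ribo = mach_k[2])
  }
  model_definition(
    species_table(spdf$id, spdf$role, spdf$compartment, spdf$conc,
                  spdf$constant),
    rx, cy, gn, machinery = mach,
    biomass = if (length(bm)) do.call(rbind, bm))
}

fmt <- function(x) sprintf("%.17g", x)

pairs_str <- function(v) {
  if (!length(v)) return("-")
  paste0(names(v), ":", fmt(unname(v)), collapse = ",")
}

#' Write a model definition file
#'
#' Inverse of [read_model()]; `read_model(write_model(def, f))` returns a
#' structurally identical definition (numbers are written at full
#' precision).  A `reaction_network` may be passed and is decomposed back
#' into its definition.
#'
#' @param def a `glusim_model_def` or `reaction_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(def, path) {
  if (inherits(def, "reaction_network"))
    def <- model_definition(def$species, def$reactions, def$cycles,
                            def$genes, def$machinery, def$biomass)
  stopifnot(inherits(def, "glusim_model_def"))
  out <- c("# glusim model definition", "[species]")
  s <- def$species
  out <- c(out, paste(s$id, s$role, s$compartment, fmt(s$conc),
                      as.integer(s$constant)))
  out <- c(out, "[reactions]")
  for (r in def$reactions) {
    law <- r$rate_law
    inh <- if (is.null(law$inhibitors)) numeric() else
      setNames(law$inhibitors$Ki, law$inhibitors$species)
    out <- c(out, paste(
      paste(r$id, law$form, fmt(law$kcat),
            if (is.na(r$catalyst)) "-" else r$catalyst,
            if (is.na(law$Keq)) "-" else fmt(law$Keq)),
      pairs_str(law$Km), pairs_str(law$Km_products), pairs_str(inh),
      pairs_str(r$stoichiometry), sep = " | "))
  }
  out <- c(out, "[cycles]")
  for (cc in def$cycles)
    out <- c(out, paste(cc$target, cc$modified_form, cc$converter,
                        fmt(cc$k_kin), fmt(cc$k_phos),
                        if (is.finite(cc$Km_target)) fmt(cc$Km_target) else "inf",
                        if (is.finite(cc$Km_modified)) fmt(cc$Km_modified) else "inf",
                        if (is.na(cc$kinase_inhibitor)) "-" else cc$kinase_inhibitor,
                        if (is.na(cc$Ki_inh)) "-" else fmt(cc$Ki_inh)))
  out <- c(out, "[genes]")
  for (g in def$genes) {
    regs <- "-"
    if (!is.null(g$regulators) && nrow(g$regulators)) {
      r <- g$regulators
      regs <- paste(vapply(seq_len(nrow(r)), function(i) {
        if (is.na(r$effector[i]))
          paste(r$tf[i], r$mode[i], fmt(r$K_bind[i]), sep = ":")
        else paste(r$tf[i], r$mode[i], fmt(r$K_bind[i]), r$effector[i],
                   r$effector_mode[i], fmt(r$K_eff[i]), sep = ":")
      }, ""), collapse = ";")
    }
    out <- c(out, paste(
      paste(g$id, g$mRNA, fmt(g$promoter_conc), fmt(g$copy_factor),
            fmt(g$k_tx), fmt(g$mRNA_deg), fmt(g$k_tl), fmt(g$protein_deg),
            as.integer(g$knocked_out)),
      paste(g$member_proteins, collapse = ","), regs, sep = " | "))
  }
  if (!is.null(def$machinery)) {
    m <- def$machinery
    out <- c(out, "[machinery]",
             paste("sat", fmt(m$K_RNAP), fmt(m$K_ribo)),
             paste(fmt(m$table$mu), fmt(m$table$RNAP), fmt(m$table$ribosome)))
  }
  if (!is.null(def$biomass))
    out <- c(out, "[biomass]",
             paste(def$biomass$species, fmt(def$biomass$coefficient)))
  writeLines(out, path)
  invisible(path)
}

#' Write a timecourse as TSV
#'
#' Columns: `time_min`, then one column per species.  Values are written
#' at full precision so the round trip through [read_timecourse()] is
#' lossless.
#'
#' @param tc a `glusim_timecourse`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "glusim_timecourse"))
  df <- data.frame(time_min = tc$time, t(tc$states), check.names = FALSE)
  header <- paste(c("time_min", rownames(tc$states)), collapse = "\t")
  body <- apply(df, 1L, function(row) paste(fmt(row), collapse = "\t"))
  writeLines(c(header, if (length(body)) body), path)
  invisible(path)
}

#' Read a timecourse TSV
#'
#' @param path file written by [write_timecourse()].
#' @return a `glusim_timecourse` (without flux information).
#' @export
read_timecourse <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty timecourse file", call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "time_min")
    stop("row 1: first column must be time_min", call. = FALSE)
  n <- length(header)
  rows <- lapply(seq_along(lines[-1]), function(i) {
    f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(v) != n || anyNA(v))
      stop("row ", i + 1L, ": malformed numeric record", call. = FALSE)
    v
  })
  m <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(), 0, n)
  states <- t(m[, -1, drop = FALSE])
  rownames(states) <- header[-1]
  structure(list(time = m[, 1], states = states, fluxes = NULL,
                 config = NULL, nsteps = NA_integer_, nreject = NA_integer_),
            class = "glusim_timecourse")
}

#' Write a sensitivity ranking table as TSV
#'
#' Columns mirror the maximum-sensitivity table format: rank, unit,
#' product, max_sensitivity, scale_factor.
#'
#' @param ranking a `ranking_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  write.table(as.data.frame(ranking), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# --- SBML level 3 export -----------------------------------------------

sbml_id <- function(x) {
  x <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl("^[A-Za-z_]", x), x, paste0("s_", x))
}

ml_ci <- function(id) paste0("<ci> ", sbml_id(id), " </ci>")
ml_cn <- function(x) paste0("<cn> ", sprintf("%.12g", x), " </cn>")
ml_apply <- function(op, ...) paste0("<apply><", op, "/>",
                                     paste0(c(...), collapse = ""),
                                     "</apply>")

ml_sat <- function(id, km)
  ml_apply("divide", ml_ci(id), ml_apply("plus", ml_cn(km), ml_ci(id)))

rate_mathml <- function(rx) {
  law <- rx$rate_law
  e <- if (!is.na(rx$catalyst)) ml_ci(rx$catalyst)
  terms <- switch(law$form,
    mass_action = c(ml_cn(law$kcat), e, vapply(names(law$Km), ml_ci, "")),
    irreversible_mm = c(ml_cn(law$kcat), e,
                        mapply(ml_sat, names(law$Km), law$Km)),
    reversible_mm = {
      fwd <- Reduce(function(a, b) ml_apply("times", a, b),
                    mapply(function(id, km) ml_apply("divide", ml_ci(id),
                                                     ml_cn(km)),
                           names(law$Km), law$Km))
      rev <- Reduce(function(a, b) ml_apply("times", a, b),
                    mapply(function(id, km) ml_apply("divide", ml_ci(id),
                                                     ml_cn(km)),
                           names(law$Km_products), law$Km_products))
      dens <- Reduce(function(a, b) ml_apply("times", a, b),
                     mapply(function(id, km)
                       ml_apply("plus", ml_cn(1),
                                ml_apply("divide", ml_ci(id), ml_cn(km))),
                       names(law$Km), law$Km))
      denp <- Reduce(function(a, b) ml_apply("times", a, b),
                     mapply(function(id, km)
                       ml_apply("plus", ml_cn(1),
                                ml_apply("divide", ml_ci(id), ml_cn(km))),
                       names(law$Km_products), law$Km_products))
      c(ml_cn(law$kcat), e,
        ml_apply("divide",
                 ml_apply("minus", fwd,
                          ml_apply("divide", rev, ml_cn(law$Keq))),
                 ml_apply("minus", ml_apply("plus", dens, denp), ml_cn(1))))
    })
  if (!is.null(law$inhibitors))
    terms <- c(terms, mapply(function(id, ki)
      ml_apply("divide", ml_cn(1),
               ml_apply("plus", ml_cn(1),
                        ml_apply("divide", ml_ci(id), ml_cn(ki)))),
      law$inhibitors$species, law$inhibitors$Ki))
  body <- Reduce(function(a, b) ml_apply("times", a, b), terms)
  paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">', body,
         "</math>")
}

#' Export a network as an SBML Level 3 document
#'
#' Writes compartments, species (boundary species flagged constant),
#' reactions with reactants/products/modifier from the stoichiometry and
#' catalyst, and each reaction's kinetic law as MathML.  The expression
#' layer, cycles and biomass drains are not part of the SBML reaction
#' graph.
#'
#' @param network a `reaction_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(network, path) {
  stopifnot(inherits(network, "reaction_network"))
  sp <- network$species
  species_xml <- paste0(
    '<species id="', sbml_id(sp$id), '" name="', sp$id,
    '" compartment="', sp$compartment,
    '" initialConcentration="', sprintf("%.12g", sp$conc),
    '" hasOnlySubstanceUnits="false" boundaryCondition="',
    tolower(sp$constant), '" constant="', tolower(sp$constant), '"/>',
    collapse = "")
  rx_xml <- vapply(network$reactions, function(rx) {
    st <- rx$stoichiometry
    ref <- function(ids, coefs)
      paste0('<speciesReference species="', sbml_id(ids),
             '" stoichiometry="', sprintf("%.12g", coefs),
             '" constant="true"/>', collapse = "")
    reac <- names(st)[st < 0]
    prod <- names(st)[st > 0]
    paste0('<reaction id="', sbml_id(rx$id), '" reversible="',
           tolower(rx$rate_law$form == "reversible_mm"), '">',
           if (length(reac)) paste0("<listOfReactants>",
                                    ref(reac, -st[st < 0]),
                                    "</listOfReactants>") else "",
           if (length(prod)) paste0("<listOfProducts>",
                                    ref(prod, st[st > 0]),
                                    "</listOfProducts>") else "",
           if (!is.na(rx$catalyst))
             paste0('<listOfModifiers><modifierSpeciesReference species="',
                    sbml_id(rx$catalyst),
                    '"/></listOfModifiers>') else "",
           "<kineticLaw>", rate_mathml(rx), "</kineticLaw>",
           "</reaction>")
  }, "")
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" ',
    'level="3" version="2">',
    '<model id="glusim_model">',
    "<listOfCompartments>",
    '<compartment id="intracellular" constant="true" spatialDimensions="3" size="1"/>',
    '<compartment id="extracellular" constant="true" spatialDimensions="3" size="1"/>',
    "</listOfCompartments>",
    "<listOfSpecies>", species_xml, "</listOfSpecies>",
    if (length(rx_xml)) paste0("<listOfReactions>",
                               paste0(rx_xml, collapse = ""),
                               "</listOfReactions>") else "",
    "</model></sbml>")
  xml2::write_xml(xml2::read_xml(doc), path)
  invisible(path)
}
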