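#' Exponential copy-number perturbation grid
#'
#' Log-spaced multipliers over `[grid_min, grid_max]`, always containing
#' the baseline factor 1.  The default reproduces the x0.001 to x1000
#' sweep at 10 points per decade (61 points).
#'
#' @param grid_min,grid_max positive range limits.
#' @param points number of grid points.
#' @return strictly increasing numeric vector of class `perturbation_grid`.
#' @export
perturbation_grid <- function(grid_min = 0.001, grid_max = 1000,
                              points = 61) {
  stopifnot(grid_min > 0, grid_max > grid_min, points >= 2)
  g <- 10^seq(log10(grid_min), log10(grid_max), length.out = points)
  if (!any(abs(log10(g)) < 1e-9)) g <- sort(unique(c(g, 1)))
  g[abs(log10(g)) < 1e-9] <- 1
  structure(g, class = "perturbation_grid")
}

# maximum sensitivity and scale factor from a (factor, yield) curve;
# ties go to the factor nearest 1 (smallest perturbation, log distance)
summarize_curve <- function(factors, Y, Y0) {
  ok <- is.finite(Y)
  s <- (Y - Y0) / Y0
  best <- max(s[ok])
  cand <- which(ok & abs(s - best) <= 1e-12 * max(1, abs(best)))
  sf <- factors[cand[which.min(abs(log(factors[cand])))]]
  list(max_sensitivity = best, scale_factor = sf)
}

#' Copy-number sweep of one gene unit
#'
#' Simulates the network once per grid factor, each run starting from the
#' unperturbed network with only this unit's copy factor scaled, and
#' summarises the yield curve by the maximum sensitivity
#' `max (Y - Y0)/Y0` and the scale factor `X/X0` at which it is attained.
#'
#' @param network baseline `reaction_network`.
#' @param profile a [growth_profile()].
#' @param config a [sim_config()].
#' @param gene_unit id of the unit to sweep.
#' @param grid a [perturbation_grid()].
#' @param Y0 baseline yield; computed from an unperturbed run if `NULL`.
#' @return object of class `sensitivity_result`: `gene_unit`, `curve`
#'   (data frame `factor`, `yield`), `Y0`, `max_sensitivity`,
#'   `scale_factor`, `failed` (factors whose simulation failed).
#' @export
sweep_gene <- function(network, profile, config = sim_config(),
                       gene_unit, grid = perturbation_grid(), Y0 = NULL) {
  stopifnot(gene_unit %in% gene_ids(network))
  if (is.null(Y0))
    Y0 <- yield_metric(simulate(network, profile, config))
  ys <- vapply(as.numeric(grid), function(f) {
    if (f == 1) return(Y0)
    tryCatch(
      yield_metric(simulate(apply_copy_factor(network, gene_unit, f),
                            profile, config)),
      error = function(e) NA_real_)
  }, numeric(1))
  failed <- as.numeric(grid)[!is.finite(ys)]
  if (length(failed) > length(grid) / 2)
    stop("sweep of ", gene_unit, " failed at more than half the grid ",
         "factors", call. = FALSE)
  sm <- summarize_curve(as.numeric(grid), ys, Y0)
  structure(list(gene_unit = gene_unit,
                 curve = data.frame(factor = as.numeric(grid), yield = ys),
                 Y0 = Y0, max_sensitivity = sm$max_sensitivity,
                 scale_factor = sm$scale_factor, failed = failed),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result> ", x$gene_unit, ": max sensitivity ",
      signif(x$max_sensitivity, 5), " at scale factor ",
      signif(x$scale_factor, 5), " (Y0 = ", signif(x$Y0, 5), ")\n", sep = "")
  invisible(x)
}

#' Rank all gene units by maximum sensitivity
#'
#' Sweeps every (non-deleted) gene unit and returns the ranking table in
#' descending order of maximum sensitivity; ties are broken by unit id.
#'
#' @inheritParams sweep_gene
#' @param units gene unit ids to sweep; defaults to every unit that has
#'   not been knocked out.
#' @param products optional named character vector mapping unit ids to
#'   product descriptions for the table.
#' @param progress print one line per unit as sweeps finish.
#' @return object of class `ranking_table`: a data frame (`rank`, `unit`,
#'   `product`, `max_sensitivity`, `scale_factor`) with the per-unit
#'   [sweep_gene()] results in attribute `"results"`.
#' @export
rank_all <- function(network, profile, config = sim_config(),
                     grid = perturbation_grid(), units = NULL,
                     products = NULL, progress = FALSE) {
  if (is.null(units)) {
    ko <- vapply(network$genes, `[[`, TRUE, "knocked_out")
    units <- gene_ids(network)[!ko]
  }
  if (!length(units)) stop("no gene units to sweep", call. = FALSE)
  Y0 <- yield_metric(simulate(network, profile, config))
  results <- list()
  for (u in units) {
    results[[u]] <- tryCatch(
      sweep_gene(network, profile, config, u, grid, Y0 = Y0),
      error = function(e) {
        message("excluding unit ", u, ": ", conditionMessage(e))
        NULL
      })
    if (progress && !is.null(results[[u]]))
      cat(sprintf("  %-10s max_sens %.5f at %g\n", u,
                  results[[u]]$max_sensitivity, results[[u]]$scale_factor))
  }
  results <- Filter(Negate(is.null), results)
  tb <- data.frame(
    unit = names(results),
    max_sensitivity = vapply(results, `[[`, 0, "max_sensitivity"),
    scale_factor = vapply(results, `[[`, 0, "scale_factor"),
    row.names = NULL)
  tb <- tb[order(-tb$max_sensitivity, tb$unit), ]
  tb$rank <- seq_len(nrow(tb))
  tb$product <- if (is.null(products)) NA_character_ else
    unname(products[tb$unit])
  tb <- tb[, c("rank", "unit", "product", "max_sensitivity", "scale_factor")]
  rownames(tb) <- NULL
  structure(tb, results = results, Y0 = Y0,
            class = c("ranking_table", "data.frame"))
}

#' Dose-response curves of observables under a copy-number sweep
#'
#' For each grid factor, simulates the perturbed network and reports the
#' end-point concentration of each observable relative to the baseline
#' end point (all ratios are exactly 1 at factor 1).
#'
#' @inheritParams sweep_gene
#' @param observables species ids to report.
#' @return data frame with columns `factor`, one column per observable
#'   (ratio to baseline at `t_end`), and `yield`.
#' @export
dose_response <- function(network, profile, config = sim_config(),
                          gene_unit, grid = perturbation_grid(),
                          observables) {
  missing <- setdiff(observables, network$species$id)
  if (length(missing))
    stop("unknown observables: ", paste(missing, collapse = ", "),
         call. = FALSE)
  base <- simulate(network, profile, config)
  nt <- length(base$time)
  ref <- base$states[observables, nt]
  Y0 <- yield_metric(base)
  rows <- lapply(as.numeric(grid), function(f) {
    tc <- if (f == 1) base else
      tryCatch(simulate(apply_copy_factor(network, gene_unit, f),
                        profile, config), error = function(e) NULL)
    if (is.null(tc))
      return(c(f, rep(NA_real_, length(observables) + 1L)))
    c(f, unname(tc$states[observables, nt] / ref),
      tryCatch(yield_metric(tc), error = function(e) NA_real_))
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("factor", observables, "yield")
  out
}

#' Relative-change snapshot under a single perturbation
#'
#' Simulates one perturbed run and reports, for every species
#' (metabolites, mRNAs, proteins), the end-point concentration relative
#' to the baseline end point, plus derived quantities used by the
#' perturbation reports (unphosphorylated ICD fraction, yields).
#'
#' @inheritParams sweep_gene
#' @param factor positive copy-number multiplier.
#' @return list with `ratios` (named vector over all species; `NA` where
#'   the baseline end point is 0), `baseline` and `perturbed` end-point
#'   states, `Y0`, `Y`, and the two timecourses.
#' @export
snapshot_relative_changes <- function(network, profile,
                                      config = sim_config(), gene_unit,
                                      factor) {
  if (factor <= 0) stop("factor must be > 0", call. = FALSE)
  base <- simulate(network, profile, config)
  pert <- simulate(apply_copy_factor(network, gene_unit, factor),
                   profile, config)
  nt <- length(base$time)
  b <- base$states[, nt]
  p <- pert$states[, nt]
  ratios <- ifelse(b > 0, p / b, NA_real_)
  list(ratios = ratios, baseline = b, perturbed = p,
       Y0 = yield_metric(base), Y = yield_metric(pert),
       baseline_tc = base, perturbed_tc = pert)
}
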