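# Bottleneck diagnostics.
#
# The procedure runs in five steps: (1) maximize the pathway MDF B* at a
# required product flux; (2) maximize the product flux with B >= B*;
# (3) fix that flux level and solve pFBA for a parsimonious witness flux
# distribution; (4) with fluxes fixed to the witness, maximize each active
# reaction's own driving force subject to all active reactions keeping
# driving force >= B*; (5) reactions whose maximum equals B* (within
# tolerance) are the bottlenecks.  One bottleneck is a localized
# bottleneck; several that pin B* simultaneously are distributed and are
# coupled through shared limiting metabolites.

# constraint system over log-concentration variables with fluxes fixed:
# every active thermodynamically constrained reaction keeps f >= Bstar
fixed_flux_system <- function(model, config, fluxes, Bstar) {
  rxns <- model$reactions
  mets <- model$metabolites
  nb <- mets$id[!mets$is_boundary]
  active <- which(!is.na(rxns$dG0) & fluxes[rxns$id] > config$flux_tol)
  cb <- conc_bounds(model, config)
  lb <- log(cb$conc_lb[match(nb, cb$id)])
  ub <- log(cb$conc_ub[match(nb, cb$id)])
  rows <- list(); dir <- character(0); rhs <- numeric(0)
  coef_of <- function(j) {
    s <- rxns$stoich[[j]]
    s <- s[names(s) %in% nb]
    row <- numeric(length(nb))
    row[match(names(s), nb)] <- config$RT * as.numeric(s)
    row
  }
  for (j in active) {
    # f_j >= Bstar  <=>  RT sum s lnc <= -dG0 - Bstar
    rows[[length(rows) + 1L]] <- coef_of(j)
    dir <- c(dir, "<="); rhs <- c(rhs, -rxns$dG0[j] - Bstar)
  }
  rc <- config$ratio_constraints
  for (k in seq_len(nrow(rc))) {
    row <- numeric(length(nb))
    row[match(rc$met_a[k], nb)] <- 1
    row[match(rc$met_b[k], nb)] <- -1
    rows[[length(rows) + 1L]] <- row
    dir <- c(dir, "<="); rhs <- c(rhs, log(rc$ratio_ub[k]))
    rows[[length(rows) + 1L]] <- row
    dir <- c(dir, ">="); rhs <- c(rhs, log(rc$ratio_lb[k]))
  }
  list(mat = if (length(rows)) do.call(rbind, rows) else
         matrix(0, 0, length(nb)),
       dir = dir, rhs = rhs, lb = lb, ub = ub, nb = nb,
       active = active, coef_of = coef_of)
}

#' Per-reaction maximum driving forces at a fixed flux distribution
#'
#' With fluxes fixed to a parsimonious witness, maximizes each active
#' reaction's driving force over the log concentrations subject to every
#' active reaction's driving force staying at least `Bstar`.
#'
#' @inheritParams model_thermo
#' @param product product reaction id (recorded, not used in the LPs).
#' @param min_flux required product flux the fixture was computed at.
#' @param Bstar the pathway MDF from the first step, kJ/mol.
#' @param flux_fixture a `solve_result` (typically from [solve_pfba()])
#'   whose fluxes define the active set, or a named flux vector.
#' @return named numeric vector: active thermodynamically constrained
#'   reaction id -> maximum driving force (kJ/mol). Inactive reactions are
#'   absent.
#' @export
reaction_max_driving_forces <- function(model, config = model_thermo(model),
                                        product, min_flux, Bstar,
                                        flux_fixture) {
  fluxes <- if (inherits(flux_fixture, "solve_result")) flux_fixture$fluxes
            else flux_fixture
  sys <- fixed_flux_system(model, config, fluxes, Bstar)
  if (!length(sys$active)) return(stats::setNames(numeric(0), character(0)))
  out <- numeric(0)
  for (j in sys$active) {
    # max f_j = -(dG0_j + RT sum s lnc): minimize the concentration term
    r <- lp_solve(sys$coef_of(j), sys$mat, sys$dir, sys$rhs, sys$lb, sys$ub,
                  maximize = FALSE)
    if (r$status != "optimal")
      stop("driving-force subproblem infeasible at Bstar = ", Bstar,
           " for reaction ", model$reactions$id[j])
    out[model$reactions$id[j]] <- -(model$reactions$dG0[j] + r$objval)
  }
  out
}

#' Concentration variability at the MDF optimum
#'
#' For each requested metabolite, minimizes and maximizes its log
#' concentration subject to all active reactions keeping driving force at
#' least `Bstar`, with fluxes fixed. Metabolites of inactive reactions are
#' unconstrained and report their full bounds.
#'
#' @inheritParams reaction_max_driving_forces
#' @param metabolites metabolite ids to analyze; default all non-boundary
#'   metabolites appearing in active reactions.
#' @return data frame with columns `metabolite`, `conc_min`, `conc_max`
#'   (mol/L).
#' @export
concentration_variability <- function(model, config = model_thermo(model),
                                      product, min_flux, Bstar, flux_fixture,
                                      metabolites = NULL) {
  fluxes <- if (inherits(flux_fixture, "solve_result")) flux_fixture$fluxes
            else flux_fixture
  sys <- fixed_flux_system(model, config, fluxes, Bstar)
  if (is.null(metabolites)) {
    metabolites <- unique(unlist(lapply(sys$active, function(j) {
      s <- model$reactions$stoich[[j]]
      intersect(names(s), sys$nb)
    })))
  }
  out <- lapply(metabolites, function(mm) {
    k <- match(mm, sys$nb)
    if (is.na(k)) stop("unknown or boundary metabolite: ", mm)
    obj <- numeric(length(sys$nb)); obj[k] <- 1
    lo <- lp_solve(obj, sys$mat, sys$dir, sys$rhs, sys$lb, sys$ub)
    hi <- lp_solve(obj, sys$mat, sys$dir, sys$rhs, sys$lb, sys$ub,
                   maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("concentration variability subproblem infeasible for ", mm)
    data.frame(metabolite = mm, conc_min = exp(lo$objval),
               conc_max = exp(hi$objval), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify limiting metabolites
#'
#' A metabolite is limiting when its concentration shows no variability at
#' the MDF optimum (`conc_max / conc_min <= 1 + var_tol`). The reason is
#' `at_lower_bound` / `at_upper_bound` when the pinned concentration sits
#' within `var_tol` (relative) of its bound — reported even if the
#' metabolite is also balanced — else `balanced` when it appears with
#' opposite signs in at least two bottleneck reactions, else `constrained`
#' (pinned indirectly, e.g. through a ratio window).
#'
#' @inheritParams model_thermo
#' @param bottlenecks character vector of bottleneck reaction ids.
#' @param conc_var data frame from [concentration_variability()].
#' @param var_tol relative tolerance for "no variability".
#' @return data frame with columns `metabolite`, `conc_min`, `conc_max`,
#'   `reason`; zero rows when nothing is limiting.
#' @export
identify_limiting_metabolites <- function(model, config = model_thermo(model),
                                          bottlenecks, conc_var,
                                          var_tol = 1e-3) {
  if (is.null(conc_var) || !nrow(conc_var)) {
    return(data.frame(metabolite = character(0), conc_min = numeric(0),
                      conc_max = numeric(0), reason = character(0),
                      stringsAsFactors = FALSE))
  }
  cb <- conc_bounds(model, config)
  rxns <- model$reactions
  bn <- match(bottlenecks, rxns$id)
  out <- list()
  for (i in seq_len(nrow(conc_var))) {
    lo <- conc_var$conc_min[i]; hi <- conc_var$conc_max[i]
    if (hi / lo > 1 + var_tol) next
    mm <- conc_var$metabolite[i]
    k <- match(mm, cb$id)
    reason <- NULL
    if (abs(lo - cb$conc_lb[k]) / cb$conc_lb[k] <= var_tol) {
      reason <- "at_lower_bound"
    } else if (abs(hi - cb$conc_ub[k]) / cb$conc_ub[k] <= var_tol) {
      reason <- "at_upper_bound"
    } else {
      signs <- vapply(bn, function(j) {
        s <- rxns$stoich[[j]]
        if (mm %in% names(s)) sign(s[[mm]]) else 0
      }, numeric(1))
      reason <- if (any(signs > 0) && any(signs < 0)) "balanced"
                else "constrained"
    }
    out[[length(out) + 1L]] <- data.frame(metabolite = mm, conc_min = lo,
                                          conc_max = hi, reason = reason,
                                          stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(metabolite = character(0), conc_min = numeric(0),
                      conc_max = numeric(0), reason = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Identify and classify thermodynamic bottleneck reactions
#'
#' Runs the five-step procedure (max MDF, max flux at that MDF,
#' parsimonious witness, per-reaction driving-force maxima, equality test)
#' and classifies the result as a localized (single reaction) or
#' distributed (several reactions) bottleneck, listing the limiting
#' metabolites shared between them.
#'
#' @inheritParams model_thermo
#' @param product product reaction id.
#' @param min_flux required product flux for the MDF step, mmol/gDW/h.
#' @param enzyme_on include the enzyme budget layer.
#' @param var_tol relative tolerance for limiting-metabolite detection.
#' @param warn_degenerate warn when the parsimonious witness is degenerate
#'   (alternate optima detected by flux variability at the optimum), in
#'   which case the reported bottleneck set depends on the witness.
#' @return an object of class `bottleneck_report`: product, `min_flux`,
#'   `mdf` (B*), `max_flux_at_mdf`, `fluxes` (the witness),
#'   `per_reaction_max_df`, `bottlenecks`, `classification`,
#'   `limiting_metabolites` (data frame with reasons) and
#'   `shared_limiting_mets` (list metabolite -> bottleneck reactions
#'   touching it).
#' @export
identify_bottlenecks <- function(model, config = model_thermo(model),
                                 product, min_flux, enzyme_on = TRUE,
                                 var_tol = 1e-3, warn_degenerate = TRUE) {
  problem <- assemble_constraints(model, config, enzyme_on = enzyme_on,
                                  thermo_on = TRUE)
  tol <- config$mdf_tol
  s1 <- solve_max_mdf(problem, product, min_flux)
  if (s1$status != "optimal")
    stop("MDF step infeasible for product '", product, "' at min_flux ",
         min_flux)
  Bstar <- s1$mdf
  s2 <- solve_max_flux_at_mdf(problem, product, Bstar - tol)
  if (s2$status != "optimal") stop("max-flux-at-MDF step infeasible")
  Fmax <- s2$objective_value
  s3 <- solve_pfba(problem, product, min_flux = Fmax - config$flux_tol,
                   mdf_lb = Bstar - tol)
  if (s3$status != "optimal") stop("pFBA step infeasible")

  if (warn_degenerate) {
    deg <- pfba_degenerate(problem, product, Fmax, Bstar - tol,
                           s3$objective_value)
    if (length(deg))
      warning("parsimonious flux witness is degenerate (alternate optima ",
              "in: ", paste(deg, collapse = ", "),
              "); bottleneck attribution may depend on the witness")
  }

  maxdf <- reaction_max_driving_forces(model, config, product, min_flux,
                                       Bstar, s3)
  bottlenecks <- names(maxdf)[maxdf <= Bstar + tol]
  classification <- if (length(bottlenecks) > 1) "distributed"
                    else if (length(bottlenecks) == 1) "localized"
                    else "none"
  b_mets <- unique(unlist(lapply(match(bottlenecks, model$reactions$id),
                                 function(j) {
    s <- model$reactions$stoich[[j]]
    setdiff(names(s), model$metabolites$id[model$metabolites$is_boundary])
  })))
  cv <- if (length(b_mets))
    concentration_variability(model, config, product, min_flux, Bstar, s3,
                              metabolites = b_mets)
  else NULL
  lim <- identify_limiting_metabolites(model, config, bottlenecks, cv,
                                       var_tol)
  shared <- list()
  for (mm in lim$metabolite) {
    touching <- bottlenecks[vapply(match(bottlenecks, model$reactions$id),
                                   function(j)
                                     mm %in% names(model$reactions$stoich[[j]]),
                                   logical(1))]
    shared[[mm]] <- touching
  }
  structure(list(product = product, min_flux = min_flux, mdf = Bstar,
                 max_flux_at_mdf = Fmax, fluxes = s3$fluxes,
                 per_reaction_max_df = maxdf, bottlenecks = bottlenecks,
                 classification = classification,
                 limiting_metabolites = lim,
                 shared_limiting_mets = shared),
            class = "bottleneck_report")
}

# reactions with alternate optimal flux values at the pFBA optimum
pfba_degenerate <- function(problem, product, Fmax, mdf_lb, total_flux,
                            tol = 1e-6) {
  pm <- problem_matrices(problem)
  j <- match(product, problem$model$reactions$id)
  tot <- numeric(pm$nvar); tot[pm$idx$v] <- 1
  extra <- list(mat = rbind(unit_obj(pm$nvar, pm$idx$v[j]), tot),
                dir = c(">=", "<="),
                rhs = c(Fmax - tol, total_flux + tol))
  lbo <- list(idx = pm$idx$B, val = mdf_lb)
  deg <- character(0)
  for (k in seq_len(nrow(problem$model$reactions))) {
    lo <- solve_problem(problem, unit_obj(pm$nvar, pm$idx$v[k]), FALSE,
                        extra_rows = extra, lb_over = lbo, pm = pm)
    hi <- solve_problem(problem, unit_obj(pm$nvar, pm$idx$v[k]), TRUE,
                        extra_rows = extra, lb_over = lbo, pm = pm)
    if (lo$sol$status == "optimal" && hi$sol$status == "optimal" &&
        hi$sol$objval - lo$sol$objval > 1e-4)
      deg <- c(deg, problem$model$reactions$id[k])
  }
  deg
}

#' @export
print.bottleneck_report <- function(x, ...) {
  cat("bottleneck_report: product ", x$product, ", min_flux ",
      signif(x$min_flux, 6), "\n", sep = "")
  cat("  MDF B* = ", signif(x$mdf, 6), " kJ/mol; max flux at B* = ",
      signif(x$max_flux_at_mdf, 6), "\n", sep = "")
  cat("  ", x$classification, " bottleneck(s): ",
      paste(x$bottlenecks, collapse = ", "), "\n", sep = "")
  if (nrow(x$limiting_metabolites)) {
    cat("  limiting metabolites:\n")
    print(x$limiting_metabolites, row.names = FALSE)
  }
  invisible(x)
}

#' Enzyme-cost variability and key-enzyme prediction
#'
#' With the product flux and the MDF level fixed as constraints (fluxes
#' otherwise free), minimizes and maximizes each reaction's enzyme cost
#' \eqn{e_i = v_i / \mathrm{efficiency}_i}. A reaction is a key-enzyme
#' candidate when its cost shows no variability (range at most `key_tol`)
#' while the total-budget constraint is binding (the constrained space can
#' reach `E_total` within `bind_tol`). Reactions without an efficiency are
#' excluded.
#'
#' @inheritParams identify_bottlenecks
#' @param Bstar MDF level to hold, kJ/mol.
#' @param key_tol cost-range threshold, g/gDW.
#' @param bind_tol binding tolerance on the total budget, g/gDW.
#' @return data frame with columns `reaction`, `cost_min`, `cost_max`
#'   (g/gDW), `is_key`; attribute `"budget_binding"` records the binding
#'   test.
#' @export
enzyme_cost_variability <- function(model, config = model_thermo(model),
                                    product, min_flux, Bstar,
                                    key_tol = 1e-6, bind_tol = 1e-6) {
  rxns <- model$reactions
  eff_i <- which(!is.na(rxns$efficiency))
  if (!length(eff_i)) stop("no reaction carries an efficiency parameter")
  problem <- assemble_constraints(model, config, enzyme_on = TRUE,
                                  thermo_on = TRUE)
  pm <- problem_matrices(problem)
  j <- check_objective_reaction(problem, product)
  extra <- list(mat = matrix(unit_obj(pm$nvar, pm$idx$v[j]), 1),
                dir = ">=", rhs = min_flux)
  lbo <- list(idx = pm$idx$B, val = Bstar - config$mdf_tol)
  # is the proteome budget attainable (and hence limiting)?
  cost_obj <- numeric(pm$nvar)
  cost_obj[pm$idx$v[eff_i]] <- 1 / rxns$efficiency[eff_i]
  mx <- solve_problem(problem, cost_obj, TRUE, extra_rows = extra,
                      lb_over = lbo, pm = pm)
  if (mx$sol$status != "optimal")
    stop("enzyme-cost system infeasible at Bstar = ", Bstar,
         ", min_flux = ", min_flux)
  binding <- mx$sol$objval >= model$total_enzyme_bound - bind_tol
  out <- lapply(eff_i, function(k) {
    lo <- solve_problem(problem, unit_obj(pm$nvar, pm$idx$v[k]), FALSE,
                        extra_rows = extra, lb_over = lbo, pm = pm)
    hi <- solve_problem(problem, unit_obj(pm$nvar, pm$idx$v[k]), TRUE,
                        extra_rows = extra, lb_over = lbo, pm = pm)
    if (lo$sol$status != "optimal" || hi$sol$status != "optimal")
      stop("cost variability subproblem failed for ", rxns$id[k])
    cmin <- lo$sol$objval / rxns$efficiency[k]
    cmax <- hi$sol$objval / rxns$efficiency[k]
    data.frame(reaction = rxns$id[k], cost_min = cmin, cost_max = cmax,
               is_key = (cmax - cmin <= key_tol) && binding,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "budget_binding") <- binding
  res
}
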