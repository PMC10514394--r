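# Assembly and solution of the multi-constraint optimization problems.
#
# Constraint layers on top of mass balance S v = 0:
#  * enzyme:  sum_i v_i / efficiency_i <= E_total.  Units: flux in
#    mmol/gDW/h over efficiency in 1/h/kDa gives mmol*kDa/gDW = g/gDW,
#    since 1 kDa = 1 g/mmol.
#  * thermodynamics: log-concentration variables ln c_j within
#    [ln conc_lb, ln conc_ub], cofactor ratio windows, a binary activity
#    indicator z_i per reaction carrying a dG0, flux linking
#    v_i <= flux_ub_i * z_i, and the max-min driving-force coupling
#    f_i >= B - M (1 - z_i) with f_i = -(dG0_i + RT sum_j s_ij ln c_j).
# B is free in sign: a negative optimum is reported as-is and
# "thermodynamically infeasible" is an interpretation (B < 0), not a solver
# constraint.

#' Thermodynamic driving force of a reaction
#'
#' Evaluates \eqn{f = -\Delta_r G' = -(\Delta_r G'^0 + RT \sum_j s_{ij}
#' \ln c_j)} at given log concentrations (natural log of the concentration
#' in mol/L; reference state 1 M). Boundary metabolites contribute no term.
#'
#' @inheritParams model_thermo
#' @param reaction a reaction id present in the model.
#' @param log_conc named numeric vector of log concentrations covering every
#'   non-boundary metabolite of the reaction.
#' @return driving force in kJ/mol (positive = forward-feasible).
#' @examples
#' m <- gen_linear_chain(generator_config(), dG0_list = c(-5, 10))
#' driving_force(m, "R1", c(A = log(1e-3), B = log(1e-3)))
#' @export
driving_force <- function(model, reaction, log_conc,
                          config = model_thermo(model)) {
  j <- match(reaction, model$reactions$id)
  if (is.na(j)) stop("unknown reaction: ", reaction)
  dG0 <- model$reactions$dG0[j]
  if (is.na(dG0))
    stop("reaction '", reaction, "' has no dG0: it is thermo-exempt")
  s <- model$reactions$stoich[[j]]
  bnd <- model$metabolites$id[model$metabolites$is_boundary]
  s <- s[!(names(s) %in% bnd)]
  miss <- setdiff(names(s), names(log_conc))
  if (length(miss))
    stop("missing log-concentration for metabolite(s): ",
         paste(miss, collapse = ", "))
  -(dG0 + config$RT * sum(s * log_conc[names(s)]))
}

#' Assemble a multi-constraint optimization problem
#'
#' Binds a validated, direction-split model to a thermodynamic
#' configuration and the constraint-layer switches. The returned problem is
#' consumed by [solve_fba()], [solve_pfba()], [solve_max_mdf()] and
#' [solve_max_flux_at_mdf()].
#'
#' @inheritParams model_thermo
#' @param enzyme_on include the total enzyme budget constraint.
#' @param thermo_on include concentration variables, ratio windows and the
#'   driving-force MILP layer.
#' @return an object of class `opt_problem`.
#' @export
assemble_constraints <- function(model, config = model_thermo(model),
                                 enzyme_on = TRUE, thermo_on = TRUE) {
  v <- validate_model(model, config)
  if (nrow(v))
    stop("model failed validation (", nrow(v), " finding(s)); see validate_model()")
  if (any(model$reactions$reversible))
    stop("model contains reversible reactions; run split_reversible() first")
  cb <- conc_bounds(model, config)
  if (thermo_on) {
    # big-M audit: M must dominate |dG0| plus the largest concentration term
    idx <- which(!is.na(model$reactions$dG0))
    for (j in idx) {
      s <- model$reactions$stoich[[j]]
      keep <- names(s) %in% cb$id[!model$metabolites$is_boundary]
      span <- 0
      for (mm in names(s)[keep]) {
        k <- match(mm, cb$id)
        span <- span + abs(s[[mm]]) *
          max(abs(log(cb$conc_lb[k])), abs(log(cb$conc_ub[k])))
      }
      if (abs(model$reactions$dG0[j]) + config$RT * span >= config$bigM)
        stop("bigM = ", config$bigM, " too small for reaction '",
             model$reactions$id[j], "' (needs > ",
             round(abs(model$reactions$dG0[j]) + config$RT * span, 1), ")")
    }
  }
  structure(list(model = model, config = config,
                 enzyme_on = enzyme_on, thermo_on = thermo_on),
            class = "opt_problem")
}

#' @export
print.opt_problem <- function(x, ...) {
  cat("opt_problem: ", nrow(x$model$reactions), " reactions, enzyme ",
      if (x$enzyme_on) "on" else "off", ", thermo ",
      if (x$thermo_on) "on" else "off", "\n", sep = "")
  invisible(x)
}

# --- internal MILP scaffolding ---------------------------------------------

# variable layout and constraint matrices for a problem instance
problem_matrices <- function(problem) {
  model <- problem$model; config <- problem$config
  rxns <- model$reactions
  mets <- model$metabolites
  nb <- mets$id[!mets$is_boundary]
  nr <- nrow(rxns)
  thermo_rxns <- if (problem$thermo_on) which(!is.na(rxns$dG0)) else integer(0)
  n_lnc <- if (problem$thermo_on) length(nb) else 0L
  idx <- list(v = seq_len(nr))
  p <- nr
  if (problem$thermo_on) {
    idx$lnc <- p + seq_len(n_lnc); p <- p + n_lnc
    idx$B <- p + 1L; p <- p + 1L
    idx$z <- p + seq_along(thermo_rxns); p <- p + length(thermo_rxns)
  }
  nvar <- p
  lb <- numeric(nvar); ub <- numeric(nvar)
  lb[idx$v] <- pmax(rxns$flux_lb, 0)
  ub[idx$v] <- rxns$flux_ub
  shut <- rxns$status == "shut"
  lb[idx$v][shut] <- 0; ub[idx$v][shut] <- 0
  cb <- conc_bounds(model, config)
  rows <- list(); dir <- character(0); rhs <- numeric(0)
  addrow <- function(coef_idx, coef_val, d, r) {
    row <- numeric(nvar); row[coef_idx] <- coef_val
    rows[[length(rows) + 1L]] <<- row
    dir <<- c(dir, d); rhs <<- c(rhs, r)
  }
  # mass balance over non-boundary metabolites
  S <- stoich_matrix(model)
  for (i in seq_len(nrow(S))) {
    nz <- which(S[i, ] != 0)
    if (length(nz)) addrow(idx$v[nz], S[i, nz], "=", 0)
  }
  # enzyme budget
  if (problem$enzyme_on) {
    eff_i <- which(!is.na(rxns$efficiency))
    if (length(eff_i))
      addrow(idx$v[eff_i], 1 / rxns$efficiency[eff_i], "<=",
             model$total_enzyme_bound)
  }
  if (problem$thermo_on) {
    lnc_lb <- log(cb$conc_lb[match(nb, cb$id)])
    lnc_ub <- log(cb$conc_ub[match(nb, cb$id)])
    lb[idx$lnc] <- lnc_lb; ub[idx$lnc] <- lnc_ub
    lb[idx$B] <- -Inf; ub[idx$B] <- Inf
    lb[idx$z] <- 0; ub[idx$z] <- 1
    M <- config$bigM; RT <- config$RT
    for (k in seq_along(thermo_rxns)) {
      j <- thermo_rxns[k]
      s <- rxns$stoich[[j]]
      s <- s[names(s) %in% nb]
      cols <- idx$lnc[match(names(s), nb)]
      # RT * sum s ln c + B + M z <= -dG0 + M
      addrow(c(cols, idx$B, idx$z[k]),
             c(RT * as.numeric(s), 1, M), "<=", -rxns$dG0[j] + M)
      # v <= flux_ub * z (uses the shut-adjusted upper bound)
      addrow(c(idx$v[j], idx$z[k]), c(1, -ub[idx$v[j]]), "<=", 0)
    }
    if (length(thermo_rxns)) addrow(idx$z, rep(1, length(idx$z)), ">=", 1)
    rc <- config$ratio_constraints
    for (k in seq_len(nrow(rc))) {
      a <- idx$lnc[match(rc$met_a[k], nb)]
      b <- idx$lnc[match(rc$met_b[k], nb)]
      addrow(c(a, b), c(1, -1), "<=", log(rc$ratio_ub[k]))
      addrow(c(a, b), c(1, -1), ">=", log(rc$ratio_lb[k]))
    }
  }
  list(nvar = nvar, idx = idx, lb = lb, ub = ub,
       mat = if (length(rows)) do.call(rbind, rows) else matrix(0, 0, nvar),
       dir = dir, rhs = rhs,
       thermo_rxns = thermo_rxns, nb = nb)
}

# package a raw solver result into a solve_result
as_solve_result <- function(problem, pm, sol, objective_value = sol$objval) {
  model <- problem$model; rxns <- model$reactions
  if (sol$status != "optimal") {
    return(structure(list(status = sol$status, objective_value = NA_real_,
                          fluxes = NULL, log_conc = NULL, mdf = NA_real_,
                          active = NULL, enzyme_costs = NULL),
                     class = "solve_result"))
  }
  x <- sol$x
  fluxes <- stats::setNames(x[pm$idx$v], rxns$id)
  log_conc <- NULL; mdf <- NA_real_; active <- NULL
  if (problem$thermo_on) {
    log_conc <- stats::setNames(x[pm$idx$lnc], pm$nb)
    mdf <- x[pm$idx$B]
    active <- stats::setNames(rep(NA_real_, nrow(rxns)), rxns$id)
    active[rxns$id[pm$thermo_rxns]] <- round(x[pm$idx$z])
  }
  costs <- ifelse(is.na(rxns$efficiency), NA_real_, fluxes / rxns$efficiency)
  names(costs) <- rxns$id
  structure(list(status = "optimal", objective_value = objective_value,
                 fluxes = fluxes, log_conc = log_conc, mdf = mdf,
                 active = active, enzyme_costs = costs),
            class = "solve_result")
}

#' @export
print.solve_result <- function(x, ...) {
  cat("solve_result: ", x$status, sep = "")
  if (x$status == "optimal") {
    cat("; objective ", signif(x$objective_value, 6), sep = "")
    if (!is.na(x$mdf)) cat("; MDF ", signif(x$mdf, 6), " kJ/mol", sep = "")
  }
  cat("\n")
  invisible(x)
}

# run the MILP/LP for a problem with optional row/bound adjustments
solve_problem <- function(problem, obj, maximize, extra_rows = NULL,
                          lb_over = NULL, ub_over = NULL, pm = NULL) {
  if (is.null(pm)) pm <- problem_matrices(problem)
  mat <- pm$mat; dir <- pm$dir; rhs <- pm$rhs
  if (!is.null(extra_rows)) {
    mat <- rbind(mat, extra_rows$mat)
    dir <- c(dir, extra_rows$dir)
    rhs <- c(rhs, extra_rows$rhs)
  }
  lb <- pm$lb; ub <- pm$ub
  if (!is.null(lb_over)) lb[lb_over$idx] <- lb_over$val
  if (!is.null(ub_over)) ub[ub_over$idx] <- ub_over$val
  sol <- milp_solve(obj, mat, dir, rhs, lb, ub,
                    bin_idx = if (problem$thermo_on) pm$idx$z else integer(0),
                    maximize = maximize)
  list(pm = pm, sol = sol)
}

unit_obj <- function(n, i, val = 1) { o <- numeric(n); o[i] <- val; o }

check_objective_reaction <- function(problem, id) {
  j <- match(id, problem$model$reactions$id)
  if (is.na(j)) stop("objective reaction '", id, "' not in model")
  j
}

# --- public solvers ---------------------------------------------------------

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux through a reaction subject to the
#' constraint layers enabled in the problem. With the thermodynamic layer on
#' this is a mixed-integer program; infeasibility and unboundedness are
#' returned in the result status, not raised.
#'
#' @param problem an [assemble_constraints()] problem.
#' @param objective_reaction reaction id to optimize.
#' @param sense `"max"` or `"min"`.
#' @return a `solve_result`.
#' @export
solve_fba <- function(problem, objective_reaction, sense = "max") {
  j <- check_objective_reaction(problem, objective_reaction)
  pm <- problem_matrices(problem)
  r <- solve_problem(problem, unit_obj(pm$nvar, pm$idx$v[j]),
                     maximize = identical(sense, "max"), pm = pm)
  as_solve_result(problem, pm, r$sol)
}

#' Parsimonious flux balance analysis
#'
#' Two-stage lexicographic solve: the objective flux is first maximized
#' (or taken from `min_flux` when supplied), then fixed to its optimum
#' within `flux_tol` while the total flux \eqn{\sum_i v_i} is minimized.
#' After direction splitting all fluxes are non-negative, so the total flux
#' is a linear objective.
#'
#' @inheritParams solve_fba
#' @param min_flux optional required objective flux; when given, stage one
#'   is skipped and the objective is constrained to at least this value.
#' @param mdf_lb optional lower bound on the pathway MDF variable B
#'   (thermodynamic layer must be enabled).
#' @return a `solve_result` whose `objective_value` is the minimized total
#'   flux; the objective reaction's flux is in `fluxes`.
#' @export
solve_pfba <- function(problem, objective_reaction, min_flux = NULL,
                       mdf_lb = NULL) {
  j <- check_objective_reaction(problem, objective_reaction)
  pm <- problem_matrices(problem)
  lb_over <- NULL
  if (!is.null(mdf_lb)) {
    if (!problem$thermo_on) stop("mdf_lb requires the thermodynamic layer")
    lb_over <- list(idx = pm$idx$B, val = mdf_lb)
  }
  if (is.null(min_flux)) {
    r1 <- solve_problem(problem, unit_obj(pm$nvar, pm$idx$v[j]),
                        maximize = TRUE, lb_over = lb_over, pm = pm)
    if (r1$sol$status != "optimal") return(as_solve_result(problem, pm, r1$sol))
    min_flux <- r1$sol$objval - problem$config$flux_tol
  }
  extra <- list(mat = matrix(unit_obj(pm$nvar, pm$idx$v[j]), 1),
                dir = ">=", rhs = min_flux)
  obj <- numeric(pm$nvar); obj[pm$idx$v] <- 1
  r2 <- solve_problem(problem, obj, maximize = FALSE, extra_rows = extra,
                      lb_over = lb_over, pm = pm)
  as_solve_result(problem, pm, r2$sol)
}

#' Maximize the pathway max-min driving force (MDF)
#'
#' Finds the largest B such that, for some concentration assignment within
#' bounds and some flux distribution delivering at least `min_flux` through
#' the product reaction, every active thermodynamically constrained
#' reaction has driving force at least B.
#'
#' @inheritParams solve_fba
#' @param product_reaction reaction id whose flux is required.
#' @param min_flux required product flux, mmol/gDW/h.
#' @return a `solve_result` with the MDF in `mdf` (equal to
#'   `objective_value`), the witness fluxes, log concentrations and the
#'   activity indicator per thermodynamically constrained reaction.
#' @export
solve_max_mdf <- function(problem, product_reaction, min_flux) {
  if (!problem$thermo_on) stop("solve_max_mdf requires the thermodynamic layer")
  j <- check_objective_reaction(problem, product_reaction)
  pm <- problem_matrices(problem)
  extra <- list(mat = matrix(unit_obj(pm$nvar, pm$idx$v[j]), 1),
                dir = ">=", rhs = min_flux)
  r <- solve_problem(problem, unit_obj(pm$nvar, pm$idx$B),
                     maximize = TRUE, extra_rows = extra, pm = pm)
  as_solve_result(problem, pm, r$sol)
}

#' Maximize product flux at a guaranteed MDF level
#'
#' Maximizes the product flux subject to the pathway MDF variable B being at
#' least `mdf_lb`.
#'
#' @inheritParams solve_max_mdf
#' @param mdf_lb lower bound on B, kJ/mol.
#' @return a `solve_result`.
#' @export
solve_max_flux_at_mdf <- function(problem, product_reaction, mdf_lb) {
  if (!problem$thermo_on) stop("solve_max_flux_at_mdf requires the thermodynamic layer")
  j <- check_objective_reaction(problem, product_reaction)
  pm <- problem_matrices(problem)
  r <- solve_problem(problem, unit_obj(pm$nvar, pm$idx$v[j]), maximize = TRUE,
                     lb_over = list(idx = pm$idx$B, val = mdf_lb), pm = pm)
  as_solve_result(problem, pm, r$sol)
}

#' Export the assembled problem as LP-format text
#'
#' Writes the constraint system (with a chosen linear objective) in CPLEX LP
#' format for inspection or debugging with external tools.
#'
#' @inheritParams solve_fba
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_lp <- function(problem, objective_reaction, path) {
  j <- check_objective_reaction(problem, objective_reaction)
  pm <- problem_matrices(problem)
  vn <- character(pm$nvar)
  vn[pm$idx$v] <- paste0("v_", problem$model$reactions$id)
  if (problem$thermo_on) {
    vn[pm$idx$lnc] <- paste0("lnc_", pm$nb)
    vn[pm$idx$B] <- "B"
    vn[pm$idx$z] <- paste0("z_", problem$model$reactions$id[pm$thermo_rxns])
  }
  vn <- gsub("[^A-Za-z0-9_]", "_", vn)
  term <- function(row) {
    nz <- which(row != 0)
    paste(sprintf("%+.12g %s", row[nz], vn[nz]), collapse = " ")
  }
  lines <- c("Maximize", paste(" obj:", vn[pm$idx$v[j]]), "Subject To")
  for (i in seq_len(nrow(pm$mat))) {
    op <- c("<=" = "<=", ">=" = ">=", "=" = "=")[pm$dir[i]]
    lines <- c(lines, sprintf(" c%d: %s %s %.12g", i, term(pm$mat[i, ]), op,
                              pm$rhs[i]))
  }
  lines <- c(lines, "Bounds")
  for (k in seq_len(pm$nvar)) {
    lines <- c(lines, sprintf(" %.12g <= %s <= %.12g", pm$lb[k], vn[k], pm$ub[k]))
  }
  if (problem$thermo_on && length(pm$idx$z)) {
    lines <- c(lines, "Binaries", paste("", paste(vn[pm$idx$z], collapse = " ")))
  }
  lines <- c(lines, "End")
  writeLines(lines, path)
  invisible(path)
}

#' Write solver results as tab-separated report files
#'
#' @param result a `solve_result`.
#' @param prefix file path prefix; writes `<prefix>_fluxes.tsv` (reaction,
#'   flux, enzyme cost, activity) and, when the thermodynamic layer was on,
#'   `<prefix>_concentrations.tsv` (metabolite, ln concentration).
#' @return character vector of files written, invisibly.
#' @export
write_solve_result <- function(result, prefix) {
  files <- character(0)
  if (result$status != "optimal") stop("no optimal result to write")
  f1 <- paste0(prefix, "_fluxes.tsv")
  utils::write.table(
    data.frame(reaction = names(result$fluxes), flux = result$fluxes,
               enzyme_cost = result$enzyme_costs[names(result$fluxes)],
               active = result$active[names(result$fluxes)]),
    f1, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- f1
  if (!is.null(result$log_conc)) {
    f2 <- paste0(prefix, "_concentrations.tsv")
    utils::write.table(
      data.frame(metabolite = names(result$log_conc),
                 ln_conc = result$log_conc),
      f2, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f2)
  }
  invisible(files)
}
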