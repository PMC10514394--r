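# Structural model correction: merging partial reactions catalyzed within
# one enzyme structure (multifunctional enzyme, complex, or channel) into an
# overall reaction, shutting the partials, and detecting reactions that are
# structurally redundant in flux balance analysis.

#' Specification of a reaction merge
#'
#' Describes the replacement of two or more partial reactions by their
#' multiplier-weighted overall reaction. Metabolites whose net coefficient
#' in the weighted sum is zero (channelled intermediates, cancelled cofactor
#' pairs) disappear from the merged equation.
#'
#' @param merged_id id of the overall reaction to create.
#' @param parts character vector (length >= 2) of partial reaction ids, or a
#'   named integer vector `c(id = multiplier, ...)`.
#' @param multipliers positive integer multipliers, recycled against
#'   `parts`; ignored when `parts` is named.
#' @param declared_intermediates optional metabolite ids that must cancel
#'   exactly in the weighted sum (audit aid; an error is raised otherwise).
#' @param dG0_override optional standard reaction energy (kJ/mol) assigned
#'   to the merged reaction instead of the additivity value; the additivity
#'   value is still computed and recorded in the audit trail.
#' @param reversible_pair also create `<merged_id>_r` with negated
#'   stoichiometry and standard energy (for merges of reversible pairs).
#' @return an object of class `merge_spec`.
#' @export
merge_spec <- function(merged_id, parts, multipliers = 1L,
                       declared_intermediates = NULL, dG0_override = NULL,
                       reversible_pair = FALSE) {
  if (!is.null(names(parts)) && all(nzchar(names(parts)))) {
    multipliers <- as.integer(parts)
    parts <- names(parts)
  } else {
    multipliers <- as.integer(rep_len(multipliers, length(parts)))
  }
  if (length(parts) < 2) stop("a merge needs at least 2 parts")
  if (any(multipliers < 1)) stop("multipliers must be positive integers")
  structure(list(merged_id = merged_id, parts = parts,
                 multipliers = multipliers,
                 declared_intermediates = declared_intermediates,
                 dG0_override = dG0_override,
                 reversible_pair = isTRUE(reversible_pair)),
            class = "merge_spec")
}

#' Merge partial reactions into an overall reaction
#'
#' Computes the multiplier-weighted stoichiometric sum of the parts, drops
#' metabolites whose net coefficient cancels, and adds the overall reaction
#' with: standard reaction energy equal to the weighted sum of the parts'
#' energies (exact additivity; the concentration terms of cancelled
#' intermediates cancel algebraically, so the merged driving force equals
#' the sum of the partial driving forces at any concentration vector);
#' uncertainty combined as the root-sum-square of the weighted parts;
#' catalytic efficiency equal to the minimum over the parts (the overall
#' rate is limited by the kinetically weakest step); genes equal to the
#' union. The parts are shut; the merged reaction gets status `"added"`,
#' flux bounds `ub = min(ub_k / mult_k)`, `lb = max(lb_k / mult_k)`.
#'
#' @inheritParams model_thermo
#' @param spec a [merge_spec()].
#' @return an object of class `merge_result`: list with `new_model`,
#'   `merged_reaction` (one-row data frame), `cancelled` (metabolite ids),
#'   `shut` (reaction ids), `dG0_additivity` and `audit` (character trail).
#' @examples
#' m <- gen_coupled_motif()
#' res <- merge_reactions(split_reversible(m), motif_merge_spec())
#' res$merged_reaction$dG0   # -5 = 15 + (-20)
#' @export
merge_reactions <- function(model, spec) {
  rxns <- model$reactions
  jj <- match(spec$parts, rxns$id)
  if (anyNA(jj))
    stop("unknown part reaction(s): ",
         paste(spec$parts[is.na(jj)], collapse = ", "))
  if (any(rxns$reversible[jj]))
    stop("parts must be irreversible; run split_reversible() first")
  if (spec$merged_id %in% rxns$id)
    stop("merged id '", spec$merged_id, "' already exists")
  audit <- character(0)
  note <- function(...) audit <<- c(audit, paste0(...))

  # multiplier-weighted stoichiometric sum
  acc <- numeric(0)
  for (k in seq_along(jj)) {
    s <- rxns$stoich[[jj[k]]] * spec$multipliers[k]
    for (mm in names(s)) acc[mm] <- (if (mm %in% names(acc)) acc[mm] else 0) + s[[mm]]
  }
  cancelled <- names(acc)[abs(acc) < 1e-12]
  merged_stoich <- acc[abs(acc) >= 1e-12]
  if (!length(merged_stoich))
    stop("all metabolites cancel: the weighted sum is the empty reaction")
  if (!is.null(spec$declared_intermediates)) {
    resid <- setdiff(spec$declared_intermediates, cancelled)
    if (length(resid)) {
      rv <- acc[resid]; rv[is.na(rv)] <- 0
      stop("declared intermediate(s) do not cancel: ",
           paste(sprintf("%s (residual %+g)", resid, rv), collapse = ", "))
    }
  } else if (!length(cancelled)) {
    warning("no metabolite cancels in merge '", spec$merged_id,
            "': pure lumping of unconnected reactions")
  }
  note("parts: ", paste(sprintf("%dx %s", spec$multipliers, spec$parts),
                        collapse = " + "))
  note("cancelled intermediates: ",
       if (length(cancelled)) paste(cancelled, collapse = ", ") else "(none)")

  dg_parts <- rxns$dG0[jj]
  dG0_add <- if (anyNA(dg_parts)) NA_real_ else sum(spec$multipliers * dg_parts)
  note("dG0 additivity value: ", format(dG0_add))
  dG0 <- if (!is.null(spec$dG0_override)) {
    note("dG0 override applied: ", format(spec$dG0_override))
    spec$dG0_override
  } else dG0_add
  sd_parts <- rxns$dG0_sd[jj]
  dG0_sd <- if (all(is.na(sd_parts))) NA_real_ else
    sqrt(sum((spec$multipliers * sd_parts)^2, na.rm = TRUE))
  effs <- rxns$efficiency[jj]
  eff <- if (all(is.na(effs))) NA_real_ else min(effs, na.rm = TRUE)
  genes <- unique(unlist(rxns$genes[jj]))
  rules <- unique(rxns$gene_rule[jj][nzchar(rxns$gene_rule[jj])])
  rule <- if (length(rules)) paste0("(", rules, ")", collapse = " and ") else ""

  merged <- rxn_df(spec$merged_id, merged_stoich, dG0 = dG0, dG0_sd = dG0_sd,
                   efficiency = eff,
                   flux_lb = max(rxns$flux_lb[jj] / spec$multipliers),
                   flux_ub = min(rxns$flux_ub[jj] / spec$multipliers),
                   gene_rule = rule, status = "added")
  merged$genes <- list(genes)

  new_model <- shut_reactions(model, spec$parts)
  new_model$reactions <- rbind(new_model$reactions, merged)
  if (spec$reversible_pair) {
    mirrored <- merged
    mirrored$id <- paste0(spec$merged_id, "_r")
    mirrored$name <- mirrored$id
    mirrored$stoich <- list(-merged_stoich)
    mirrored$dG0 <- if (is.na(dG0)) NA_real_ else -dG0
    new_model$reactions <- rbind(new_model$reactions, mirrored)
    note("reversible pair: added ", mirrored$id, " with dG0 ",
         format(mirrored$dG0))
  }
  rownames(new_model$reactions) <- NULL
  structure(list(new_model = new_model, merged_reaction = merged,
                 cancelled = cancelled, shut = spec$parts,
                 dG0_additivity = dG0_add, audit = audit),
            class = "merge_result")
}

#' @export
print.merge_result <- function(x, ...) {
  s <- x$merged_reaction$stoich[[1]]
  lhs <- s[s < 0]; rhs <- s[s > 0]
  eq <- paste(paste(sprintf("%g %s", -lhs, names(lhs)), collapse = " + "),
              "-->",
              paste(sprintf("%g %s", rhs, names(rhs)), collapse = " + "))
  cat("merge_result: ", x$merged_reaction$id, ": ", eq, "\n", sep = "")
  cat("  dG0 = ", format(x$merged_reaction$dG0), " kJ/mol; shut: ",
      paste(x$shut, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Shut reactions
#'
#' Sets the listed reactions' status to `"shut"` and their flux bounds to
#' zero; idempotent.
#'
#' @inheritParams model_thermo
#' @param ids reaction ids to shut.
#' @return the modified model.
#' @export
shut_reactions <- function(model, ids) {
  jj <- match(ids, model$reactions$id)
  if (anyNA(jj))
    stop("unknown reaction id(s): ", paste(ids[is.na(jj)], collapse = ", "))
  model$reactions$status[jj] <- "shut"
  model$reactions$flux_lb[jj] <- 0
  model$reactions$flux_ub[jj] <- 0
  model
}

#' Detect structurally redundant reactions
#'
#' Flags, on a direction-split model (shut reactions ignored):
#' \describe{
#'   \item{orphan-substrate}{the reaction consumes a metabolite that no
#'     other open reaction produces, so it can never carry steady-state
#'     flux;}
#'   \item{dead-end-product}{the reaction produces a metabolite that
#'     nothing consumes or exports;}
#'   \item{blocked}{flux variability analysis at zero demand gives a zero
#'     flux range (catches redundancy that is not visible locally).}
#' }
#'
#' @inheritParams model_thermo
#' @return data frame with columns `reaction`, `reason`.
#' @export
find_redundant_reactions <- function(model) {
  if (any(model$reactions$reversible))
    stop("run split_reversible() first")
  rxns <- model$reactions
  open <- which(rxns$status != "shut")
  bnd <- model$metabolites$id[model$metabolites$is_boundary]
  out <- list()
  flag <- function(id, reason)
    out[[length(out) + 1L]] <<- data.frame(reaction = id, reason = reason,
                                           stringsAsFactors = FALSE)
  prod_by <- list(); cons_by <- list()
  for (j in open) {
    s <- rxns$stoich[[j]]
    for (mm in names(s)[s > 0]) prod_by[[mm]] <- c(prod_by[[mm]], j)
    for (mm in names(s)[s < 0]) cons_by[[mm]] <- c(cons_by[[mm]], j)
  }
  # a reaction and its exact mirror (a split reversible pair) do not count
  # as each other's producer/consumer: the pair would mask its own isolation
  mirrors <- function(j) {
    s <- rxns$stoich[[j]]
    open[vapply(open, function(k) {
      q <- rxns$stoich[[k]]
      length(q) == length(s) && setequal(names(q), names(s)) &&
        all(q[names(s)] == -s)
    }, logical(1))]
  }
  structural <- character(0)
  for (j in open) {
    s <- rxns$stoich[[j]]
    subs <- setdiff(names(s)[s < 0], bnd)
    prods <- setdiff(names(s)[s > 0], bnd)
    skip <- c(j, mirrors(j))
    orphan <- subs[vapply(subs, function(mm)
      !length(setdiff(prod_by[[mm]], skip)), logical(1))]
    dead <- prods[vapply(prods, function(mm)
      !length(setdiff(cons_by[[mm]], skip)), logical(1))]
    if (length(orphan)) {
      flag(rxns$id[j], paste0("orphan-substrate: ",
                              paste(orphan, collapse = ", ")))
      structural <- c(structural, rxns$id[j])
    }
    if (length(dead)) {
      flag(rxns$id[j], paste0("dead-end-product: ",
                              paste(dead, collapse = ", ")))
      structural <- c(structural, rxns$id[j])
    }
  }
  # FVA at zero demand for the rest
  S <- stoich_matrix(model)
  nr <- nrow(rxns)
  lb <- pmax(rxns$flux_lb, 0); ub <- rxns$flux_ub
  shut <- rxns$status == "shut"
  lb[shut] <- 0; ub[shut] <- 0
  dirs <- rep("=", nrow(S)); rhs <- rep(0, nrow(S))
  for (j in open) {
    if (rxns$id[j] %in% structural) next
    r <- lp_solve(unit_obj(nr, j), S, dirs, rhs, lb, ub, maximize = TRUE)
    if (r$status == "optimal" && r$objval <= 1e-9)
      flag(rxns$id[j], "blocked")
  }
  if (!length(out))
    return(data.frame(reaction = character(0), reason = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Hints for merge candidates from shared genes
#'
#' Lists pairs of open reactions sharing at least one gene — candidate
#' partial reactions of one multifunctional enzyme or complex. Merging
#' remains user-directed; this is a screen, not a decision.
#'
#' @inheritParams model_thermo
#' @return data frame with columns `reaction_a`, `reaction_b`,
#'   `shared_genes`.
#' @export
merge_hints <- function(model) {
  rxns <- model$reactions
  open <- which(rxns$status != "shut" &
                  vapply(rxns$genes, length, integer(1)) > 0)
  out <- list()
  if (length(open) > 1) {
    for (a in seq_along(open)[-length(open)]) {
      for (b in seq((a + 1), length(open))) {
        shared <- intersect(rxns$genes[[open[a]]], rxns$genes[[open[b]]])
        if (length(shared))
          out[[length(out) + 1L]] <- data.frame(
            reaction_a = rxns$id[open[a]], reaction_b = rxns$id[open[b]],
            shared_genes = paste(shared, collapse = ";"),
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(reaction_a = character(0), reaction_b = character(0),
                      shared_genes = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Switch between aerobic and anaerobic scenarios
#'
#' Anaerobic closes the oxygen exchange reaction (bounds set to zero) after
#' recording the original bounds; aerobic restores them.
#'
#' @inheritParams model_thermo
#' @param scenario `"aerobic"` or `"anaerobic"`.
#' @param o2_exchange id of the oxygen exchange reaction; by default the
#'   first reaction id matching `^EX_o2` (case-insensitive).
#' @return the modified model.
#' @export
apply_scenario <- function(model, scenario = c("aerobic", "anaerobic"),
                           o2_exchange = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(o2_exchange)) {
    hit <- grep("^EX_o2", model$reactions$id, ignore.case = TRUE, value = TRUE)
    o2_exchange <- if (length(hit)) hit[1] else NULL
  }
  if (scenario == "anaerobic") {
    if (is.null(o2_exchange) || !o2_exchange %in% model$reactions$id)
      stop("oxygen exchange reaction not found; pass o2_exchange explicitly")
    j <- match(o2_exchange, model$reactions$id)
    attr(model, "o2_restore") <- list(id = o2_exchange,
                                      lb = model$reactions$flux_lb[j],
                                      ub = model$reactions$flux_ub[j])
    model$reactions$flux_lb[j] <- 0
    model$reactions$flux_ub[j] <- 0
  } else {
    rest <- attr(model, "o2_restore")
    if (!is.null(rest)) {
      j <- match(rest$id, model$reactions$id)
      if (!is.na(j)) {
        model$reactions$flux_lb[j] <- rest$lb
        model$reactions$flux_ub[j] <- rest$ub
      }
      attr(model, "o2_restore") <- NULL
    }
  }
  model
}

#' Read a batch of merge specifications from YAML
#'
#' The file is a list of entries with fields `merged_id`, `parts` (list of
#' `{reaction, multiplier}` or plain ids), and optionally
#' `declared_intermediates`, `dG0_override`, `reversible_pair`, plus an
#' optional top-level `shut` list of reaction ids to shut outright.
#'
#' @param path YAML file path.
#' @return list with elements `specs` (list of [merge_spec()]) and `shut`
#'   (character vector).
#' @export
read_merge_specs <- function(path) {
  if (!file.exists(path)) stop("merge spec file not found: ", path)
  doc <- yaml::read_yaml(path)
  entries <- if (!is.null(doc$merges)) doc$merges else doc
  shut <- as.character(unlist(doc$shut))
  specs <- lapply(entries, function(e) {
    if (is.null(e$merged_id)) return(NULL)
    parts <- e$parts
    if (is.list(parts) && !is.null(parts[[1]]$reaction)) {
      ids <- vapply(parts, function(p) p$reaction, character(1))
      mult <- vapply(parts, function(p)
        if (is.null(p$multiplier)) 1L else as.integer(p$multiplier), integer(1))
    } else {
      ids <- as.character(unlist(parts)); mult <- 1L
    }
    merge_spec(e$merged_id, ids, mult,
               declared_intermediates = unlist(e$declared_intermediates),
               dG0_override = e$dG0_override,
               reversible_pair = isTRUE(e$reversible_pair))
  })
  list(specs = Filter(Negate(is.null), specs), shut = shut)
}
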