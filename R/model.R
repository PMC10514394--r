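#' Thermodynamic configuration
#'
#' Collects the constants and bounds that parameterize the thermodynamic
#' constraint layer: the RT product used in the concentration term of the
#' reaction Gibbs energy, default and metabolite-specific concentration
#' bounds, concentration-ratio constraints for conserved cofactor pairs,
#' and numerical tolerances.
#'
#' Defaults follow common practice for E. coli models: metabolite
#' concentrations 0.5 uM - 20 mM, with tighter physiological windows for
#' dissolved oxygen (0.5-200 uM), CO2 (0.1-100 uM) and ammonium
#' (10 uM - 1 mM), and RT = 2.579 kJ/mol (310 K scale commonly used with
#' transformed reaction energies).
#'
#' @param RT product of gas constant and temperature, kJ/mol.
#' @param default_conc_lb,default_conc_ub default metabolite concentration
#'   bounds, mol/L.
#' @param special_bounds named list of length-2 numeric vectors
#'   `c(lb, ub)` (mol/L) overriding the defaults for specific metabolite ids.
#' @param ratio_constraints data frame with columns `met_a`, `met_b`,
#'   `ratio_lb`, `ratio_ub` constraining the concentration ratio
#'   \eqn{c_a / c_b} (e.g. a narrow NADPH/NADP window).
#' @param bigM big-M constant (kJ/mol) relaxing the driving-force
#'   constraint of inactive reactions in the MILP.
#' @param mdf_tol equality tolerance on driving forces / MDF values, kJ/mol.
#' @param flux_tol tolerance below which a flux counts as zero, mmol/gDW/h.
#' @return an object of class `thermo_config`.
#' @export
thermo_config <- function(RT = 2.579,
                          default_conc_lb = 0.5e-6,
                          default_conc_ub = 20e-3,
                          special_bounds = list(
                            o2_c = c(0.5e-6, 200e-6),
                            co2_c = c(0.1e-6, 100e-6),
                            nh4_c = c(10e-6, 1e-3)),
                          ratio_constraints = NULL,
                          bigM = 1000,
                          mdf_tol = 1e-4,
                          flux_tol = 1e-6) {
  stopifnot(RT > 0, default_conc_lb > 0, default_conc_lb <= default_conc_ub,
            bigM > 0, mdf_tol > 0, flux_tol > 0)
  if (is.null(ratio_constraints)) {
    ratio_constraints <- data.frame(met_a = character(0), met_b = character(0),
                                    ratio_lb = numeric(0), ratio_ub = numeric(0))
  }
  ratio_constraints <- as.data.frame(ratio_constraints)
  if (nrow(ratio_constraints)) {
    stopifnot(all(c("met_a", "met_b", "ratio_lb", "ratio_ub") %in%
                    names(ratio_constraints)))
    if (any(ratio_constraints$ratio_lb <= 0) ||
        any(ratio_constraints$ratio_lb > ratio_constraints$ratio_ub)) {
      stop("ratio constraints must satisfy 0 < ratio_lb <= ratio_ub")
    }
  }
  structure(list(RT = RT,
                 default_conc_lb = default_conc_lb,
                 default_conc_ub = default_conc_ub,
                 special_bounds = special_bounds,
                 ratio_constraints = ratio_constraints,
                 bigM = bigM, mdf_tol = mdf_tol, flux_tol = flux_tol),
            class = "thermo_config")
}

#' Construct a multi-constraint metabolic model
#'
#' A `compart_model` bundles the stoichiometric network with the per-reaction
#' thermodynamic (standard transformed reaction Gibbs energy, kJ/mol) and
#' kinetic (catalytic efficiency kcat/MW, 1/h/kDa) parameters and the
#' per-metabolite concentration bounds used by the constraint layers.
#'
#' @param metabolites data frame with columns `id`, and optionally `name`,
#'   `conc_lb`, `conc_ub` (mol/L) and `is_boundary`. Boundary metabolites are
#'   excluded from mass balance and carry no concentration variable.
#' @param reactions data frame with columns `id` and `stoich` (a list column
#'   of named numeric vectors, negative coefficients for substrates), and
#'   optionally `name`, `reversible`, `flux_lb`, `flux_ub` (mmol/gDW/h),
#'   `dG0`, `dG0_sd` (kJ/mol), `efficiency` (1/h/kDa), `genes` (list column
#'   of character vectors), `gene_rule` and `status` (one of `"keep"`,
#'   `"shut"`, `"added"`).
#' @param exchanges character vector of reaction ids crossing the system
#'   boundary; by default reactions touching a boundary metabolite.
#' @param total_enzyme_bound total proteome budget E_total, g enzyme/gDW.
#' @param provenance free-text notes carried through I/O.
#' @param thermo optional [thermo_config()] attached to the model (used as
#'   the default configuration by the solvers; ratio constraints usually
#'   live here).
#' @return an object of class `compart_model`.
#' @seealso [validate_model()], [load_model()], [split_reversible()]
#' @export
compart_model <- function(metabolites, reactions, exchanges = NULL,
                          total_enzyme_bound = 0.13, provenance = "",
                          thermo = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stopifnot("id" %in% names(metabolites), "id" %in% names(reactions),
            "stoich" %in% names(reactions))
  nm <- nrow(metabolites); nr <- nrow(reactions)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$conc_lb)) metabolites$conc_lb <- NA_real_
  if (is.null(metabolites$conc_ub)) metabolites$conc_ub <- NA_real_
  if (is.null(metabolites$is_boundary)) metabolites$is_boundary <- FALSE
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$reversible)) reactions$reversible <- FALSE
  if (is.null(reactions$flux_lb)) reactions$flux_lb <- 0
  if (is.null(reactions$flux_ub)) reactions$flux_ub <- 1000
  if (is.null(reactions$dG0)) reactions$dG0 <- NA_real_
  if (is.null(reactions$dG0_sd)) reactions$dG0_sd <- NA_real_
  if (is.null(reactions$efficiency)) reactions$efficiency <- NA_real_
  if (is.null(reactions$status)) reactions$status <- "keep"
  if (is.null(reactions$gene_rule)) reactions$gene_rule <- ""
  if (is.null(reactions$genes)) {
    reactions$genes <- lapply(reactions$gene_rule, parse_gene_rule)
  }
  if (!is.list(reactions$stoich)) stop("`stoich` must be a list column")
  if (is.null(exchanges)) {
    bnd <- metabolites$id[metabolites$is_boundary]
    touches <- vapply(reactions$stoich,
                      function(s) any(names(s) %in% bnd), logical(1))
    exchanges <- reactions$id[touches | grepl("^EX_", reactions$id)]
  }
  rownames(metabolites) <- NULL; rownames(reactions) <- NULL
  m <- structure(list(metabolites = metabolites, reactions = reactions,
                      exchanges = exchanges,
                      total_enzyme_bound = total_enzyme_bound,
                      provenance = provenance),
                 class = "compart_model")
  attr(m, "thermo") <- thermo
  m
}

# flat gene set from a BiGG-style boolean rule string; AND/OR semantics are
# not evaluated, only the identifiers are retained
parse_gene_rule <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(rule)) return(character(0))
  toks <- strsplit(gsub("[()]", " ", rule), "\\s+")[[1]]
  toks <- toks[nzchar(toks) & !(tolower(toks) %in% c("and", "or"))]
  unique(toks)
}

#' Thermodynamic configuration attached to a model
#'
#' Returns `config` when given, otherwise the configuration stored on the
#' model, otherwise [thermo_config()] defaults.
#'
#' @param model a [compart_model()].
#' @param config optional explicit [thermo_config()].
#' @return a `thermo_config`.
#' @export
model_thermo <- function(model, config = NULL) {
  if (!is.null(config)) return(config)
  th <- attr(model, "thermo")
  if (is.null(th)) thermo_config() else th
}

#' Effective concentration bounds for every metabolite
#'
#' Metabolite-level bounds stored in the model take precedence; missing
#' values fall back to `config$special_bounds` (matched by metabolite id)
#' and then to the configuration defaults. Boundary metabolites get NA.
#'
#' @inheritParams model_thermo
#' @return data frame with columns `id`, `conc_lb`, `conc_ub`.
#' @export
conc_bounds <- function(model, config = model_thermo(model)) {
  mets <- model$metabolites
  lb <- mets$conc_lb; ub <- mets$conc_ub
  for (i in seq_len(nrow(mets))) {
    sp <- config$special_bounds[[mets$id[i]]]
    if (is.na(lb[i])) lb[i] <- if (!is.null(sp)) sp[1] else config$default_conc_lb
    if (is.na(ub[i])) ub[i] <- if (!is.null(sp)) sp[2] else config$default_conc_ub
  }
  lb[mets$is_boundary] <- NA_real_
  ub[mets$is_boundary] <- NA_real_
  data.frame(id = mets$id, conc_lb = lb, conc_ub = ub,
             stringsAsFactors = FALSE)
}

#' Stoichiometric matrix
#'
#' @inheritParams model_thermo
#' @param boundary include boundary metabolites as rows (default `FALSE`).
#' @return numeric matrix, metabolites x reactions, signed coefficients.
#' @export
stoich_matrix <- function(model, boundary = FALSE) {
  mets <- model$metabolites
  if (!boundary) mets <- mets[!mets$is_boundary, , drop = FALSE]
  S <- matrix(0, nrow(mets), nrow(model$reactions),
              dimnames = list(mets$id, model$reactions$id))
  for (j in seq_len(nrow(model$reactions))) {
    s <- model$reactions$stoich[[j]]
    keep <- names(s) %in% mets$id
    if (any(keep)) S[names(s)[keep], j] <- s[keep]
  }
  S
}

#' Validate a model's structural invariants
#'
#' Checks the type invariants of the data model and returns findings rather
#' than raising: duplicate ids, references to undeclared metabolites, empty
#' or zero-coefficient stoichiometries, inverted flux or concentration
#' bounds, non-positive concentrations on non-boundary metabolites,
#' non-positive efficiencies, shut reactions with open bounds, and ratio
#' constraints naming unknown metabolites.
#'
#' @inheritParams model_thermo
#' @return data frame with columns `entity`, `id`, `message`; zero rows when
#'   the model is valid.
#' @export
validate_model <- function(model, config = model_thermo(model)) {
  f <- list()
  add <- function(entity, id, message) {
    f[[length(f) + 1L]] <<- data.frame(entity = entity, id = id,
                                       message = message,
                                       stringsAsFactors = FALSE)
  }
  mets <- model$metabolites; rxns <- model$reactions
  dup <- mets$id[duplicated(mets$id)]
  for (d in unique(dup)) add("metabolite", d, "duplicate metabolite id")
  dup <- rxns$id[duplicated(rxns$id)]
  for (d in unique(dup)) add("reaction", d, "duplicate reaction id")
  cb <- conc_bounds(model, config)
  for (i in seq_len(nrow(mets))) {
    if (mets$is_boundary[i]) next
    lb <- cb$conc_lb[i]; ub <- cb$conc_ub[i]
    if (!is.na(lb) && lb <= 0)
      add("metabolite", mets$id[i],
          "concentration lower bound must be > 0 (log undefined)")
    if (!is.na(lb) && !is.na(ub) && lb > ub)
      add("metabolite", mets$id[i], "conc_lb > conc_ub")
  }
  for (j in seq_len(nrow(rxns))) {
    s <- rxns$stoich[[j]]
    if (!length(s)) add("reaction", rxns$id[j], "empty stoichiometry")
    if (any(s == 0)) add("reaction", rxns$id[j], "zero stoichiometric coefficient stored")
    unk <- setdiff(names(s), mets$id)
    for (u in unk)
      add("reaction", rxns$id[j], paste0("references undeclared metabolite '", u, "'"))
    if (rxns$flux_lb[j] > rxns$flux_ub[j])
      add("reaction", rxns$id[j], "flux_lb > flux_ub")
    if (!is.na(rxns$efficiency[j]) && rxns$efficiency[j] <= 0)
      add("reaction", rxns$id[j], "efficiency must be > 0 when present")
    if (!rxns$status[j] %in% c("keep", "shut", "added"))
      add("reaction", rxns$id[j], paste0("unknown status '", rxns$status[j], "'"))
    if (rxns$status[j] == "shut" &&
        (rxns$flux_lb[j] != 0 || rxns$flux_ub[j] != 0))
      add("reaction", rxns$id[j], "shut reaction with non-zero flux bounds")
  }
  if (model$total_enzyme_bound <= 0)
    add("model", "total_enzyme_bound", "total_enzyme_bound must be > 0")
  rc <- config$ratio_constraints
  for (k in seq_len(nrow(rc))) {
    for (mm in c(rc$met_a[k], rc$met_b[k])) {
      if (!mm %in% mets$id)
        add("config", mm, "ratio constraint references unknown metabolite")
      else if (mets$is_boundary[match(mm, mets$id)])
        add("config", mm, "ratio constraint references boundary metabolite")
    }
  }
  if (!length(f)) {
    return(data.frame(entity = character(0), id = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, f)
}

#' Split reversible reactions into irreversible direction pairs
#'
#' Every reversible reaction is replaced by an irreversible forward copy and
#' a reverse reaction `<id>_reverse` with negated stoichiometry and negated
#' standard reaction Gibbs energy; catalytic efficiency and gene association
#' are inherited by both directions. All resulting flux bounds are
#' non-negative. Idempotent on its own output.
#'
#' @inheritParams model_thermo
#' @return a direction-split `compart_model`.
#' @export
split_reversible <- function(model) {
  rxns <- model$reactions
  if (!any(rxns$reversible)) return(model)
  out <- list(); ex <- model$exchanges
  for (j in seq_len(nrow(rxns))) {
    r <- rxns[j, , drop = FALSE]
    if (!r$reversible) { out[[length(out) + 1L]] <- r; next }
    rid <- paste0(r$id, "_reverse")
    if (rid %in% rxns$id)
      stop("cannot split '", r$id, "': id '", rid, "' already exists")
    fwd <- r
    fwd$reversible <- FALSE
    fwd$flux_lb <- max(0, r$flux_lb)
    fwd$flux_ub <- max(0, r$flux_ub)
    rev <- r
    rev$id <- rid
    rev$name <- paste0(r$name, " (reverse)")
    rev$reversible <- FALSE
    rev$stoich <- list(-r$stoich[[1]])
    rev$dG0 <- -r$dG0
    rev$flux_lb <- max(0, -r$flux_ub)
    rev$flux_ub <- max(0, -r$flux_lb)
    if (r$status == "shut") { rev$flux_lb <- 0; rev$flux_ub <- 0 }
    out[[length(out) + 1L]] <- fwd
    out[[length(out) + 1L]] <- rev
    if (r$id %in% ex) ex <- c(ex, rid)
  }
  model$reactions <- do.call(rbind, out)
  rownames(model$reactions) <- NULL
  model$exchanges <- ex
  model
}

#' @export
print.compart_model <- function(x, ...) {
  nb <- sum(x$metabolites$is_boundary)
  cat("compart_model: ", nrow(x$metabolites), " metabolites (",
      nb, " boundary), ", nrow(x$reactions), " reactions (",
      length(x$exchanges), " exchanges)\n", sep = "")
  cat("  E_total: ", x$total_enzyme_bound, " g/gDW; with dG0: ",
      sum(!is.na(x$reactions$dG0)), "; with efficiency: ",
      sum(!is.na(x$reactions$efficiency)), "\n", sep = "")
  st <- table(x$reactions$status)
  cat("  status:", paste(names(st), st, sep = "=", collapse = " "), "\n")
  if (nzchar(x$provenance)) cat("  ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @export
print.thermo_config <- function(x, ...) {
  cat("thermo_config: RT=", x$RT, " kJ/mol; conc ", x$default_conc_lb, "-",
      x$default_conc_ub, " M; ", length(x$special_bounds),
      " special bounds; ", nrow(x$ratio_constraints),
      " ratio constraints; bigM=", x$bigM, "\n", sep = "")
  invisible(x)
}
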