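# Model and parameter I/O.
#
# Models travel as BiGG-style JSON (the community dialect: a "metabolites"
# array, a "reactions" array with a metabolite->coefficient map, bounds and
# a gene_reaction_rule).  The thermodynamic and kinetic parameters are not
# part of that dialect, so they live either in per-entity "notes" objects
# (written by save_model, giving lossless round trips) or in a separate
# tab-separated parameter table keyed by reaction id.

num_or_na <- function(x) {
  if (is.null(x) || length(x) == 0L) return(NA_real_)
  as.numeric(x)
}

#' Load a metabolic model with thermodynamic and kinetic parameters
#'
#' Reads a BiGG-style JSON model, optionally overlays a tab-separated
#' parameter table (columns `reaction_id`, `dG0_kJ_mol`, `dG0_sd`,
#' `kcat_per_MW_h_per_kDa`, `genes`), and attaches concentration bounds from
#' `thermo` to metabolites that do not carry explicit bounds. Metabolites
#' are flagged as boundary when their notes say so or, failing that, when
#' their id ends in `_e` or their compartment is `"e"`. Reactions without a
#' standard reaction Gibbs energy are exempt from thermodynamic constraints;
#' reactions without a catalytic efficiency are exempt from the enzyme
#' budget.
#'
#' @param model_path path to the JSON model file.
#' @param params_path optional path to the parameter TSV. Cells equal to
#'   `""`, `"NA"` or `"/"` are treated as absent; any other non-numeric cell
#'   raises an error naming the row and column.
#' @param thermo a [thermo_config()] providing default concentration bounds.
#' @return a validated [compart_model()].
#' @export
load_model <- function(model_path, params_path = NULL,
                       thermo = thermo_config()) {
  if (!file.exists(model_path)) stop("model file not found: ", model_path)
  doc <- jsonlite::fromJSON(model_path, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    notes <- m$notes
    comp <- if (!is.null(m$compartment)) m$compartment else ""
    isb <- if (!is.null(notes$is_boundary)) isTRUE(notes$is_boundary)
           else grepl("_e$", m$id) || identical(comp, "e")
    data.frame(id = m$id,
               name = if (!is.null(m$name)) m$name else m$id,
               conc_lb = num_or_na(notes$conc_lb),
               conc_ub = num_or_na(notes$conc_ub),
               is_boundary = isb, stringsAsFactors = FALSE)
  }))
  if (is.null(mets) || !nrow(mets)) stop("model declares no metabolites")
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    s <- unlist(r$metabolites)
    if (is.null(s) || !length(s))
      stop("reaction '", r$id, "' has empty stoichiometry")
    notes <- r$notes
    lbd <- if (!is.null(r$lower_bound)) r$lower_bound else 0
    ubd <- if (!is.null(r$upper_bound)) r$upper_bound else 1000
    rule <- if (!is.null(r$gene_reaction_rule)) r$gene_reaction_rule else ""
    d <- data.frame(id = r$id,
                    name = if (!is.null(r$name)) r$name else r$id,
                    reversible = if (!is.null(notes$reversible))
                      isTRUE(notes$reversible) else lbd < 0,
                    flux_lb = lbd, flux_ub = ubd,
                    dG0 = num_or_na(notes$dG0),
                    dG0_sd = num_or_na(notes$dG0_uncertainty),
                    efficiency = num_or_na(notes$efficiency),
                    status = if (!is.null(notes$status)) notes$status else "keep",
                    gene_rule = rule, stringsAsFactors = FALSE)
    d$stoich <- list(s)
    d$genes <- list(parse_gene_rule(rule))
    d
  }))
  if (is.null(rxns) || !nrow(rxns)) stop("model declares no reactions")
  unk <- setdiff(unique(unlist(lapply(rxns$stoich, names))), mets$id)
  if (length(unk))
    stop("reaction(s) reference undeclared metabolite(s): ",
         paste(unk, collapse = ", "))
  if (anyDuplicated(mets$id))
    stop("duplicate metabolite id(s): ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  if (anyDuplicated(rxns$id))
    stop("duplicate reaction id(s): ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))

  if (!is.null(params_path)) {
    par <- read_params(params_path)
    for (k in seq_len(nrow(par))) {
      j <- match(par$reaction_id[k], rxns$id)
      if (is.na(j)) next
      if (!is.na(par$dG0[k])) rxns$dG0[j] <- par$dG0[k]
      if (!is.na(par$dG0_sd[k])) rxns$dG0_sd[j] <- par$dG0_sd[k]
      if (!is.na(par$efficiency[k])) rxns$efficiency[j] <- par$efficiency[k]
      if (nzchar(par$genes[k])) {
        rxns$gene_rule[j] <- par$genes[k]
        rxns$genes[[j]] <- parse_gene_rule(par$genes[k])
      }
    }
  }

  notes <- doc$notes
  tot <- if (!is.null(notes$total_enzyme_bound)) notes$total_enzyme_bound else 0.13
  prov <- if (!is.null(notes$provenance)) notes$provenance else ""
  ex <- if (!is.null(notes$exchanges)) unlist(notes$exchanges) else NULL
  m <- compart_model(mets, rxns, exchanges = ex, total_enzyme_bound = tot,
                     provenance = prov, thermo = thermo)
  v <- validate_model(m)
  if (nrow(v)) {
    stop("model failed validation:\n",
         paste0("  [", v$entity, " ", v$id, "] ", v$message, collapse = "\n"))
  }
  m
}

#' Read a reaction parameter table
#'
#' @param params_path TSV with header `reaction_id  dG0_kJ_mol  dG0_sd
#'   kcat_per_MW_h_per_kDa  genes`.
#' @return data frame with columns `reaction_id`, `dG0`, `dG0_sd`,
#'   `efficiency`, `genes`.
#' @export
read_params <- function(params_path) {
  if (!file.exists(params_path)) stop("parameter file not found: ", params_path)
  raw <- utils::read.delim(params_path, colClasses = "character",
                           check.names = FALSE)
  need <- c("reaction_id", "dG0_kJ_mol", "dG0_sd", "kcat_per_MW_h_per_kDa")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("parameter table missing column(s): ", paste(miss, collapse = ", "))
  parse_num <- function(col) {
    v <- trimws(raw[[col]])
    out <- rep(NA_real_, length(v))
    has <- !(v %in% c("", "NA", "/", "na"))
    suppressWarnings(num <- as.numeric(v[has]))
    bad <- which(has)[is.na(num)]
    if (length(bad))
      stop("non-numeric value '", raw[[col]][bad[1]], "' in column '", col,
           "', row ", bad[1], " of ", params_path)
    out[has] <- num
    out
  }
  data.frame(reaction_id = raw$reaction_id,
             dG0 = parse_num("dG0_kJ_mol"),
             dG0_sd = parse_num("dG0_sd"),
             efficiency = parse_num("kcat_per_MW_h_per_kDa"),
             genes = if ("genes" %in% names(raw)) raw$genes else "",
             stringsAsFactors = FALSE)
}

#' Save a model as BiGG-style JSON
#'
#' Thermodynamic and kinetic parameters, concentration bounds, boundary
#' flags, statuses and the enzyme budget are written into `notes` objects so
#' that [load_model()] reproduces the model field for field.
#'
#' @inheritParams model_thermo
#' @param model_path output path.
#' @return `model_path`, invisibly.
#' @export
save_model <- function(model, model_path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    notes <- list(is_boundary = m$is_boundary)
    if (!is.na(m$conc_lb)) notes$conc_lb <- m$conc_lb
    if (!is.na(m$conc_ub)) notes$conc_ub <- m$conc_ub
    list(id = m$id, name = m$name, notes = notes)
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(j) {
    r <- model$reactions[j, ]
    notes <- list(status = r$status, reversible = r$reversible)
    if (!is.na(r$dG0)) notes$dG0 <- r$dG0
    if (!is.na(r$dG0_sd)) notes$dG0_uncertainty <- r$dG0_sd
    if (!is.na(r$efficiency)) notes$efficiency <- r$efficiency
    list(id = r$id, name = r$name,
         metabolites = as.list(r$stoich[[1]]),
         lower_bound = r$flux_lb, upper_bound = r$flux_ub,
         gene_reaction_rule = r$gene_rule, notes = notes)
  })
  doc <- list(id = "compart_model", version = "1",
              metabolites = mets, reactions = rxns,
              notes = list(total_enzyme_bound = model$total_enzyme_bound,
                           provenance = model$provenance,
                           exchanges = as.list(model$exchanges)))
  con <- file(model_path, open = "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"), con)
  invisible(model_path)
}

#' Save / load a thermodynamic configuration as YAML
#'
#' @param config a [thermo_config()].
#' @param path file path.
#' @return `path` (save) or a `thermo_config` (load).
#' @export
save_thermo_config <- function(config, path) {
  rc <- config$ratio_constraints
  doc <- list(RT = config$RT,
              default_conc_lb = config$default_conc_lb,
              default_conc_ub = config$default_conc_ub,
              special_bounds = lapply(config$special_bounds, as.numeric),
              ratio_constraints = lapply(seq_len(nrow(rc)), function(k)
                list(met_a = rc$met_a[k], met_b = rc$met_b[k],
                     ratio_lb = rc$ratio_lb[k], ratio_ub = rc$ratio_ub[k])),
              bigM = config$bigM, mdf_tol = config$mdf_tol,
              flux_tol = config$flux_tol)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname save_thermo_config
#' @export
load_thermo_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- yaml::read_yaml(path)
  rc <- NULL
  if (length(doc$ratio_constraints)) {
    rc <- do.call(rbind, lapply(doc$ratio_constraints, function(k)
      data.frame(met_a = k$met_a, met_b = k$met_b,
                 ratio_lb = k$ratio_lb, ratio_ub = k$ratio_ub,
                 stringsAsFactors = FALSE)))
  }
  thermo_config(RT = doc$RT,
                default_conc_lb = doc$default_conc_lb,
                default_conc_ub = doc$default_conc_ub,
                special_bounds = lapply(doc$special_bounds, as.numeric),
                ratio_constraints = rc,
                bigM = doc$bigM, mdf_tol = doc$mdf_tol,
                flux_tol = doc$flux_tol)
}
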