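# End-to-end orchestration: load -> scenario -> staircase -> diagnostics ->
# merge -> re-analysis, with reports written per stage.

#' Pipeline configuration
#'
#' @param model a [compart_model()] or a path to a model JSON file.
#' @param params optional parameter TSV path (when `model` is a path).
#' @param thermo a [thermo_config()], a YAML path, or `NULL` for the model's
#'   attached configuration.
#' @param product product reaction id (must exist in the loaded model).
#' @param scenario `"aerobic"` or `"anaerobic"`.
#' @param min_flux required product flux for the bottleneck analysis;
#'   default half of the stoichiometric maximum.
#' @param n_points staircase grid points.
#' @param merge_specs optional: a [merge_spec()], a list of them, or a YAML
#'   path as read by [read_merge_specs()].
#' @param out_dir output directory for [write_report()]; `NULL` to skip
#'   writing.
#' @param enzyme_on include the enzyme budget layer.
#' @param log_level `"info"` (stage messages to stderr) or `"quiet"`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(model, params = NULL, thermo = NULL, product,
                            scenario = "aerobic", min_flux = NULL,
                            n_points = 20, merge_specs = NULL,
                            out_dir = NULL, enzyme_on = TRUE,
                            log_level = "info") {
  structure(list(model = model, params = params, thermo = thermo,
                 product = product, scenario = scenario,
                 min_flux = min_flux, n_points = n_points,
                 merge_specs = merge_specs, out_dir = out_dir,
                 enzyme_on = enzyme_on, log_level = log_level),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Loads and validates the model, applies the scenario, computes the MDF
#' staircase and the bottleneck / limiting-metabolite / enzyme-cost
#' diagnostics, then — when merge specifications are given — applies them
#' and recomputes the staircase, summarizing the before/after comparison
#' (MDF at low demand, last thermodynamically feasible flux, stage counts).
#'
#' @param config a [pipeline_config()].
#' @return an object of class `pipeline_result` with elements
#'   `curve_before`, `bottlenecks`, `enzyme_costs`, and (when merging)
#'   `model_after`, `curve_after`, `merges`, plus a `summary` data frame.
#'   When `config$out_dir` is set, reports are written there via
#'   [write_report()].
#' @export
run_pipeline <- function(config) {
  say <- function(...) {
    if (!identical(config$log_level, "quiet"))
      message("[mdfpath] ", ...)
  }
  model <- config$model
  if (is.character(model)) {
    say("loading model from ", model)
    th0 <- if (is.character(config$thermo)) load_thermo_config(config$thermo)
           else if (!is.null(config$thermo)) config$thermo else thermo_config()
    model <- load_model(model, config$params, thermo = th0)
    thermo <- th0
  } else {
    thermo <- if (is.character(config$thermo)) load_thermo_config(config$thermo)
              else model_thermo(model, config$thermo)
  }
  if (!config$product %in% model$reactions$id)
    stop("product reaction '", config$product, "' not found in model")
  model <- split_reversible(model)
  v <- validate_model(model, thermo)
  if (nrow(v)) stop("model failed validation (", nrow(v), " finding(s))")
  if (config$scenario == "anaerobic") {
    say("closing oxygen exchange (anaerobic scenario)")
    model <- apply_scenario(model, "anaerobic")
  }
  problem <- assemble_constraints(model, thermo, enzyme_on = config$enzyme_on,
                                  thermo_on = TRUE)
  say("sweeping MDF staircase (", config$n_points, " grid points)")
  curve_before <- sweep_mdf_curve(problem, config$product,
                                  n_points = config$n_points)
  min_flux <- if (is.null(config$min_flux)) curve_before$max_flux / 2
              else config$min_flux
  say("bottleneck analysis at min_flux = ", signif(min_flux, 6))
  bn <- identify_bottlenecks(model, thermo, config$product, min_flux,
                             enzyme_on = config$enzyme_on)
  ec <- tryCatch(
    enzyme_cost_variability(model, thermo, config$product, min_flux, bn$mdf),
    error = function(e) NULL)

  res <- list(config = config, model_before = model,
              curve_before = curve_before, bottlenecks = bn,
              enzyme_costs = ec)

  if (!is.null(config$merge_specs)) {
    specs <- config$merge_specs
    shut_ids <- character(0)
    if (is.character(specs)) {
      batch <- read_merge_specs(specs)
      specs <- batch$specs; shut_ids <- batch$shut
    } else if (inherits(specs, "merge_spec")) specs <- list(specs)
    say("applying ", length(specs), " merge(s)")
    model_after <- model
    merges <- list()
    for (sp in specs) {
      mr <- merge_reactions(model_after, sp)
      model_after <- mr$new_model
      merges[[sp$merged_id]] <- mr
    }
    if (length(shut_ids))
      model_after <- shut_reactions(model_after, shut_ids)
    problem_after <- assemble_constraints(model_after, thermo,
                                          enzyme_on = config$enzyme_on,
                                          thermo_on = TRUE)
    say("re-sweeping MDF staircase after merging")
    curve_after <- sweep_mdf_curve(problem_after, config$product,
                                   n_points = config$n_points)
    res$model_after <- model_after
    res$curve_after <- curve_after
    res$merges <- merges
  }

  res$summary <- pipeline_summary(res)
  class(res) <- "pipeline_result"
  if (!is.null(config$out_dir)) write_report(res, config$out_dir)
  res
}

# feasible-flux limit: largest grid flux whose stage MDF is >= 0
feasible_flux_limit <- function(curve) {
  ok <- curve$points$mdf >= 0
  if (!any(ok)) 0 else max(curve$points$min_flux[ok])
}

pipeline_summary <- function(res) {
  rows <- list(
    data.frame(quantity = "max_flux", before = res$curve_before$max_flux,
               after = if (!is.null(res$curve_after))
                 res$curve_after$max_flux else NA_real_),
    data.frame(quantity = "mdf_low_demand",
               before = res$curve_before$points$mdf[1],
               after = if (!is.null(res$curve_after))
                 res$curve_after$points$mdf[1] else NA_real_),
    data.frame(quantity = "feasible_flux_limit",
               before = feasible_flux_limit(res$curve_before),
               after = if (!is.null(res$curve_after))
                 feasible_flux_limit(res$curve_after) else NA_real_),
    data.frame(quantity = "n_stages",
               before = nrow(res$curve_before$stages),
               after = if (!is.null(res$curve_after))
                 nrow(res$curve_after$stages) else NA_real_))
  do.call(rbind, rows)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result for product ", x$config$product, "\n", sep = "")
  print(x$summary, row.names = FALSE)
  cat("bottlenecks (", x$bottlenecks$classification, "): ",
      paste(x$bottlenecks$bottlenecks, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write pipeline reports
#'
#' Writes TSV/JSON reports named by stage into `out_dir`: the MDF curve(s)
#' with stage indices, the bottleneck report, limiting metabolites, enzyme
#' costs, a run manifest (configuration hash, solver, tolerances) and a
#' staircase plot (PDF). Empty diagnostics give headers-only files.
#'
#' @param res a `pipeline_result`.
#' @param out_dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_report <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)
  wtsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, p)
  }
  wtsv(res$curve_before$points, "curve_before.tsv")
  if (!is.null(res$curve_after)) wtsv(res$curve_after$points, "curve_after.tsv")
  bn <- res$bottlenecks
  wtsv(data.frame(product = bn$product, min_flux = bn$min_flux, mdf = bn$mdf,
                  reaction = if (length(bn$bottlenecks)) bn$bottlenecks
                             else character(0),
                  max_df = if (length(bn$bottlenecks))
                    bn$per_reaction_max_df[bn$bottlenecks] else numeric(0),
                  class = if (length(bn$bottlenecks)) bn$classification
                          else character(0)),
       "bottlenecks.tsv")
  wtsv(bn$limiting_metabolites, "limiting_metabolites.tsv")
  wtsv(if (is.null(res$enzyme_costs))
         data.frame(reaction = character(0), cost_min = numeric(0),
                    cost_max = numeric(0), is_key = logical(0))
       else res$enzyme_costs,
       "enzyme_costs.tsv")
  manifest <- list(
    package = "mdfpath",
    version = as.character(utils::packageVersion("mdfpath")),
    product = res$config$product, scenario = res$config$scenario,
    n_points = res$config$n_points,
    solver = "internal two-phase simplex + branch-and-bound",
    tolerances = list(mdf_tol = model_thermo(res$model_before)$mdf_tol,
                      flux_tol = model_thermo(res$model_before)$flux_tol),
    config_hash = config_hash(res$config),
    summary = stats::setNames(as.list(res$summary$before),
                              res$summary$quantity),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, mp)
  pp <- file.path(out_dir, "mdf_curve.pdf")
  grDevices::pdf(pp, width = 6, height = 4)
  print(plot_mdf_curve(res$curve_before, res$curve_after))
  grDevices::dev.off()
  files <- c(files, pp)
  invisible(files)
}

# stable md5 of the configuration (timestamps excluded)
config_hash <- function(config) {
  x <- config[setdiff(names(config), c("out_dir", "log_level"))]
  x <- x[!vapply(x, is.function, logical(1))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(x, digits.d = 15)), tmp)
  unname(tools::md5sum(tmp))
}
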