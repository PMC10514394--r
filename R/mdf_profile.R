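# The MDF-versus-required-yield staircase: as the demanded product flux
# grows, pathways with high driving force saturate and the optimizer must
# recruit thermodynamically poorer routes, so the achievable max-min
# driving force drops in plateaus separated by turning points.

#' Sweep the MDF staircase over required product flux
#'
#' Evaluates [solve_max_mdf()] on a uniform grid of required product fluxes
#' from a tiny positive demand (`flux_res`, so that the product pathway must
#' actually run) to the plain-FBA maximum, optionally bisecting each
#' detected MDF drop until the flux breakpoint is localized, then groups
#' the grid into stages of constant MDF.
#'
#' @param problem an [assemble_constraints()] problem with the
#'   thermodynamic layer enabled (build it once; the sweep reuses it).
#' @param product product (exchange) reaction id.
#' @param n_points number of grid points (>= 2).
#' @param refine bisect MDF drops down to `flux_res` (default `TRUE`).
#' @param flux_res flux resolution of breakpoint refinement, mmol/gDW/h.
#' @param stage_tol MDF tolerance (kJ/mol) within which grid points belong
#'   to one stage.
#' @return an object of class `mdf_curve`: data frame `points` (columns
#'   `min_flux`, `mdf`, `stage`), data frame `stages` (columns `index`,
#'   `flux_lo`, `flux_hi`, `mdf`), `max_flux`, and `product`.
#' @export
sweep_mdf_curve <- function(problem, product, n_points = 50, refine = TRUE,
                            flux_res = 1e-3, stage_tol = 0.01) {
  stopifnot(n_points >= 2)
  if (!problem$thermo_on) stop("sweep_mdf_curve requires the thermodynamic layer")
  fba <- solve_fba(problem, product, "max")
  if (fba$status != "optimal" || fba$objective_value <= problem$config$flux_tol)
    stop("product reaction '", product, "' can carry no flux")
  max_flux <- fba$objective_value
  grid <- seq(min(flux_res, max_flux / 2), max_flux, length.out = n_points)
  mdf <- vapply(grid, function(fl) {
    r <- solve_max_mdf(problem, product, fl)
    if (r$status == "optimal") r$mdf else NA_real_
  }, numeric(1))
  keep <- !is.na(mdf)
  grid <- grid[keep]; mdf <- mdf[keep]
  if (!length(grid)) stop("MDF problem infeasible on the whole grid")
  if (refine) {
    k <- 1L
    while (k < length(grid)) {
      if (abs(mdf[k + 1L] - mdf[k]) > stage_tol &&
          (grid[k + 1L] - grid[k]) > flux_res) {
        mid <- (grid[k] + grid[k + 1L]) / 2
        r <- solve_max_mdf(problem, product, mid)
        v <- if (r$status == "optimal") r$mdf else NA_real_
        if (!is.na(v)) {
          grid <- append(grid, mid, after = k)
          mdf <- append(mdf, v, after = k)
          next  # re-examine the left half of the split interval
        }
      }
      k <- k + 1L
    }
  }
  curve <- structure(list(points = data.frame(min_flux = grid, mdf = mdf,
                                              stage = NA_integer_),
                          stages = NULL, max_flux = max_flux,
                          product = product),
                     class = "mdf_curve")
  curve$stages <- detect_stages(curve, stage_tol)
  curve$points$stage <- findInterval(curve$points$min_flux,
                                     c(curve$stages$flux_lo[1],
                                       curve$stages$flux_hi),
                                     rightmost.closed = TRUE)
  curve$points$stage[curve$points$stage == 0L] <- 1L
  curve
}

#' Group an MDF curve into stages of constant driving force
#'
#' Greedy left-to-right grouping: a grid point opens a new stage when its
#' MDF differs from the running stage's first point by more than
#' `stage_tol`. The turning point (last flux) of each stage closes it, so
#' stage flux ranges are half-open on the left: `(lo, hi]`.
#'
#' @param curve an `mdf_curve` (or any list with a `points` data frame).
#' @param stage_tol kJ/mol.
#' @return data frame with columns `index`, `flux_lo`, `flux_hi`, `mdf`
#'   (the stage's MDF level).
#' @export
detect_stages <- function(curve, stage_tol = 0.01) {
  pts <- curve$points
  stopifnot(nrow(pts) >= 1)
  idx <- 1L; first_mdf <- pts$mdf[1]; lo <- pts$min_flux[1]
  out <- list()
  for (k in seq_len(nrow(pts))[-1]) {
    if (abs(pts$mdf[k] - first_mdf) > stage_tol) {
      out[[idx]] <- data.frame(index = idx, flux_lo = lo,
                               flux_hi = pts$min_flux[k - 1L],
                               mdf = first_mdf)
      idx <- idx + 1L
      first_mdf <- pts$mdf[k]
      lo <- pts$min_flux[k - 1L]
    }
  }
  out[[idx]] <- data.frame(index = idx, flux_lo = lo,
                           flux_hi = pts$min_flux[nrow(pts)], mdf = first_mdf)
  do.call(rbind, out)
}

#' Yield percentage relative to the stoichiometric maximum
#'
#' @param flux achieved product flux, mmol/gDW/h.
#' @param max_flux stoichiometric maximum product flux, mmol/gDW/h.
#' @return percentage rounded to one decimal for reporting; the raw value
#'   is retained in attribute `"raw"`.
#' @examples
#' yield_percentage(8.99, 21.03)   # 42.7
#' @export
yield_percentage <- function(flux, max_flux) {
  if (max_flux <= 0) stop("max_flux must be > 0")
  raw <- 100 * flux / max_flux
  structure(round(raw, 1), raw = raw)
}

#' @export
print.mdf_curve <- function(x, ...) {
  cat("mdf_curve for ", x$product, ": ", nrow(x$points), " points, ",
      nrow(x$stages), " stage(s), max flux ", signif(x$max_flux, 6),
      " mmol/gDW/h\n", sep = "")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Staircase plot of one or two MDF curves
#'
#' @param curve an `mdf_curve`.
#' @param curve_after optional second curve (e.g. after reaction merging)
#'   drawn for comparison.
#' @return a ggplot object.
#' @export
plot_mdf_curve <- function(curve, curve_after = NULL) {
  d <- curve$points; d$which <- "before"
  if (!is.null(curve_after)) {
    d2 <- curve_after$points; d2$which <- "after"
    d <- rbind(d, d2)
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$min_flux, y = .data$mdf,
                                       colour = .data$which)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "required product flux (mmol/gDW/h)",
                  y = "MDF (kJ/mol)", colour = NULL) +
    ggplot2::theme_minimal()
  if (is.null(curve_after)) p <- p + ggplot2::guides(colour = "none")
  p
}
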