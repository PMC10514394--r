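# Seeded generators of small networks carrying the thermodynamic and
# enzymatic structure the analysis assumes: linear chains with designed
# bottlenecks, a coupled-enzyme (shared gene + cofactor pair) motif, a
# two-route branched network, and random sparse networks that are
# thermodynamically feasible by construction.

#' Generator configuration
#'
#' @param seed integer RNG seed; identical configurations produce
#'   bit-identical models.
#' @param n_reactions number of internal reactions for [gen_random_model()].
#' @param dG0_range range (kJ/mol) from which random standard reaction
#'   energies are drawn (subject to the feasibility construction).
#' @param efficiency_range range of catalytic efficiencies kcat/MW
#'   (1/h/kDa), bracketing typical curated values.
#' @param conc_bounds metabolite concentration bounds (mol/L) written onto
#'   generated internal metabolites.
#' @param uptake_ub substrate uptake upper bound, mmol/gDW/h.
#' @param E_total total proteome budget, g/gDW.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_reactions = 6L,
                             dG0_range = c(-25, 10),
                             efficiency_range = c(100, 4000),
                             conc_bounds = c(1e-6, 1e-2),
                             uptake_ub = 10, E_total = 0.13) {
  stopifnot(n_reactions >= 1, conc_bounds[1] > 0,
            conc_bounds[1] <= conc_bounds[2], uptake_ub > 0, E_total > 0)
  structure(list(seed = as.integer(seed), n_reactions = as.integer(n_reactions),
                 dG0_range = dG0_range, efficiency_range = efficiency_range,
                 conc_bounds = conc_bounds, uptake_ub = uptake_ub,
                 E_total = E_total),
            class = "generator_config")
}

# run expr with a locally seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

met_df <- function(id, conc_lb = NA_real_, conc_ub = NA_real_,
                   is_boundary = FALSE) {
  data.frame(id = id, name = id, conc_lb = conc_lb, conc_ub = conc_ub,
             is_boundary = is_boundary, stringsAsFactors = FALSE)
}

rxn_df <- function(id, stoich, dG0 = NA_real_, dG0_sd = NA_real_,
                   efficiency = NA_real_, flux_lb = 0, flux_ub = 1000,
                   gene_rule = "", status = "keep") {
  d <- data.frame(id = id, name = id, reversible = FALSE,
                  flux_lb = flux_lb, flux_ub = flux_ub, dG0 = dG0,
                  dG0_sd = dG0_sd, efficiency = efficiency, status = status,
                  gene_rule = gene_rule, stringsAsFactors = FALSE)
  d$stoich <- list(stoich)
  d$genes <- list(parse_gene_rule(gene_rule))
  d
}

#' Linear chain with designed standard reaction energies
#'
#' Builds `source exchange -> A -> B -> ... -> sink` with one internal
#' reaction per entry of `dG0_list` (ids `R1`, `R2`, ...), internal
#' metabolites named `A`, `B`, `C`, ... with the configuration's
#' concentration bounds, boundary metabolites `A_ext` and `<last>_ext`, an
#' uptake exchange `EX_A` bounded by `uptake_ub` and a product exchange
#' `EX_<last>`. Exchanges carry no dG0 and are thermo-exempt.
#'
#' The two canonical fixtures are `dG0_list = c(-5, 10)` (a distributed
#' bottleneck pair: at the optimum both reactions pin the MDF) and
#' `c(-30, 30)` (a localized bottleneck: only the second reaction pins it).
#'
#' @param config a [generator_config()].
#' @param dG0_list numeric vector of standard reaction energies, kJ/mol.
#' @param efficiency catalytic efficiency assigned to every internal
#'   reaction (1/h/kDa).
#' @return a [compart_model()] with an attached default [thermo_config()].
#' @export
gen_linear_chain <- function(config = generator_config(),
                             dG0_list = c(-5, 10), efficiency = 1000) {
  n <- length(dG0_list)
  stopifnot(n >= 1, n <= 25)
  ids <- LETTERS[seq_len(n + 1)]
  last <- ids[n + 1]
  mets <- rbind(
    met_df(paste0(ids[1], "_ext"), is_boundary = TRUE),
    do.call(rbind, lapply(ids, met_df,
                          conc_lb = config$conc_bounds[1],
                          conc_ub = config$conc_bounds[2])),
    met_df(paste0(last, "_ext"), is_boundary = TRUE))
  rxns <- rxn_df(paste0("EX_", ids[1]),
                 stats::setNames(c(-1, 1), c(paste0(ids[1], "_ext"), ids[1])),
                 flux_ub = config$uptake_ub)
  for (k in seq_len(n)) {
    rxns <- rbind(rxns, rxn_df(paste0("R", k),
                               stats::setNames(c(-1, 1), ids[k + 1:0][2:1]),
                               dG0 = dG0_list[k], efficiency = efficiency))
  }
  rxns <- rbind(rxns, rxn_df(paste0("EX_", last),
                             stats::setNames(c(-1, 1),
                                             c(last, paste0(last, "_ext")))))
  compart_model(mets, rxns, total_enzyme_bound = config$E_total,
                provenance = "gen_linear_chain", thermo = thermo_config())
}

#' Coupled-enzyme motif with a cofactor pair and a shared gene
#'
#' Emulates the serine-synthesis situation in which a thermodynamically
#' unfavorable dehydrogenase step is coupled, within one multifunctional
#' enzyme, to a favorable reduction-force-consuming step. The motif is
#'
#' \preformatted{EX_S -> S -(U)-> M2 -(D)-> P -> EX_P,  F: Xred -> Xox}
#'
#' where `U` (`dG0_u`, default +15 kJ/mol) reduces the cofactor
#' (`Xox -> Xred`) and `F` (`dG0_f`, default -20) reoxidizes it; `U` and `F`
#' share a gene, and the attached configuration constrains the
#' `Xred`/`Xox` concentration ratio to a narrow window. The downstream step
#' `D` (dG0 -4) runs between two metabolites with narrow concentration
#' windows (1e-5 to 2e-5 M), so it caps the network MDF at
#' \eqn{4 + RT\ln 2} kJ/mol independently of the cofactor ratio: with the
#' narrow ratio window `U` is the bottleneck, and merging `U` with `F`
#' (which cancels the cofactor pair) lifts the MDF back to the `D` cap.
#'
#' @inheritParams gen_linear_chain
#' @param dG0_u,dG0_f standard reaction energies of the coupled pair.
#' @param ratio_bounds `c(lb, ub)` window on the `Xred`/`Xox` ratio.
#' @return a [compart_model()] whose attached [thermo_config()] carries the
#'   cofactor ratio constraint.
#' @export
gen_coupled_motif <- function(config = generator_config(), dG0_u = 15,
                              dG0_f = -20, ratio_bounds = c(0.5, 2)) {
  lb <- config$conc_bounds[1]; ub <- config$conc_bounds[2]
  mets <- rbind(
    met_df("S_ext", is_boundary = TRUE),
    met_df("S", lb, ub),
    met_df("M2", 1e-5, 2e-5),
    met_df("P", 1e-5, 2e-5),
    met_df("P_ext", is_boundary = TRUE),
    met_df("Xox", lb, ub),
    met_df("Xred", lb, ub))
  rxns <- rbind(
    rxn_df("EX_S", c(S_ext = -1, S = 1), flux_ub = config$uptake_ub),
    rxn_df("U", c(S = -1, Xox = -1, M2 = 1, Xred = 1), dG0 = dG0_u,
           dG0_sd = 1, efficiency = 150, gene_rule = "g_multi"),
    rxn_df("F", c(Xred = -1, Xox = 1), dG0 = dG0_f, dG0_sd = 1,
           efficiency = 900, gene_rule = "g_multi"),
    rxn_df("D", c(M2 = -1, P = 1), dG0 = -4, dG0_sd = 0.5, efficiency = 2000),
    rxn_df("EX_P", c(P = -1, P_ext = 1)))
  th <- thermo_config(ratio_constraints = data.frame(
    met_a = "Xred", met_b = "Xox",
    ratio_lb = ratio_bounds[1], ratio_ub = ratio_bounds[2],
    stringsAsFactors = FALSE))
  compart_model(mets, rxns, total_enzyme_bound = config$E_total,
                provenance = "gen_coupled_motif", thermo = th)
}

#' Merge specification for the coupled motif
#'
#' Convenience constructor for the `U + F` merge of [gen_coupled_motif()],
#' cancelling the cofactor pair.
#' @return a [merge_spec()].
#' @export
motif_merge_spec <- function() {
  merge_spec("UF", parts = c("U", "F"),
             declared_intermediates = c("Xox", "Xred"))
}

#' Two-route branched network
#'
#' A source metabolite `A` feeds a product `P` through two routes sharing
#' `A` and `P`: route A (`RA`, one step) with standard energy `dG0_a` and
#' flux capacity `cap_a`, and route B (`RB1`, `RB2`, ...) with energies
#' `dG0_b` and capacity `cap_b`. With the defaults route A is short, highly
#' favorable and capacity-limited while route B is longer and
#' thermodynamically poor, so the MDF staircase has two stages with a drop
#' at route A's capacity.
#'
#' @inheritParams gen_linear_chain
#' @param dG0_a standard reaction energy of the one-step route, kJ/mol.
#' @param dG0_b vector of standard energies for the steps of route B.
#' @param cap_a,cap_b route flux capacities, mmol/gDW/h.
#' @return a [compart_model()].
#' @export
gen_branched_network <- function(config = generator_config(), dG0_a = -20,
                                 dG0_b = c(5, 5), cap_a = 3, cap_b = 20) {
  lb <- config$conc_bounds[1]; ub <- config$conc_bounds[2]
  nb <- length(dG0_b)
  bmets <- if (nb > 1) paste0("N", seq_len(nb - 1)) else character(0)
  mets <- rbind(
    met_df("A_ext", is_boundary = TRUE),
    met_df("A", lb, ub),
    if (length(bmets)) do.call(rbind, lapply(bmets, met_df, lb, ub)),
    met_df("P", lb, ub),
    met_df("P_ext", is_boundary = TRUE))
  chain_ids <- c("A", bmets, "P")
  rxns <- rbind(
    rxn_df("EX_A", c(A_ext = -1, A = 1), flux_ub = config$uptake_ub),
    rxn_df("RA", c(A = -1, P = 1), dG0 = dG0_a, efficiency = 1000,
           flux_ub = cap_a))
  for (k in seq_len(nb)) {
    rxns <- rbind(rxns, rxn_df(
      paste0("RB", k),
      stats::setNames(c(-1, 1), c(chain_ids[k], chain_ids[k + 1])),
      dG0 = dG0_b[k], efficiency = 1000, flux_ub = cap_b))
  }
  rxns <- rbind(rxns, rxn_df("EX_P", c(P = -1, P_ext = 1)))
  compart_model(mets, rxns, total_enzyme_bound = config$E_total,
                provenance = "gen_branched_network", thermo = thermo_config())
}

#' Random sparse network, thermodynamically feasible by construction
#'
#' Generates a backbone chain `source -> M1 -> ... -> Mk -> sink` plus
#' random extra reactions between internal metabolites. Feasibility is
#' built in rather than tested for: a concentration vector is sampled
#' inside the bounds first, and each reaction's standard energy is then
#' drawn so that its driving force at that vector is at least 0.1 kJ/mol --
#' hence the network MDF is at least 0.1 before any merging. Extra
#' reactions never touch the first backbone intermediate, so the first two
#' backbone reactions always share an exclusive intermediate and remain a
#' valid merge candidate.
#'
#' @inheritParams gen_linear_chain
#' @return a [compart_model()].
#' @export
gen_random_model <- function(config = generator_config()) {
  n <- config$n_reactions
  stopifnot(n >= 2)
  with_seed(config$seed, {
    k <- max(2L, min(n - 1L, 5L))     # backbone length (internal reactions)
    n_extra <- n - k
    ids <- paste0("M", seq_len(k + 1))
    lb <- config$conc_bounds[1]; ub <- config$conc_bounds[2]
    lnc_star <- stats::setNames(stats::runif(k + 1, log(lb), log(ub)), ids)
    mets <- rbind(met_df("SRC_ext", is_boundary = TRUE),
                  do.call(rbind, lapply(ids, met_df, lb, ub)),
                  met_df("SNK_ext", is_boundary = TRUE))
    RT <- thermo_config()$RT
    draw_dG0 <- function(s) {
      # f = -(dG0 + RT * sum s lnc*) >= 0.1  <=>  dG0 <= -0.1 - RT sum s lnc*
      cap <- -0.1 - RT * sum(s * lnc_star[names(s)])
      cap - stats::runif(1, 0, diff(range(config$dG0_range)))
    }
    eff <- function() stats::runif(1, config$efficiency_range[1],
                                   config$efficiency_range[2])
    rxns <- rxn_df("EX_SRC", c(SRC_ext = -1, M1 = 1),
                   flux_ub = config$uptake_ub)
    for (i in seq_len(k)) {
      s <- stats::setNames(c(-1, 1), c(ids[i], ids[i + 1]))
      rxns <- rbind(rxns, rxn_df(paste0("R", i), s, dG0 = draw_dG0(s),
                                 efficiency = eff()))
    }
    pool <- ids[-2]                   # keep M2 exclusive to R1/R2
    extra_added <- 0L; tries <- 0L
    while (extra_added < n_extra && tries < 50L) {
      tries <- tries + 1L
      pair <- sample(pool, 2)
      rid <- paste0("X", extra_added + 1L)
      s <- stats::setNames(c(-1, 1), pair)
      dup <- any(vapply(rxns$stoich, function(q)
        length(q) == length(s) && setequal(names(q), names(s)) &&
          all(q[names(s)] == s), logical(1)))
      if (dup) next
      extra_added <- extra_added + 1L
      rxns <- rbind(rxns, rxn_df(rid, s, dG0 = draw_dG0(s), efficiency = eff()))
    }
    rxns <- rbind(rxns, rxn_df("EX_SNK",
                               stats::setNames(c(-1, 1),
                                               c(ids[k + 1], "SNK_ext"))))
    compart_model(mets, rxns, total_enzyme_bound = config$E_total,
                  provenance = paste0("gen_random_model seed=", config$seed),
                  thermo = thermo_config())
  })
}
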