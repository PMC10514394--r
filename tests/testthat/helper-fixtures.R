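# Fixtures assembled in code.

rxn_row <- mdfpath:::rxn_df
met_row <- function(id, lb = 1e-6, ub = 1e-2, boundary = FALSE) {
  data.frame(id = id, name = id,
             conc_lb = if (boundary) NA_real_ else lb,
             conc_ub = if (boundary) NA_real_ else ub,
             is_boundary = boundary, stringsAsFactors = FALSE)
}

# two-route diamond: source -> A, route A of `lenA` steps and route B of
# `lenB` steps to P, P -> sink; pure flux network (no thermodynamics)
fixture_diamond <- function(lenA = 2, lenB = 2, capA = 1000, capB = 1000,
                            uptake = 10) {
  a_mets <- if (lenA > 1) paste0("AM", seq_len(lenA - 1)) else character(0)
  b_mets <- if (lenB > 1) paste0("BM", seq_len(lenB - 1)) else character(0)
  mets <- do.call(rbind, c(list(met_row("A_ext", boundary = TRUE),
                                met_row("A")),
                           lapply(c(a_mets, b_mets), met_row),
                           list(met_row("P"), met_row("P_ext", boundary = TRUE))))
  chainA <- c("A", a_mets, "P"); chainB <- c("A", b_mets, "P")
  rxns <- rxn_row("EX_A", c(A_ext = -1, A = 1), flux_ub = uptake)
  for (k in seq_len(lenA))
    rxns <- rbind(rxns, rxn_row(paste0("RA", k),
                                stats::setNames(c(-1, 1),
                                                c(chainA[k], chainA[k + 1])),
                                flux_ub = capA))
  for (k in seq_len(lenB))
    rxns <- rbind(rxns, rxn_row(paste0("RB", k),
                                stats::setNames(c(-1, 1),
                                                c(chainB[k], chainB[k + 1])),
                                flux_ub = capB))
  rxns <- rbind(rxns, rxn_row("EX_P", c(P = -1, P_ext = 1)))
  compart_model(mets, rxns, thermo = thermo_config())
}

# three partial reactions whose merge cancels every intermediate (B, I1,
# I2), leaving A -> C; standard energies chosen so that each partial's
# driving force at the 1 M reference state is exactly `f_each`
fixture_three_partials <- function(f_each = -1.897 / 3) {
  mets <- do.call(rbind, c(lapply(c("A", "B", "C", "I1", "I2"), met_row),
                           list(met_row("A_ext", boundary = TRUE),
                                met_row("C_ext", boundary = TRUE))))
  rxns <- rbind(
    rxn_row("EX_A", c(A_ext = -1, A = 1), flux_ub = 10),
    rxn_row("P1", c(A = -1, B = 1, I1 = 1), dG0 = -f_each, dG0_sd = 0.5),
    rxn_row("P2", c(I1 = -1, I2 = 1), dG0 = -f_each, dG0_sd = 0.5),
    rxn_row("P3", c(B = -1, I2 = -1, C = 1), dG0 = -f_each, dG0_sd = 0.5),
    rxn_row("EX_C", c(C = -1, C_ext = 1)))
  compart_model(mets, rxns, thermo = thermo_config())
}

# serine-like partial pair: a dehydrogenase releasing reduction force and
# its cofactor-consuming partner within the same enzyme
fixture_serA_partials <- function() {
  mets <- do.call(rbind, c(lapply(c("3pg_c", "3php_c", "akg_c", "s2hglut_c",
                                    "nad_c", "nadh_c"), met_row),
                           list(met_row("src_e", boundary = TRUE),
                                met_row("snk_e", boundary = TRUE))))
  rxns <- rbind(
    rxn_row("EX_src", c(src_e = -1, "3pg_c" = 1), flux_ub = 10),
    rxn_row("PGCD", c("3pg_c" = -1, nad_c = -1, "3php_c" = 1, nadh_c = 1),
            dG0 = 19.5, dG0_sd = 1, efficiency = 520, gene_rule = "b2913"),
    rxn_row("AHGDx_reverse", c(akg_c = -1, nadh_c = -1, s2hglut_c = 1,
                               nad_c = 1),
            dG0 = -17.4, dG0_sd = 1, efficiency = 145.44,
            gene_rule = "b2913"),
    rxn_row("EX_snk", c("3php_c" = -1, snk_e = 1)))
  compart_model(mets, rxns, thermo = thermo_config())
}

expect_no_findings <- function(model) {
  v <- validate_model(model)
  expect_equal(nrow(v), 0, info = paste(v$message, collapse = "; "))
}
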