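# Reaction merging, redundancy detection, scenarios.

test_that("the serine-style partial pair merges with cofactor cancellation", {
  m <- fixture_serA_partials()
  res <- merge_reactions(m, merge_spec("SerA", c("PGCD", "AHGDx_reverse"),
                                       declared_intermediates = c("nad_c", "nadh_c"),
                                       dG0_override = 2.1))
  s <- res$merged_reaction$stoich[[1]]
  expect_equal(s[order(names(s))],
               c("3pg_c" = -1, "3php_c" = 1, akg_c = -1, s2hglut_c = 1))
  expect_setequal(res$cancelled, c("nad_c", "nadh_c"))
  expect_equal(res$merged_reaction$dG0, 2.1)
  expect_equal(res$dG0_additivity, 19.5 - 17.4)   # logged despite override
  # the kinetically weakest step sets the merged efficiency
  expect_equal(res$merged_reaction$efficiency, 145.44)
  expect_setequal(res$merged_reaction$genes[[1]], "b2913")
  expect_equal(res$new_model$reactions$status[
    match(c("PGCD", "AHGDx_reverse"), res$new_model$reactions$id)],
    c("shut", "shut"))
  expect_equal(res$merged_reaction$status, "added")
  # uncertainty combines as root sum of squares
  expect_equal(res$merged_reaction$dG0_sd, sqrt(2), tolerance = 1e-12)
})

test_that("tryptophan-synthase partials recompose the overall reaction", {
  mp <- system.file("extdata", "trp_mini_model.json", package = "mdfpath")
  pp <- system.file("extdata", "trp_params.tsv", package = "mdfpath")
  m <- load_model(mp, pp)
  res <- merge_reactions(m, merge_spec("TRPS_overall", c("TRPS3", "TRPS2"),
                                       declared_intermediates = "indole_c"))
  s1 <- m$reactions$stoich[[match("TRPS1", m$reactions$id)]]
  s2 <- res$merged_reaction$stoich[[1]]
  expect_equal(s2[order(names(s2))], s1[order(names(s1))])
  expect_equal(res$cancelled, "indole_c")
  expect_setequal(res$merged_reaction$genes[[1]], c("b1260", "b1261"))
})

test_that("the aconitase correction builds the reversible overall pair", {
  mp <- system.file("extdata", "trp_mini_model.json", package = "mdfpath")
  pp <- system.file("extdata", "trp_params.tsv", package = "mdfpath")
  m <- load_model(mp, pp)
  batch <- read_merge_specs(system.file("extdata", "table2_corrections.yaml",
                                        package = "mdfpath"))
  expect_length(batch$specs, 1)
  res <- merge_reactions(m, batch$specs[[1]])
  m2 <- shut_reactions(res$new_model, batch$shut)
  ja <- match("ACONT", m2$reactions$id)
  jr <- match("ACONT_r", m2$reactions$id)
  expect_equal(m2$reactions$stoich[[ja]][order(names(m2$reactions$stoich[[ja]]))],
               c(cit_c = -1, icit_c = 1))
  expect_equal(m2$reactions$dG0[ja], 8.3)
  expect_equal(m2$reactions$dG0[jr], -8.3)
  expect_setequal(res$cancelled, c("acon_C_c", "h2o_c"))
  # Table-style statuses after the batch
  expect_true(all(m2$reactions$status[match(c("TRPS2", "TRPS3", "ACONTa",
                                              "ACONTb", "ACONTa_r",
                                              "ACONTb_r"),
                                            m2$reactions$id)] == "shut"))
  expect_equal(m2$reactions$status[match("TRPS1", m2$reactions$id)], "keep")
})

test_that("driving-force additivity holds at any concentration vector", {
  m <- fixture_serA_partials()
  res <- merge_reactions(m, merge_spec("SerA", c("PGCD", "AHGDx_reverse"),
                                       declared_intermediates = c("nad_c", "nadh_c")))
  mets <- c("3pg_c", "3php_c", "akg_c", "s2hglut_c", "nad_c", "nadh_c")
  set.seed(11)
  for (k in 1:100) {
    lnc <- stats::setNames(stats::runif(6, log(1e-6), log(1e-2)), mets)
    f_parts <- driving_force(m, "PGCD", lnc) +
      driving_force(m, "AHGDx_reverse", lnc)
    expect_equal(driving_force(res$new_model, "SerA", lnc), f_parts,
                 tolerance = 1e-9)
  }
})

test_that("merge errors and warnings are specific", {
  m <- fixture_serA_partials()
  expect_error(merge_reactions(m, merge_spec("X", c("PGCD", "nope"))),
               "nope")
  expect_error(merge_reactions(m, merge_spec("PGCD", c("PGCD", "AHGDx_reverse"))),
               "already exists")
  expect_error(
    merge_reactions(m, merge_spec("X", c("PGCD", "AHGDx_reverse"),
                                  declared_intermediates = "akg_c")),
    "akg_c")
  # nothing cancels: pure lumping is a warning, not an error
  d <- fixture_diamond(lenA = 1, lenB = 2)
  expect_warning(merge_reactions(d, merge_spec("L", c("RA1", "RB1"))),
                 "pure lumping")
  expect_error(merge_spec("X", "only_one"), "at least 2")
})

test_that("multipliers weight the stoichiometric sum", {
  mets <- do.call(rbind, lapply(c("A", "B", "C"), met_row))
  rxns <- rbind(rxn_row("R1", c(A = -1, B = 2), dG0 = -3),
                rxn_row("R2", c(B = -1, C = 1), dG0 = 1))
  m <- compart_model(mets, rxns)
  res <- merge_reactions(m, merge_spec("M", c(R1 = 1L, R2 = 2L),
                                       declared_intermediates = "B"))
  s <- res$merged_reaction$stoich[[1]]
  expect_equal(s[order(names(s))], c(A = -1, C = 2))
  expect_equal(res$merged_reaction$dG0, -3 + 2 * 1)
})

test_that("shut reactions are idempotent and cut the network", {
  m <- gen_linear_chain(generator_config(), c(-5, 10))
  m2 <- shut_reactions(m, c("R1", "R1"))
  expect_identical(shut_reactions(m2, "R1"), m2)
  r <- solve_fba(assemble_constraints(m2, enzyme_on = FALSE,
                                      thermo_on = FALSE), "EX_C")
  expect_equal(r$objective_value, 0)
  m3 <- shut_reactions(m, "EX_C")   # only product-forming exchange
  r3 <- solve_fba(assemble_constraints(m3, enzyme_on = FALSE,
                                       thermo_on = FALSE), "EX_C")
  expect_equal(r3$objective_value, 0)
  expect_error(shut_reactions(m, "nope"), "nope")
})

test_that("redundancy flags orphan substrates, dead ends and blocked pairs", {
  mp <- system.file("extdata", "trp_mini_model.json", package = "mdfpath")
  m <- load_model(mp)
  red <- find_redundant_reactions(m)
  expect_true(any(red$reaction == "MTRPOXN" &
                    grepl("orphan-substrate: mtrp_c", red$reason)))

  # an isolated reversible stereoisomer pair: both directions flagged
  mets <- do.call(rbind, c(lapply(c("akg2", "r2hglut", "nadh2", "nad2"),
                                  met_row),
                           list(met_row("s_e", boundary = TRUE))))
  r <- rxn_row("ARHGDx", c(akg2 = -1, nadh2 = -1, r2hglut = 1, nad2 = 1),
               dG0 = -10)
  r$reversible <- TRUE; r$flux_lb <- -1000
  m2 <- compart_model(mets, rbind(
    r, rxn_row("EX_n", c(s_e = -1, nadh2 = 1, nad2 = -1))))
  sp <- split_reversible(m2)
  red2 <- find_redundant_reactions(sp)
  expect_true(all(c("ARHGDx", "ARHGDx_reverse") %in% red2$reaction))

  # a fully connected chain is clean
  clean <- find_redundant_reactions(gen_linear_chain(generator_config(),
                                                     c(-5, 10)))
  expect_equal(nrow(clean), 0)
})

test_that("scenario switching closes and restores the oxygen exchange", {
  m <- gen_linear_chain(generator_config(), c(-5, 10))
  m$reactions$id[1] <- "EX_o2"; m$reactions$name[1] <- "EX_o2"
  man <- apply_scenario(m, "anaerobic")
  r <- solve_fba(assemble_constraints(man, enzyme_on = FALSE,
                                      thermo_on = FALSE), "EX_C")
  expect_equal(r$objective_value, 0)
  rest <- apply_scenario(man, "aerobic")
  expect_equal(rest$reactions$flux_ub[1], 10)

  # O2-independent network is untouched
  m2 <- gen_linear_chain(generator_config(), c(-5, 10))
  expect_error(apply_scenario(m2, "anaerobic"), "not found")
  m2$reactions <- rbind(m2$reactions,
                        rxn_row("EX_o2", c(A_ext = -1), flux_ub = 5))
  man2 <- apply_scenario(m2, "anaerobic")
  r2 <- solve_fba(assemble_constraints(man2, enzyme_on = FALSE,
                                       thermo_on = FALSE), "EX_C")
  expect_equal(r2$objective_value, 10)
})

test_that("shared-gene scan hints at the coupled pair", {
  m <- gen_coupled_motif()
  h <- merge_hints(m)
  expect_true(any(h$reaction_a == "U" & h$reaction_b == "F" &
                    h$shared_genes == "g_multi"))
})
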