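# Driving-force arithmetic, problem assembly, and the four solvers.

RTconst <- thermo_config()$RT

test_that("driving force follows -(dG0 + RT * sum s ln c)", {
  m <- fixture_serA_partials()
  res <- merge_reactions(m, merge_spec("SerA", c("PGCD", "AHGDx_reverse"),
                                       declared_intermediates = c("nad_c", "nadh_c"),
                                       dG0_override = 2.1))
  mm <- res$new_model
  # at the 1 M reference state the concentration term vanishes
  lnc <- stats::setNames(rep(0, 6), c("3pg_c", "3php_c", "akg_c",
                                      "s2hglut_c", "nad_c", "nadh_c"))
  expect_equal(driving_force(mm, "SerA", lnc), -2.1)

  # raising one substrate (coefficient -1) a thousand-fold adds RT ln 1000
  lnc2 <- lnc; lnc2["3pg_c"] <- log(1000)
  gain <- driving_force(mm, "SerA", lnc2) - driving_force(mm, "SerA", lnc)
  expect_equal(gain, RTconst * log(1000), tolerance = 1e-12)

  # equal concentrations leave only -dG0
  chain <- gen_linear_chain(generator_config(), c(-5, 10))
  lnc3 <- c(A = log(1e-4), B = log(1e-4), C = log(1e-4))
  expect_equal(driving_force(chain, "R1", lnc3), 5)

  # error paths: thermo-exempt reaction, missing concentration
  expect_error(driving_force(chain, "EX_A", lnc3), "thermo-exempt")
  expect_error(driving_force(chain, "R1", lnc3[-2]), "B")
})

test_that("assembly builds the expected structure and audits bigM", {
  m <- gen_linear_chain(generator_config(), c(-5, 10))
  p <- assemble_constraints(m, enzyme_on = FALSE)
  pm <- mdfpath:::problem_matrices(p)
  expect_length(pm$idx$z, 2)        # one binary per dG0-carrying reaction
  expect_length(pm$idx$B, 1)
  expect_length(pm$idx$lnc, 3)      # A, B, C
  # 3 balance rows + 2 driving-force rows + 2 linking rows + sum z >= 1
  expect_equal(nrow(pm$mat), 8)

  small <- thermo_config(bigM = 10)
  expect_error(assemble_constraints(m, small, enzyme_on = FALSE), "bigM")

  expect_error(assemble_constraints(m, enzyme_on = FALSE, thermo_on = TRUE,
                                    config = thermo_config()) |>
                 solve_fba("nope"), "not in model")

  # enzyme cost term: flux over efficiency, g/gDW
  m2 <- gen_linear_chain(generator_config(), c(-5), efficiency = 3540)
  p2 <- assemble_constraints(m2, thermo_on = FALSE)
  r <- solve_fba(p2, "EX_B")
  expect_equal(unname(r$enzyme_costs["R1"]),
               unname(r$fluxes["R1"]) / 3540)
  v10 <- 10 / 3540
  expect_equal(v10, 0.002824859, tolerance = 1e-6)
})

test_that("a degenerate ratio window forces equal concentrations", {
  m <- gen_coupled_motif(ratio_bounds = c(1, 1))
  p <- assemble_constraints(m, enzyme_on = FALSE)
  r <- solve_max_mdf(p, "EX_P", 1)
  expect_equal(unname(r$log_conc["Xred"]), unname(r$log_conc["Xox"]),
               tolerance = 1e-9)
})

test_that("FBA respects conservation, cuts and the enzyme budget", {
  m <- gen_linear_chain(generator_config(), c(-5, 10))
  p <- assemble_constraints(m, enzyme_on = FALSE, thermo_on = FALSE)
  r <- solve_fba(p, "EX_C")
  expect_equal(r$objective_value, 10)
  S <- stoich_matrix(m)
  expect_lt(max(abs(S %*% r$fluxes[colnames(S)])), 1e-6)

  m2 <- shut_reactions(m, "R1")
  r2 <- solve_fba(assemble_constraints(m2, enzyme_on = FALSE,
                                       thermo_on = FALSE), "EX_C")
  expect_equal(r2$objective_value, 0)

  # enzyme budget binds at v = E_total * efficiency: 0.05 * 140 = 7
  m3 <- gen_linear_chain(generator_config(E_total = 0.05), c(-5),
                         efficiency = 140)
  r3 <- solve_fba(assemble_constraints(m3, thermo_on = FALSE), "EX_B")
  expect_equal(r3$objective_value, 7, tolerance = 1e-9)
  expect_lte(sum(r3$enzyme_costs, na.rm = TRUE),
             m3$total_enzyme_bound + 1e-9)
})

test_that("pFBA minimizes total flux at the objective optimum", {
  # redundant parallel path: 1 step vs 2 steps -> all flux on the short one
  d <- fixture_diamond(lenA = 1, lenB = 2)
  p <- assemble_constraints(d, enzyme_on = FALSE, thermo_on = FALSE)
  r <- solve_pfba(p, "EX_P")
  expect_equal(unname(r$fluxes["RA1"]), 10, tolerance = 1e-5)
  expect_equal(unname(r$fluxes["RB1"]), 0, tolerance = 1e-5)

  # single path: pFBA flux vector equals the FBA one
  m <- gen_linear_chain(generator_config(), c(-5, 10))
  ps <- assemble_constraints(m, enzyme_on = FALSE, thermo_on = FALSE)
  expect_equal(solve_pfba(ps, "EX_C")$fluxes, solve_fba(ps, "EX_C")$fluxes,
               tolerance = 1e-5)

  # diamond: minimum total flux matches exhaustive split enumeration
  for (lens in list(c(2, 2), c(2, 3))) {
    dd <- fixture_diamond(lenA = lens[1], lenB = lens[2])
    pd <- assemble_constraints(dd, enzyme_on = FALSE, thermo_on = FALSE)
    rr <- solve_pfba(pd, "EX_P")
    expect_equal(rr$objective_value,
                 brute_min_total_flux(10, lens[1], lens[2], 1000, 1000),
                 tolerance = 1e-4, info = paste(lens, collapse = "/"))
  }
  # capacity-limited short route forces a split
  dc <- fixture_diamond(lenA = 1, lenB = 2, capA = 4)
  rc <- solve_pfba(assemble_constraints(dc, enzyme_on = FALSE,
                                        thermo_on = FALSE), "EX_P")
  expect_equal(rc$objective_value, brute_min_total_flux(10, 1, 2, 4, 1000),
               tolerance = 1e-4)
  expect_equal(unname(rc$fluxes["RA1"]), 4, tolerance = 1e-5)
})

test_that("max-MDF matches the analytic and grid-search oracles", {
  m1 <- gen_linear_chain(generator_config(), c(-5, 10))
  p1 <- assemble_constraints(m1, enzyme_on = FALSE)
  r1 <- solve_max_mdf(p1, "EX_C", 1)
  analytic1 <- -2.5 + RTconst / 2 * log(1e4)   # balanced pair over the span
  expect_equal(r1$mdf, analytic1, tolerance = 1e-6)
  expect_equal(oracle_mdf(m1, n = 60), r1$mdf, tolerance = RTconst * 0.16)

  m2 <- gen_linear_chain(generator_config(), c(-30, 30))
  r2 <- solve_max_mdf(assemble_constraints(m2, enzyme_on = FALSE), "EX_C", 1)
  analytic2 <- -30 + RTconst * log(1e4)        # second step at full span
  expect_equal(r2$mdf, analytic2, tolerance = 1e-6)

  # every active reaction keeps driving force >= B at the witness
  for (rid in c("R1", "R2")) {
    expect_gte(driving_force(m1, rid, r1$log_conc), r1$mdf - 1e-4)
  }

  # min_flux 0: the best single reaction sets B (activity is optional)
  r0 <- solve_max_mdf(p1, "EX_C", 0)
  expect_equal(r0$mdf, 5 + RTconst * log(1e4), tolerance = 1e-6)

  # demand above the network maximum is infeasible
  rinf <- solve_max_mdf(p1, "EX_C", 11)
  expect_equal(rinf$status, "infeasible")
})

test_that("max flux at MDF closes the loop with max-MDF", {
  m <- gen_linear_chain(generator_config(), c(-5, 10))
  p <- assemble_constraints(m, enzyme_on = FALSE)
  # vacuous MDF bound reproduces plain FBA
  rv <- solve_max_flux_at_mdf(p, "EX_C", -1000)
  expect_equal(rv$objective_value, 10, tolerance = 1e-6)
  # at the exact optimum B* the uptake bound is attainable
  B <- solve_max_mdf(p, "EX_C", 1)$mdf
  ratB <- solve_max_flux_at_mdf(p, "EX_C", B - 1e-4)
  expect_equal(ratB$objective_value, 10, tolerance = 1e-4)
  # above B* the demanded pathway cannot run: flux collapses to zero
  rup <- solve_max_flux_at_mdf(p, "EX_C", B + 1)
  expect_equal(rup$objective_value, 0, tolerance = 1e-6)
  # above the best single reaction's maximum nothing at all is feasible
  expect_equal(solve_max_flux_at_mdf(p, "EX_C", 30)$status, "infeasible")

  # duality of the two steps: re-running step 1 at the step-2 flux gives B
  B2 <- solve_max_mdf(p, "EX_C", ratB$objective_value - 1e-6)$mdf
  expect_equal(B2, B, tolerance = 1e-4)
})

test_that("MDF is monotone non-increasing in required flux", {
  for (seed in 1:6) {
    m <- gen_random_model(generator_config(seed = seed, n_reactions = 6))
    p <- assemble_constraints(m, enzyme_on = FALSE)
    fmax <- solve_fba(p, "EX_SNK")$objective_value
    vals <- vapply(seq(0.1, fmax, length.out = 4), function(fl)
      solve_max_mdf(p, "EX_SNK", fl)$mdf, numeric(1))
    expect_true(all(diff(vals) <= 1e-4), info = paste("seed", seed))
  }
})

test_that("LP export writes a readable problem file", {
  m <- gen_linear_chain(generator_config(), c(-5, 10))
  p <- assemble_constraints(m, enzyme_on = FALSE)
  f <- tempfile(fileext = ".lp")
  export_lp(p, "EX_C", f)
  txt <- readLines(f)
  expect_true(any(grepl("^Maximize", txt)))
  expect_true(any(grepl("Binaries", txt)))
  expect_true(any(grepl("v_EX_C", txt)))
})
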