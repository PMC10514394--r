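# Bottleneck identification, limiting metabolites, enzyme-cost variability.

test_that("per-reaction driving-force maxima agree with the grid oracle", {
  for (dgs in list(c(-5, 10), c(-30, 30))) {
    m <- gen_linear_chain(generator_config(), dgs)
    p <- assemble_constraints(m, enzyme_on = FALSE)
    B <- solve_max_mdf(p, "EX_C", 1)$mdf
    fx <- solve_pfba(p, "EX_C", min_flux = 1, mdf_lb = B - 1e-4)
    maxdf <- reaction_max_driving_forces(m, product = "EX_C", min_flux = 1,
                                         Bstar = B, flux_fixture = fx)
    og <- oracle_grid(m, n = 80)
    odf <- oracle_max_df(m, n = 80, Bstar = B, og = og)
    for (rid in names(maxdf)) {
      expect_equal(maxdf[[rid]], odf[[rid]],
                   tolerance = 2 * thermo_config()$RT * max(og$step),
                   info = paste(paste(dgs, collapse = ","), rid))
    }
  }
})

test_that("the balanced pair both pin B*, the harsh pair only at the worst step", {
  m1 <- gen_linear_chain(generator_config(), c(-5, 10))
  p1 <- assemble_constraints(m1, enzyme_on = FALSE)
  B1 <- solve_max_mdf(p1, "EX_C", 1)$mdf
  fx1 <- solve_pfba(p1, "EX_C", min_flux = 1, mdf_lb = B1 - 1e-4)
  maxdf1 <- reaction_max_driving_forces(m1, product = "EX_C", min_flux = 1,
                                        Bstar = B1, flux_fixture = fx1)
  expect_equal(unname(maxdf1["R1"]), B1, tolerance = 1e-4)
  expect_equal(unname(maxdf1["R2"]), B1, tolerance = 1e-4)
  expect_false("EX_A" %in% names(maxdf1))   # thermo-exempt, absent

  m2 <- gen_linear_chain(generator_config(), c(-30, 30))
  p2 <- assemble_constraints(m2, enzyme_on = FALSE)
  B2 <- solve_max_mdf(p2, "EX_C", 1)$mdf
  fx2 <- solve_pfba(p2, "EX_C", min_flux = 1, mdf_lb = B2 - 1e-4)
  maxdf2 <- reaction_max_driving_forces(m2, product = "EX_C", min_flux = 1,
                                        Bstar = B2, flux_fixture = fx2)
  expect_equal(unname(maxdf2["R2"]), B2, tolerance = 1e-4)
  expect_gt(unname(maxdf2["R1"]), B2 + 10)  # far from pinning
})

test_that("bottleneck classification and limiting metabolites are recovered", {
  m1 <- gen_linear_chain(generator_config(), c(-5, 10))
  bn1 <- identify_bottlenecks(m1, product = "EX_C", min_flux = 1,
                              enzyme_on = FALSE)
  expect_setequal(bn1$bottlenecks, c("R1", "R2"))
  expect_equal(bn1$classification, "distributed")
  lim1 <- bn1$limiting_metabolites
  expect_equal(lim1$reason[lim1$metabolite == "A"], "at_upper_bound")
  expect_equal(lim1$reason[lim1$metabolite == "B"], "balanced")
  expect_equal(lim1$reason[lim1$metabolite == "C"], "at_lower_bound")
  # the distributed pair shares the balanced intermediate
  expect_setequal(bn1$shared_limiting_mets[["B"]], c("R1", "R2"))

  m2 <- gen_linear_chain(generator_config(), c(-30, 30))
  bn2 <- identify_bottlenecks(m2, product = "EX_C", min_flux = 1,
                              enzyme_on = FALSE)
  expect_equal(bn2$bottlenecks, "R2")
  expect_equal(bn2$classification, "localized")
})

test_that("concentration variability pins sources, sinks and balances", {
  m <- gen_linear_chain(generator_config(), c(-5, 10))
  p <- assemble_constraints(m, enzyme_on = FALSE)
  B <- solve_max_mdf(p, "EX_C", 1)$mdf
  fx <- solve_pfba(p, "EX_C", min_flux = 1, mdf_lb = B - 1e-4)
  cv <- concentration_variability(m, product = "EX_C", min_flux = 1,
                                  Bstar = B, flux_fixture = fx)
  a <- cv[cv$metabolite == "A", ]
  expect_equal(a$conc_min, 1e-2, tolerance = 1e-3)
  expect_equal(a$conc_max, 1e-2, tolerance = 1e-3)
  b <- cv[cv$metabolite == "B", ]
  expect_equal(b$conc_min, b$conc_max, tolerance = 1e-6)
  # grid oracle confirms the ranges within two grid steps
  og <- oracle_grid(m, n = 80)
  orng <- oracle_conc_range(m, n = 80, Bstar = B, og = og)
  for (mm in cv$metabolite) {
    expect_lt(abs(log(cv$conc_min[cv$metabolite == mm]) - orng[mm, 1]),
              2 * max(og$step))
    expect_lt(abs(log(cv$conc_max[cv$metabolite == mm]) - orng[mm, 2]),
              2 * max(og$step))
  }

  # a metabolite of an inactive reaction spans its full bounds
  m3 <- gen_branched_network(generator_config())
  p3 <- assemble_constraints(m3, enzyme_on = FALSE)
  B3 <- solve_max_mdf(p3, "EX_P", 1)$mdf   # only route A active at low demand
  fx3 <- solve_pfba(p3, "EX_P", min_flux = 1, mdf_lb = B3 - 1e-4)
  cv3 <- concentration_variability(m3, product = "EX_P", min_flux = 1,
                                   Bstar = B3, flux_fixture = fx3,
                                   metabolites = "N1")
  expect_equal(cv3$conc_min, 1e-6, tolerance = 1e-6)
  expect_equal(cv3$conc_max, 1e-2, tolerance = 1e-6)
})

test_that("merging the coupled pair moves the bottleneck downstream", {
  m <- gen_coupled_motif()
  bn_pre <- identify_bottlenecks(m, product = "EX_P", min_flux = 0.5,
                                 enzyme_on = FALSE)
  expect_true("U" %in% bn_pre$bottlenecks)   # ratio-limited dehydrogenase
  merged <- merge_reactions(m, motif_merge_spec())$new_model
  bn_post <- identify_bottlenecks(merged, product = "EX_P", min_flux = 0.5,
                                  enzyme_on = FALSE)
  # the cofactor constraint is gone; the narrow-window downstream step now
  # caps the pathway alone
  expect_equal(bn_post$bottlenecks, "D")
  expect_equal(bn_post$classification, "localized")
  expect_gt(bn_post$mdf, bn_pre$mdf)
})

test_that("no bottlenecks means no limiting metabolites", {
  m <- gen_linear_chain(generator_config(), c(-5, 10))
  lim <- identify_limiting_metabolites(m, bottlenecks = character(0),
                                       conc_var = NULL)
  expect_equal(nrow(lim), 0)
})

test_that("bottleneck soundness: relaxing a non-bottleneck never helps", {
  for (seed in c(2, 5, 8, 11, 14, 17, 20, 23, 26, 29, 32, 35)) {
    m <- gen_random_model(generator_config(seed = seed, n_reactions = 5))
    bn <- suppressWarnings(
      identify_bottlenecks(m, product = "EX_SNK", min_flux = 0.5,
                           enzyme_on = FALSE, warn_degenerate = FALSE))
    thermo_ids <- m$reactions$id[!is.na(m$reactions$dG0)]
    relax <- function(ids) {
      mm <- m
      mm$reactions$dG0[match(ids, mm$reactions$id)] <- NA_real_
      solve_max_mdf(assemble_constraints(mm, enzyme_on = FALSE),
                    "EX_SNK", 0.5)$mdf
    }
    for (rid in setdiff(names(bn$per_reaction_max_df), bn$bottlenecks)) {
      expect_lte(relax(rid), bn$mdf + 1e-4,
                 label = paste("seed", seed, "relax", rid))
    }
    if (length(bn$bottlenecks) &&
        length(setdiff(thermo_ids, bn$bottlenecks))) {
      expect_gt(relax(bn$bottlenecks), bn$mdf - 1e-4)
    }
  }
})

test_that("enzyme costs lose variability exactly when the budget binds", {
  # single path, budget sized to bind at the demanded flux
  m <- gen_linear_chain(generator_config(E_total = 2 / 100), c(-5, 10),
                        efficiency = 1000)
  # cost at v = 10: 2 reactions * 10/1000 = 0.02 = E_total -> binding
  B <- solve_max_mdf(assemble_constraints(m), "EX_C", 10)$mdf
  ec <- enzyme_cost_variability(m, product = "EX_C", min_flux = 10, Bstar = B)
  expect_true(all(ec$is_key))
  expect_true(all(ec$cost_max - ec$cost_min <= 1e-6))
  expect_true(attr(ec, "budget_binding"))

  # two equal parallel routes with slack budget: variable costs, no keys
  d <- fixture_diamond(lenA = 2, lenB = 2)
  d$reactions$dG0 <- c(NA, -10, -10, -10, -10, NA)
  d$reactions$efficiency <- c(NA, 1000, 1000, 1000, 1000, NA)
  d$total_enzyme_bound <- 10   # never binding
  B2 <- solve_max_mdf(assemble_constraints(d), "EX_P", 5)$mdf
  ec2 <- enzyme_cost_variability(d, product = "EX_P", min_flux = 5,
                                 Bstar = B2)
  expect_false(any(ec2$is_key))
  expect_true(all(ec2$cost_max - ec2$cost_min > 1e-4))
  expect_false(attr(ec2, "budget_binding"))
  # reactions without efficiency are absent from the records
  expect_false(any(c("EX_A", "EX_P") %in% ec2$reaction))
})
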