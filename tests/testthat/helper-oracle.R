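# Independent grid-search oracles.  These never call the package's MILP
# path: they evaluate driving forces directly on a dense log-concentration
# grid and take exhaustive minima/maxima.  Suitable for fixtures with at
# most three or four non-boundary metabolites.

# per-reaction driving-force arrays (as flat vectors over the grid) plus a
# feasibility mask from the ratio constraints
oracle_grid <- function(model, config = model_thermo(model), n = 60) {
  nb <- model$metabolites$id[!model$metabolites$is_boundary]
  cb <- conc_bounds(model, config)
  dims <- rep(n, length(nb))
  npts <- prod(dims)
  grids <- lapply(nb, function(mm) {
    k <- match(mm, cb$id)
    seq(log(cb$conc_lb[k]), log(cb$conc_ub[k]), length.out = n)
  })
  names(grids) <- nb
  tmpl <- array(0L, dims)
  axis <- lapply(seq_along(nb), function(i) {
    as.vector(grids[[i]][slice.index(tmpl, i)])
  })
  names(axis) <- nb
  step <- vapply(grids, function(g) if (length(g) > 1) g[2] - g[1] else 0,
                 numeric(1))
  rxns <- model$reactions
  idx <- which(!is.na(rxns$dG0) & rxns$status != "shut")
  f <- lapply(idx, function(j) {
    s <- rxns$stoich[[j]]
    s <- s[names(s) %in% nb]
    term <- numeric(npts)
    for (mm in names(s)) term <- term + s[[mm]] * axis[[mm]]
    -(rxns$dG0[j] + config$RT * term)
  })
  names(f) <- rxns$id[idx]
  mask <- rep(TRUE, npts)
  rc <- config$ratio_constraints
  for (k in seq_len(nrow(rc))) {
    d <- axis[[rc$met_a[k]]] - axis[[rc$met_b[k]]]
    mask <- mask & d <= log(rc$ratio_ub[k]) + 1e-9 &
      d >= log(rc$ratio_lb[k]) - 1e-9
  }
  list(axis = axis, f = f, mask = mask, step = step, nb = nb)
}

# exhaustive MDF with every dG0-carrying reaction active
oracle_mdf <- function(model, config = model_thermo(model), n = 60,
                       og = NULL) {
  if (is.null(og)) og <- oracle_grid(model, config, n)
  worst <- Reduce(pmin, og$f)
  worst[!og$mask] <- -Inf
  max(worst)
}

# per-reaction maximum driving force subject to all reactions >= Bstar;
# `slack` absorbs the grid discretization of Bstar itself
oracle_max_df <- function(model, config = model_thermo(model), n = 60,
                          Bstar, slack = NULL, og = NULL) {
  if (is.null(og)) og <- oracle_grid(model, config, n)
  if (is.null(slack)) slack <- config$RT * max(og$step)
  ok <- og$mask
  for (f in og$f) ok <- ok & f >= Bstar - slack
  vapply(og$f, function(f) max(f[ok]), numeric(1))
}

# concentration variability (in ln units) subject to all reactions >= Bstar
oracle_conc_range <- function(model, config = model_thermo(model), n = 60,
                              Bstar, slack = NULL, og = NULL) {
  if (is.null(og)) og <- oracle_grid(model, config, n)
  if (is.null(slack)) slack <- config$RT * max(og$step)
  ok <- og$mask
  for (f in og$f) ok <- ok & f >= Bstar - slack
  t(vapply(og$nb, function(mm)
    c(min(og$axis[[mm]][ok]), max(og$axis[[mm]][ok])), numeric(2)))
}

# minimum total flux of a two-route source->product network by exhaustive
# enumeration over the route split (routes of lenA and lenB internal steps,
# two exchange reactions, capacities per route)
brute_min_total_flux <- function(demand, lenA, lenB, capA, capB,
                                 by = 0.005) {
  ts <- seq(0, 1, by = by)
  tot <- vapply(ts, function(t) {
    vA <- t * demand; vB <- (1 - t) * demand
    if (vA > capA + 1e-9 || vB > capB + 1e-9) return(Inf)
    2 * demand + lenA * vA + lenB * vB
  }, numeric(1))
  min(tot)
}
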