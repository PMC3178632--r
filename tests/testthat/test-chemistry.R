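# stochastic chemistry: eligibility, hydrolysis, depolymerization, severing

test_that("eligible binders: tip-only vs side-binding counting", {
  st <- make_tiny_state(n_fil = 4, len = 25, n_parb = 6, n_bind = 4)
  side <- chemistry_params(binding_mode = "SIDE")
  tip <- chemistry_params(binding_mode = "TIP_ONLY")
  expect_length(eligible_binders(st, side), 100)
  tips <- eligible_binders(st, tip)
  expect_length(tips, 4)
  expect_setequal(tips, vapply(st$chains[1:4], `[`, integer(1), 1))
})

test_that("after depolymerization events the new terminal subunit becomes the eligible tip", {
  st <- make_tiny_state(n_fil = 4, len = 25, n_parb = 6, n_bind = 4)
  tip <- chemistry_params(binding_mode = "TIP_ONLY", k_d = 1e6,
                          disassembly_mode = "TIP_ONLY")
  # hydrolyze the first three subunits of filament 1 by hand, then let the
  # near-certain per-step conversion remove them one per step from the tip
  st$nucleotide[st$chains[[1]][1:3]] <- "ADP"
  expected_tip <- st$chains[[1]][4]
  removed <- integer(0)
  for (k in 1:3) {
    out <- depolymerization_step(st, tip, dt = 1, seed = 100 + k)
    expect_equal(nrow(out$events[out$events$kind == "DEPOLYMERIZATION" &
                                   out$events$filament_id == 1, ]), 1)
    removed <- c(removed, out$events$subunit_id)
    st <- out$state
  }
  expect_equal(length(st$chains[[1]]), 22)
  expect_equal(st$chains[[1]][1], expected_tip)
  expect_equal(eligible_binders(st, tip)[1], expected_tip)
  expect_true(audit_topology(st)$pass)
})

test_that("hydrolysis requires threshold binding and matches the binomial oracle", {
  st <- make_tiny_state(n_fil = 2, len = 10, n_parb = 6, n_bind = 4)
  ch <- chemistry_params(k_h = 0.5, eps_threshold = 5)
  # no ParB within range: zero events always
  none <- hydrolysis_step(st, numeric(n_subunits(st)), ch, dt = 1, seed = 1)
  expect_equal(nrow(none$events), 0)
  # saturation: enormous rate converts every threshold-satisfying subunit
  mb <- numeric(n_subunits(st)); mb[st$chains[[1]]] <- 6
  sat <- hydrolysis_step(st, mb, chemistry_params(k_h = 1e9, eps_threshold = 5),
                         dt = 1, seed = 2)
  expect_equal(sort(sat$events$subunit_id), sort(st$chains[[1]]))
  expect_true(all(sat$state$nucleotide[st$chains[[1]]] == "ADP"))
  # binomial oracle: 1e4 independent bound subunits, k_h dt = 0.01
  big <- make_tiny_state(n_fil = 1, len = 1e4, n_parb = 2, n_bind = 2)
  p <- 1 - exp(-0.01)
  out <- hydrolysis_step(big, c(rep(10, 1e4), 0, 0),
                         chemistry_params(k_h = 0.01, eps_threshold = 5),
                         dt = 1, seed = 1234)
  expect_lt(abs(nrow(out$events) - 1e4 * p), 4 * sqrt(1e4 * p * (1 - p)))
})

test_that("tip-only depolymerization: ATP tips never detach; anchored ends never detach; hydrolyzed tips leave one per step", {
  st <- make_tiny_state(n_fil = 1, len = 10, n_parb = 4, n_bind = 2)
  ch <- chemistry_params(k_d = 1e9, disassembly_mode = "TIP_ONLY")
  # ATP at the tip: nothing happens even at enormous rate
  out <- depolymerization_step(st, ch, dt = 1, seed = 1)
  expect_equal(nrow(out$events), 0)
  # pre-hydrolyze everything: the filament sheds exactly one subunit per
  # step, always from the free tip, and the anchored end survives
  st$nucleotide[st$chains[[1]]] <- "ADP"
  lens <- integer(0)
  for (k in 1:12) {
    out <- depolymerization_step(st, ch, dt = 1, seed = 10 + k)
    st <- out$state
    lens <- c(lens, length(st$chains[[1]]))
  }
  expect_equal(lens[1:9], 9:1)
  expect_equal(lens[10:12], c(1, 1, 1)) # the anchored terminal never leaves
  expect_true(st$anchored[st$chains[[1]][1]])
  expect_equal(sum(st$species == "PARA"), st$n_para0)
})

test_that("hydrolyzed tip lifetime matches the exponential waiting-time oracle", {
  ts <- tip_lifetime_sample()
  expect_true(all(!is.na(ts$lifetimes)))
  # discrete-time geometric mean lifetime: dt / (1 - exp(-k dt)) ~ 1/k + dt/2
  expect_lt(abs(mean(ts$lifetimes) - ts$expected) / ts$expected, 0.05)
})

test_that("severing splits at interior ADP subunits with the documented cut convention", {
  st <- make_tiny_state(n_fil = 1, len = 25, n_parb = 4, n_bind = 2)
  sev <- chemistry_params(k_d = 1e9, disassembly_mode = "SEVERING")
  # no interior ADP: no severing ever
  out <- severing_step(st, sev, dt = 1, seed = 1)
  expect_equal(nrow(out$events), 0)
  # one interior ADP at chain index 11 of a 25-mer: fragments of length 10
  # (tip side, unanchored) and 14 (anchor side) plus one freed monomer
  cut_id <- st$chains[[1]][11]
  st$nucleotide[cut_id] <- "ADP"
  out <- severing_step(st, sev, dt = 1, seed = 2)
  expect_equal(out$events$kind, "SEVER")
  expect_equal(out$events$subunit_id, cut_id)
  parA_chains <- out$state$chains[vapply(out$state$chains, function(ch)
    out$state$species[ch[1]] == "PARA", logical(1))]
  expect_setequal(vapply(parA_chains, length, integer(1)), c(10L, 14L))
  anchored_chain <- vapply(seq_along(out$state$chains), function(c)
    out$state$chain_anchored[c] && out$state$species[out$state$chains[[c]][1]] == "PARA",
    logical(1))
  expect_equal(length(out$state$chains[[which(anchored_chain)]]), 14)
  m <- chain_membership(out$state)
  expect_equal(m$chain_id[cut_id], 0L) # freed monomer
  expect_true(audit_topology(out$state)$pass)
  # severed fragment subunits (still ATP) remain eligible binders in SIDE mode
  elig <- eligible_binders(out$state, chemistry_params(binding_mode = "SIDE"))
  frag <- parA_chains[[which(vapply(parA_chains, length, integer(1)) == 10)]]
  expect_true(all(frag %in% elig))
})

test_that("chemistry negative controls: k_h = 0 or eps_b = 0 never disassemble the bundle", {
  cfg <- small_config(n_fil = 2, len = 8, parb = 16, bind = 10, n_relax = 1000)
  cfg$integrator$n_steps <- 5000
  for (variant in c("kh0", "eps0")) {
    c2 <- cfg
    if (variant == "kh0") c2$chemistry$k_h <- 0 else c2$forcefield$eps_b <- 0
    run <- run_simulation(c2, seed = 8, sample_stride = 500)
    expect_equal(nrow(run$events), 0)
    expect_true(all(run$samples$n_poly == run$samples$n_poly[1]))
  }
})

test_that("topology audit passes through mixed chemistry and fails the planted defect", {
  cfg <- small_config(n_fil = 3, len = 10, parb = 20, bind = 12, n_relax = 2000,
                      chemistry = list(k_h = 0.2, k_d = 0.05))
  cfg$integrator$n_steps <- 1000
  run <- run_simulation(cfg, seed = 13, sample_stride = 100)
  expect_true(audit_topology(run$state)$pass)
  # conservation at every sampled step
  expect_true(all(run$samples$n_poly + (run$state$n_para0 - run$samples$n_poly) ==
                    run$state$n_para0))
  # planted defect: delete a subunit from its chain
  broken <- run$state
  broken$species[broken$chains[[1]][1]] <- "PARB_INERT"
  broken$nucleotide[broken$chains[[1]][1]] <- "NONE"
  audit <- audit_topology(broken)
  expect_false(audit$pass)
  expect_match(paste(audit$diagnostics, collapse = " "), "count")
})

test_that("tip-only ordering invariant: polymerized runs never develop interior gaps", {
  cfg <- small_config(n_fil = 3, len = 12, parb = 24, bind = 14, n_relax = 2000,
                      chemistry = list(k_h = 0.3, k_d = 0.1))
  cfg$integrator$n_steps <- 30000
  run <- run_simulation(cfg, seed = 17, sample_stride = 0)
  # every surviving ParA chain must be a contiguous id run of its original
  # filament (ids were assigned consecutively at build time)
  for (c in seq_along(run$state$chains)) {
    ch <- run$state$chains[[c]]
    if (run$state$species[ch[1]] != "PARA") next
    expect_true(all(diff(ch) == 1))
  }
  expect_gt(nrow(run$events), 0) # chemistry actually ran
})
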