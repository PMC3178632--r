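# system construction and scenario presets

test_that("hexagonal bundle: one central filament plus a ring at the configured spacing", {
  spec <- geometry_spec(n_filaments = 7, filament_length = 10, spacing = 1.5)
  bun <- build_bundle(spec, ff_default, seed = 1)
  expect_length(bun$chains, 7)
  centers <- t(vapply(bun$chains, function(ch) bun$pos[ch[1], 2:3], numeric(2)))
  radii <- sqrt(rowSums(centers^2))
  expect_equal(sum(radii < 1e-9), 1)
  expect_equal(unname(radii[radii > 1e-9]), rep(1.5, 6), tolerance = 1e-9)
  # tips at x = 0, pole ends at x = L-1, polarizations unit and perpendicular
  expect_true(all(vapply(bun$chains, function(ch) bun$pos[ch[1], 1] == 0, logical(1))))
  expect_equal(sqrt(rowSums(bun$pol^2)), rep(1, nrow(bun$pol)))
  expect_equal(max(abs(bun$pol[, 1])), 0)
})

test_that("crosslink sampling: none at fraction 0; exact reproducible count at 0.4", {
  spec0 <- geometry_spec(n_filaments = 5, filament_length = 10, crosslink_fraction = 0)
  expect_equal(nrow(build_bundle(spec0, ff_default, seed = 2)$crosslinks), 0)
  spec <- geometry_spec(n_filaments = 5, filament_length = 100,
                        crosslink_fraction = 0.4)
  b1 <- build_bundle(spec, ff_default, seed = 3)
  b2 <- build_bundle(spec, ff_default, seed = 3)
  expect_equal(b1$n_selected, 200)
  expect_identical(b1$crosslinks, b2$crosslinks)
  # partners sit at the same axial index in a neighboring filament
  idx <- (b1$crosslinks - 1) %% 100
  expect_true(all(idx[, 1] == idx[, 2]))
  d <- sqrt(rowSums((b1$pos[b1$crosslinks[, 1], ] - b1$pos[b1$crosslinks[, 2], ])^2))
  expect_equal(d, rep(spec$spacing, length(d)), tolerance = 1e-9)
})

test_that("ParB polymer: centered binding strip with inert flanks and their drag factor", {
  spec <- geometry_spec(parb_total_length = 100, parb_binding_length = 50)
  pb <- build_parb_polymer(spec, ff_default, seed = 4)
  expect_equal(as.integer(table(pb$species)), c(50L, 50L))
  expect_equal(pb$species[1:25], rep("PARB_INERT", 25))
  expect_equal(pb$species[26:75], rep("PARB_BIND", 50))
  expect_equal(pb$species[76:100], rep("PARB_INERT", 25))
  expect_equal(unique(pb$alpha[pb$species == "PARB_INERT"]), 5)
  expect_equal(unique(pb$alpha[pb$species == "PARB_BIND"]), 1)
  # bonds at rest length, self-avoiding growth
  bl <- sqrt(rowSums((pb$pos[-1, ] - pb$pos[-100, ])^2))
  expect_equal(bl, rep(1, 99), tolerance = 1e-9)
  d <- as.matrix(dist(pb$pos)); diag(d) <- Inf
  expect_gt(min(d), 0.9)
  # binding length = total length: no inert subunits
  all_bind <- build_parb_polymer(
    geometry_spec(parb_total_length = 30, parb_binding_length = 30),
    ff_default, seed = 5)
  expect_true(all(all_bind$species == "PARB_BIND"))
})

test_that("scenario presets encode the documented variant differences", {
  std <- scenario("standard")
  expect_equal(std$chemistry$binding_mode, "SIDE")
  expect_equal(std$chemistry$disassembly_mode, "TIP_ONLY")
  sev <- scenario("severing")
  expect_equal(sev$chemistry$disassembly_mode, "SEVERING")
  sev$chemistry$disassembly_mode <- "TIP_ONLY"
  sev$chemistry$disassembly_mode_code <- 0L
  sev$scenario_name <- "standard"
  expect_equal(sev, std)
  sparse <- scenario("sparse_bundle")
  expect_equal(sparse$geometry$spacing, 4 * std$geometry$spacing)
  tip <- scenario("tip_binding")
  expect_equal(tip$chemistry$binding_mode, "TIP_ONLY")
  expect_error(scenario("no_such_model"), "standard")
})

test_that("every preset builds, audits, and survives a short run", {
  for (name in parabd:::.SCENARIOS) {
    cfg <- scenario(name, geometry = list(n_relax_steps = 1500))
    if (!is.null(cfg$sweep)) cfg <- apply_sweep_value(cfg, cfg$sweep$values[1])
    st <- build_system(cfg, seed = 20)
    expect_true(audit_topology(st)$pass, label = paste(name, "audit"))
    run <- run_simulation(cfg, seed = 21, state = st, n_steps = 1000,
                          sample_stride = 500)
    expect_true(audit_topology(run$state)$pass, label = paste(name, "run audit"))
    expect_false(any(!is.finite(run$state$pos)), label = name)
  }
})

test_that("builder is deterministic given spec and seed", {
  cfg <- small_config(n_relax = 1000)
  s1 <- build_system(cfg, seed = 30)
  s2 <- build_system(cfg, seed = 30)
  expect_identical(s1$pos, s2$pos)
  expect_identical(s1$crosslinks, s2$crosslinks)
})

test_that("ParB polymer starts before the tip plane without hard overlaps", {
  cfg <- small_config(n_relax = 0)
  st <- build_system(cfg, seed = 31)
  parb <- st$species != "PARA"
  expect_lt(mean(st$pos[parb, 1]), 0)
  d <- parabd:::cross_dist2(st$pos[parb, , drop = FALSE],
                            st$pos[!parb, , drop = FALSE])
  expect_gt(min(d), 0.8^2)
})
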