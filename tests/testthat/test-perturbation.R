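test_that("config validation enforces stability and step-cap bounds", {
  expect_error(perturbation_config(E = -1), "E > 0")
  expect_error(perturbation_config(max_steps = 10), "max_steps")
  cfg <- perturbation_config()
  expect_equal(cfg$max_steps, 10000)
  star <- interaction_network(rep("c", 4), paste0("l", 1:4))
  expect_error(
    run_perturbation(star, "c", perturbation_config(k = 0.5)),
    "stability bound")
})

test_that("starting energy is split equally among seeds", {
  net <- interaction_network(c("X", "Y", "Z"), c("Y", "Z", "W"))
  st <- initialize_energy(net, "X", E = 1000)
  expect_equal(unname(st$energy["X"]), 1000)
  expect_equal(sum(st$energy), 1000)
  expect_equal(sum(st$reached), 1)

  st2 <- initialize_energy(net, c("X", "Y"), E = 1000)
  expect_equal(unname(st2$energy[c("X", "Y")]), c(500, 500))

  st3 <- initialize_energy(net, c("X", "Y", "Z", "W"), E = 1000)
  expect_true(all(st3$energy == 250))

  expect_error(initialize_energy(net, "missing"), "missing")
  expect_error(initialize_energy(net, character(0)), "nonempty")
})

test_that("a single step applies flow then clamped dissipation", {
  iso <- interaction_network(character(0), character(0), isolated = "A")
  st <- initialize_energy(iso, "A", E = 1000)
  st <- perturb_step(st, iso, perturbation_config())
  expect_equal(unname(st$energy), 995)

  duo <- interaction_network("u", "v")
  cfg <- perturbation_config(E = 100, D = 5, k = 0.25)
  st <- initialize_energy(duo, "u", E = 100)
  st <- perturb_step(st, duo, cfg)
  expect_equal(unname(st$energy[c("u", "v")]), c(70, 20))
  expect_true(all(st$reached))
})

test_that("silencing time matches the closed form on an isolated node", {
  iso <- interaction_network(character(0), character(0), isolated = "A")
  r <- run_perturbation(iso, "A", perturbation_config(E = 1000, D = 5))
  expect_equal(r$silencing_time, 200)
  expect_equal(r$perturbation_reach, 1)
  expect_false(r$terminated_by_cap)

  r2 <- run_perturbation(
    iso, "A", perturbation_config(E = 10000, D = 1, max_steps = 1e5))
  expect_equal(r2$silencing_time, 10000)
  expect_equal(r2$perturbation_reach, 1)
})

test_that("the simulator equals the dense Laplacian oracle elementwise", {
  for (rep in 1:20) {
    net <- random_fixture_graph(5 + (rep %% 16), 0.3, seed = 500 + rep)
    A <- as.matrix(igraph::as_adjacency_matrix(net))
    k <- 1 / (max(rowSums(A)) + 1)
    cfg <- perturbation_config(E = 1000, D = 5, k = k)
    seed_node <- igraph::V(net)$name[1]
    st <- initialize_energy(net, seed_node, E = 1000)
    e <- unname(st$energy)
    for (s in 1:8) {
      st <- perturb_step(st, net, cfg)
      ph <- oracle_step(e, A, k, 5)
      e <- ph$after_dissipation
      expect_equal(unname(st$energy), e, tolerance = 1e-9)
    }
    res <- run_perturbation(net, seed_node, cfg)
    orc <- oracle_run(replace(numeric(nrow(A)), 1, 1000), A, k, 5)
    expect_identical(res$silencing_time, orc$silencing_time)
    expect_identical(res$perturbation_reach, as.integer(orc$reach))
  }
})

test_that("path-graph run agrees with the oracle at k = 1/3", {
  net <- path_graph(c("A", "B", "C"))
  cfg <- perturbation_config(E = 1000, D = 5, k = 1 / 3)
  res <- run_perturbation(net, "A", cfg)
  A <- as.matrix(igraph::as_adjacency_matrix(net))
  e0 <- ifelse(igraph::V(net)$name == "A", 1000, 0)
  orc <- oracle_run(e0, A, 1 / 3, 5)
  expect_equal(res$silencing_time, orc$silencing_time)
  expect_equal(res$perturbation_reach, as.integer(orc$reach))
})

test_that("flow conserves energy and dissipation is exactly accounted", {
  for (rep in 1:10) {
    net <- random_fixture_graph(12, 0.35, seed = 700 + rep)
    A <- as.matrix(igraph::as_adjacency_matrix(net))
    k <- 1 / (max(rowSums(A)) + 1)
    cfg <- perturbation_config(E = 1000, D = 5, k = k)
    st <- initialize_energy(net, igraph::V(net)$name[1], E = 1000)
    for (s in 1:30) {
      before <- st$energy
      flow_only <- before + k * (as.numeric(A %*% before) - rowSums(A) * before)
      st <- perturb_step(st, net, cfg)
      # flow sub-phase conserves total energy
      expect_equal(sum(flow_only), sum(before), tolerance = 1e-9)
      # dissipation removes exactly sum(min(energy, D)), never below zero
      expect_equal(sum(st$energy),
                   sum(flow_only) - sum(pmin(flow_only, 5)),
                   tolerance = 1e-9)
      expect_true(all(st$energy >= 0))
    }
  }
})

test_that("total energy decreases monotonically and silencing obeys E/theta", {
  for (rep in 1:6) {
    net <- random_fixture_graph(15, 0.25, seed = 900 + rep)
    cfg <- perturbation_config()
    res <- run_perturbation(net, igraph::V(net)$name[1], cfg,
                            trajectory = TRUE)
    expect_lte(res$silencing_time, cfg$E / cfg$theta)
    totals <- c(cfg$E, res$trajectory)
    expect_true(all(diff(totals) < 0))
    expect_false(res$terminated_by_cap)
  }
})

test_that("vertex-transitive graphs give identical results for every seed", {
  ids <- sprintf("c%d", 1:5)
  c5 <- interaction_network(ids, ids[c(2:5, 1)])
  prof <- silencing_profile(c5, cfg = perturbation_config())
  expect_equal(length(unique(prof$silencing_time)), 1)
  expect_equal(length(unique(prof$perturbation_reach)), 1)

  k4 <- random_fixture_graph(4, 1.1, seed = 1) # p > 1: complete graph
  prof4 <- silencing_profile(k4, cfg = perturbation_config())
  expect_equal(length(unique(prof4$silencing_time)), 1)
})

test_that("batched profile equals independent per-probe runs and repeats", {
  net <- generate_network(50, 2, rng_seed = 31)
  cfg <- perturbation_config()
  prof <- silencing_profile(net, cfg = cfg)
  again <- silencing_profile(net, cfg = cfg)
  expect_identical(prof, again)
  pick <- prof$probe[c(1, 10, 25, 50)]
  for (p in pick) {
    r <- run_perturbation(net, p, cfg)
    row <- prof[prof$probe == p, ]
    expect_equal(row$silencing_time, r$silencing_time)
    expect_equal(row$perturbation_reach, r$perturbation_reach)
  }
})

test_that("multi-target seed sets split the energy and run per set", {
  net <- generate_network(50, 2, rng_seed = 31)
  cfg <- perturbation_config()
  sets <- list(drugA = igraph::V(net)$name[1:2],
               drugB = igraph::V(net)$name[5])
  prof <- silencing_profile(net, cfg = cfg, seed_sets = sets)
  expect_identical(prof$probe, c("drugA", "drugB"))
  rA <- run_perturbation(net, sets$drugA, cfg)
  expect_equal(prof$silencing_time[1], rA$silencing_time)
  st <- initialize_energy(net, sets$drugA, E = cfg$E)
  expect_equal(unname(st$energy[sets$drugA]), c(500, 500))
  expect_error(silencing_profile(net, cfg = cfg,
                                 seed_sets = list(d = "nope")),
               "not in network")
})

test_that("the step cap is honoured and reported", {
  iso <- interaction_network(character(0), character(0), isolated = "A")
  cfg <- perturbation_config(E = 1000, D = 5)
  cfg$max_steps <- 50L # under the validated floor: forces the cap path
  r <- run_perturbation(iso, "A", cfg)
  expect_true(r$terminated_by_cap)
  expect_equal(r$silencing_time, 50)
})

test_that("seed degree anticorrelates with silencing time on scale-free nets", {
  net <- generate_network(500, 2, rng_seed = 77)
  prof <- silencing_profile(net, cfg = perturbation_config())
  deg <- igraph::degree(net)[prof$probe]
  rho <- cor(deg, prof$silencing_time, method = "spearman")
  expect_lt(rho, -0.3)
})
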