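test_that("pairing is a permutation and infection follows theta", {
  set.seed(14)
  pop <- random_population(200, 10)
  pr <- pair_and_infect(pop$hosts, pop$pathogens, theta = 1)
  expect_identical(sort(pr$pathogen), 1:200)   # each pathogen meets one host
  expect_true(all(pr$infected))
  pr0 <- pair_and_infect(pop$hosts, pop$pathogens, theta = 0)
  expect_false(any(pr0$infected))
  frac <- mean(replicate(30, mean(pair_and_infect(pop$hosts, pop$pathogens, 0.7)$infected)))
  expect_lt(abs(frac - 0.7), 4 * sqrt(0.7 * 0.3 / 6000))
  expect_error(pair_and_infect(pop$hosts, pop$pathogens[1:10, ], 1), "equal size")
})

test_that("host fitness is the exponential burden decay", {
  expect_identical(host_fitness(0, 0, 2, 1), 1)
  expect_equal(host_fitness(0.5, 0.2, 2, 1), exp(-1.2))
  expect_equal(host_fitness(c(0, 1), c(0, 1), 1, 1), c(1, exp(-2)))
  expect_error(host_fitness(-0.1, 0, 1, 1), "non-negative")
})

test_that("pathogen fitness is P_bar for infecting pathogens, else 0", {
  expect_identical(pathogen_fitness(0.8, TRUE), 0.8)
  expect_identical(pathogen_fitness(0.8, FALSE), 0)
  expect_identical(pathogen_fitness(0, TRUE), 0)  # fully cleared
})

test_that("parent selection is fitness-proportional", {
  set.seed(41)
  draws <- select_parents(rep(1, 4), 20000)
  expect_true(all(abs(tabulate(draws, 4) / 20000 - 0.25) < 0.02))
  draws2 <- select_parents(c(0.2, 0.8), 20000)
  expect_lt(abs(mean(draws2 == 2) - 0.8), 0.02)
  prs <- select_parents(c(1, 2, 3), 500, pairs = TRUE)
  expect_true(all(prs[, 1] != prs[, 2]))
  expect_error(select_parents(c(0, 0, 0), 5), "degenerate")
  expect_error(select_parents(c(0, 1, 0), 5, pairs = TRUE), "distinct")
})

test_that("a generation conserves population sizes and is reproducible", {
  cfg <- tiny_config(n = 40, generations = 1, seed = 5)
  set.seed(5); pop <- random_population(40, 10)
  set.seed(17); out1 <- step_generation(pop, cfg)
  set.seed(17); out2 <- step_generation(pop, cfg)
  expect_identical(out1, out2)
  expect_identical(dim(out1$state$hosts), dim(pop$hosts))
  expect_identical(dim(out1$state$pathogens), dim(pop$pathogens))
  expect_true(all(out1$state$hosts %in% 0:1))
  rec <- out1$record
  expect_equal(rec$frac_infected, 1)
  expect_true(all(abs(rec[paste0("mu_", edge_names())]) <= 1))
})

test_that("without mutation every offspring allele comes from the parents", {
  cfg <- tiny_config(n = 30, generations = 1, MH = 0, MP = 0, seed = 2)
  set.seed(2); pop <- random_population(30, 10)
  set.seed(3); out <- step_generation(pop, cfg)
  # hosts: per-site provenance (recombination only reshuffles parental bits)
  for (j in seq_len(ncol(pop$hosts))) {
    expect_true(all(out$state$hosts[, j] %in% pop$hosts[, j]))
  }
  # pathogens: asexual, so offspring rows are exact parental copies
  parent_rows <- apply(pop$pathogens, 1, paste, collapse = "")
  child_rows <- apply(out$state$pathogens, 1, paste, collapse = "")
  expect_true(all(child_rows %in% parent_rows))
})

test_that("both engines are deterministic and structurally consistent", {
  cfg <- tiny_config(n = 30, generations = 12, seed = 123)
  for (eng in c("cpp", "r")) {
    r1 <- run_simulation(cfg, engine = eng)
    r2 <- run_simulation(cfg, engine = eng)
    expect_identical(r1$records, r2$records)
    expect_identical(unclass(r1$hosts), unclass(r2$hosts))
    expect_identical(unclass(r1$pathogens), unclass(r2$pathogens))
    expect_identical(nrow(r1$records), 12L)
    expect_identical(dim(r1$hosts), c(30L, 150L))
    expect_identical(r1$consensus$generations, c(0L, 5L, 10L))
    expect_true(all(is.finite(r1$records$mean_host_fitness)))
  }
})

test_that("a zero-generation run returns the initial populations untouched", {
  cfg <- tiny_config(n = 20, generations = 0, seed = 9)
  set.seed(9); pop <- random_population(20, 10)
  r <- run_simulation(cfg)
  expect_identical(nrow(r$records), 0L)
  expect_identical(unclass(r$hosts), unclass(pop$hosts))
  expect_identical(nrow(r$omega), 0L)
})

test_that("theta = 0 reduces host evolution to neutral drift", {
  # no infections: every host fitness is 1, pathogens drift; per-site
  # consensus change over replicates is centred on zero
  rep_means <- vapply(1:20, function(r) {
    cfg <- tiny_config(n = 100, generations = 100, theta = 0, MH = 0.01,
                       seed = 100 + r)
    run <- run_simulation(cfg)
    expect_true(all(run$records$frac_infected == 0))
    expect_true(all(run$records$mean_host_fitness == 1))
    mean(run$consensus$hosts[nrow(run$consensus$hosts), ] -
           run$consensus$hosts[1, ])
  }, numeric(1))
  tstat <- mean(rep_means) / (sd(rep_means) / sqrt(length(rep_means)))
  expect_lt(abs(tstat), 4)
})

test_that("a pure response cost drives the immune response down", {
  cfg <- tiny_config(n = 200, generations = 400, alpha = 0, beta = 10,
                     seed = 77, MH = 0.004)
  r <- run_simulation(cfg)
  first <- mean(r$records$mean_I_bar[1:40])
  last <- mean(r$records$mean_I_bar[361:400])
  expect_lt(last, first)
})

test_that("pinning the regulator edges to zero ablates them cleanly", {
  cfg <- tiny_config(n = 60, generations = 60, seed = 31,
                     mu_overrides = c(R_U = 0, I_D = 0))
  r <- run_simulation(cfg)
  expect_true(all(r$records$mu_R_U == 0))
  expect_true(all(r$records$mu_I_D == 0))
  expect_true(all(is.finite(r$records$mu_A_R)))
})

test_that("replicate runs use distinct derived seeds and reproduce", {
  cfg <- tiny_config(n = 20, generations = 5)
  runs <- run_replicates(cfg, 2, master_seed = 50)
  runs2 <- run_replicates(cfg, 2, master_seed = 50)
  expect_identical(runs[[1]]$records, runs2[[1]]$records)
  expect_false(identical(runs[[1]]$records, runs[[2]]$records))
})
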