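#' Configuration of an evolutionary run
#'
#' Bundles the population-genetic parameters with the within-host dynamics
#' parameters. The defaults are the model's standard study conditions:
#' `n = 2000` hosts and pathogens, 20000 non-overlapping generations,
#' infection probability `theta = 1`, host mutation rate `MH = 0.001` with
#' pathogens mutating twice as fast (`MP = 2 * MH`), and consensus sampling
#' every 5 generations for the evolutionary-rate estimator.
#'
#' @param dynamics A [dynamics_params()] object (with `infected = TRUE`; the
#'   infection flag is decided per host per generation).
#' @param alpha Cost coefficient of infection in host fitness
#'   `exp(-(alpha * P_bar + beta * I_bar))`.
#' @param beta Cost coefficient of the immune response.
#' @param n Population size (constant across generations, same for hosts and
#'   pathogens).
#' @param generations Number of generations to simulate.
#' @param theta Per-generation probability that a host's random pathogen
#'   encounter results in infection, in `[0, 1]`.
#' @param MH Host per-offspring mutation probability.
#' @param MP Pathogen per-offspring mutation probability (default `2 * MH`;
#'   set to 0 to freeze the pathogen).
#' @param mu_overrides Named numeric vector of interaction coefficients fixed
#'   for the whole run (see [compute_interactions()]), or `NULL`.
#' @param L Sites per domain.
#' @param sample_interval Generations between consensus samples for the
#'   rate estimator.
#' @param saturation_threshold Neutral-domain divergence above which the
#'   focal consensus is reset (see [update_track()]).
#' @param seed Integer seed; a run is fully reproducible from
#'   `(config, seed)`.
#' @return A validated list of class `evolution_config`.
#' @export
evolution_config <- function(dynamics, alpha, beta,
                             n = 2000L, generations = 20000L, theta = 1,
                             MH = 0.001, MP = 2 * MH,
                             mu_overrides = NULL, L = 10L,
                             sample_interval = 5L, saturation_threshold = 0.5,
                             seed = NULL) {
  stopifnot(inherits(dynamics, "dynamics_params"))
  if (n < 2) stop("population size n must be at least 2")
  if (generations < 0) stop("generations must be non-negative")
  for (nm in c("theta", "MH", "MP")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0 || v > 1) stop(nm, " must be a probability in [0, 1]")
  }
  if (!is.finite(alpha) || alpha < 0) stop("alpha must be finite and >= 0")
  if (!is.finite(beta) || beta < 0) stop("beta must be finite and >= 0")
  if (sample_interval < 1) stop("sample_interval must be >= 1")
  structure(list(dynamics = dynamics, alpha = alpha, beta = beta,
                 n = as.integer(n), generations = as.integer(generations),
                 theta = theta, MH = MH, MP = MP,
                 mu_overrides = check_overrides(mu_overrides),
                 L = as.integer(L),
                 sample_interval = as.integer(sample_interval),
                 saturation_threshold = saturation_threshold,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "evolution_config")
}

#' Random host-pathogen pairing and infection draw
#'
#' Pathogens are randomly permuted against hosts (each pathogen meets exactly
#' one host), then each encounter is realized as an infection with
#' probability `theta`. Pathogens whose encounter is not realized do not
#' infect anyone that generation and will have fitness 0.
#'
#' @param hosts,pathogens Population matrices with equal row counts.
#' @param theta Infection probability in `[0, 1]`.
#' @return A data frame with columns `host` (1..n), `pathogen` (the permuted
#'   partner index) and `infected` (logical).
#' @export
pair_and_infect <- function(hosts, pathogens, theta) {
  n <- nrow(hosts)
  if (n != nrow(pathogens)) stop("host and pathogen populations must have equal size")
  perm <- sample.int(n)
  infected <- if (theta >= 1) rep(TRUE, n)
              else if (theta <= 0) rep(FALSE, n)
              else stats::runif(n) < theta
  data.frame(host = seq_len(n), pathogen = perm, infected = infected)
}

#' Host fitness from lifetime pathogen and immunity burden
#'
#' `F_H = exp(-(alpha * P_bar + beta * I_bar))`: fitness decays from 1
#' towards 0 as the lifetime-average pathogen load and immune-response level
#' increase (infection cost and energetic/immunopathology cost of response).
#' Uninfected hosts bypass this and get fitness exactly 1 -- the model assumes
#' no constitutive investment in immunity.
#'
#' @param P_bar,I_bar Lifetime averages in `[0, 1]` (vectorized).
#' @param alpha,beta Non-negative cost coefficients.
#' @return Fitness values in `(0, 1]`.
#' @export
host_fitness <- function(P_bar, I_bar, alpha, beta) {
  if (any(P_bar < 0) || any(I_bar < 0)) stop("P_bar and I_bar must be non-negative")
  exp(-(alpha * P_bar + beta * I_bar))
}

#' Pathogen fitness
#'
#' The lifetime-average concentration `P_bar` the pathogen reached in the
#' host it infected; pathogens that failed to infect a host have fitness 0.
#'
#' @param P_bar Lifetime average in `[0, 1]` (vectorized).
#' @param infected Logical; did this pathogen infect a host?
#' @return Fitness values in `[0, 1]`.
#' @export
pathogen_fitness <- function(P_bar, infected) {
  ifelse(infected, P_bar, 0)
}

#' Fitness-proportional parent sampling
#'
#' Multinomial sampling with replacement, probability proportional to
#' fitness. For sexual (host) reproduction each offspring draws two distinct
#' parents, both fitness-proportionally.
#'
#' @param fitnesses Non-negative fitness vector; at least one must be
#'   strictly positive.
#' @param k Number of offspring.
#' @param pairs If `TRUE`, return a `k x 2` matrix of distinct parent pairs;
#'   otherwise a length-`k` index vector.
#' @return Parent indices.
#' @export
select_parents <- function(fitnesses, k, pairs = FALSE) {
  if (all(fitnesses == 0)) {
    stop("degenerate population: every fitness is zero")
  }
  if (any(fitnesses < 0)) stop("fitnesses must be non-negative")
  first <- sample.int(length(fitnesses), k, replace = TRUE, prob = fitnesses)
  if (!pairs) return(first)
  if (sum(fitnesses > 0) < 2L) {
    stop("sexual reproduction needs two distinct viable parents, ",
         "but only one individual has positive fitness")
  }
  second <- sample.int(length(fitnesses), k, replace = TRUE, prob = fitnesses)
  for (i in which(second == first)) {
    tries <- 0L
    while (second[i] == first[i]) {
      second[i] <- sample.int(length(fitnesses), 1L, prob = fitnesses)
      tries <- tries + 1L
      if (tries > 10000L) stop("could not draw two distinct parents")
    }
  }
  cbind(parent1 = first, parent2 = second)
}

record_columns <- function() {
  c(paste0("mu_", edge_names()),
    "mean_host_fitness", "mean_pathogen_fitness", "frac_infected",
    "mean_P_bar", "mean_I_bar")
}

#' Advance a population state by one generation (reference implementation)
#'
#' The full generational pipeline in plain R: random pairing and infection,
#' per-pairing interaction coefficients, within-host integration for every
#' infected host, host and pathogen fitnesses, fitness-proportional
#' selection, sexual host reproduction with per-protein recombination,
#' asexual pathogen reproduction, and mutation of the offspring. Population
#' sizes are conserved. The compiled engine behind [run_simulation()] runs
#' the same pipeline at scale; this function is its behavioural reference
#' and is practical up to a few hundred individuals.
#'
#' In a generation with no realized infection (e.g. `theta = 0`) every
#' pathogen fitness is 0; pathogen parents are then drawn uniformly at
#' random, i.e. the pathogen population drifts neutrally.
#'
#' @param state List with population matrices `hosts` and `pathogens`.
#' @param config An [evolution_config()].
#' @return List with the new `state` and a one-row data frame `record`
#'   holding the population-mean coefficient per edge (host-internal edges
#'   averaged over all hosts; the two pathogen-facing edges averaged over
#'   realized pairings), mean fitnesses, the infected fraction, and the
#'   population means of `P_bar` and `I_bar`.
#' @export
step_generation <- function(state, config) {
  hosts <- state$hosts
  paths <- state$pathogens
  n <- nrow(hosts)
  L <- population_L(hosts)
  pairing <- pair_and_infect(hosts, paths, config$theta)

  mu_all <- matrix(NA_real_, n, length(edge_names()),
                   dimnames = list(NULL, edge_names()))
  for (i in seq_len(n)) {
    mu_all[i, ] <- compute_interactions(
      population_genotype(hosts, i),
      population_genotype(paths, pairing$pathogen[i]),
      config$mu_overrides
    )
  }

  P_bar <- numeric(n)
  I_bar <- numeric(n)
  inf <- which(pairing$infected)
  if (length(inf)) {
    res <- batch_integrate(mu_all[inf, , drop = FALSE], config$dynamics,
                           trajectories = FALSE)
    P_bar[inf] <- res$P_bar
    I_bar[inf] <- res$I_bar
  }
  fit_h <- ifelse(pairing$infected,
                  host_fitness(P_bar, I_bar, config$alpha, config$beta), 1)
  fit_p <- numeric(n)
  fit_p[pairing$pathogen[inf]] <- P_bar[inf]

  internal <- !(edge_names() %in% c("R_P", "P_I"))
  rec <- stats::setNames(numeric(length(record_columns())), record_columns())
  rec[paste0("mu_", edge_names()[internal])] <- colMeans(mu_all[, internal, drop = FALSE])
  rec[c("mu_R_P", "mu_P_I")] <- if (length(inf)) {
    colMeans(mu_all[inf, c("R_P", "P_I"), drop = FALSE])
  } else c(NA_real_, NA_real_)
  rec["mean_host_fitness"] <- mean(fit_h)
  rec["mean_pathogen_fitness"] <- mean(fit_p)
  rec["frac_infected"] <- length(inf) / n
  rec["mean_P_bar"] <- mean(P_bar)
  rec["mean_I_bar"] <- mean(I_bar)

  # host reproduction: sexual, two distinct fitness-proportional parents
  parents <- select_parents(fit_h, n, pairs = TRUE)
  new_hosts <- matrix(0L, n, ncol(hosts))
  for (i in seq_len(n)) {
    off <- recombine_host(population_genotype(hosts, parents[i, 1L]),
                          population_genotype(hosts, parents[i, 2L]))
    off <- mutate_genotype(off, config$MH)
    new_hosts[i, ] <- unclass(off)
  }

  # pathogen reproduction: asexual copies; uniform draw when nothing infected
  p_parents <- if (all(fit_p == 0)) sample.int(n, n, replace = TRUE)
               else select_parents(fit_p, n)
  new_paths <- paths[p_parents, , drop = FALSE]
  for (i in seq_len(n)) {
    off <- mutate_genotype(pathogen_genotype(new_paths[i, ], L), config$MP)
    new_paths[i, ] <- unclass(off)
  }

  list(state = list(hosts = new_population(new_hosts, L, "host_population"),
                    pathogens = new_population(new_paths, L, "pathogen_population")),
       record = as.data.frame(as.list(rec)))
}

#' Run a full evolutionary simulation
#'
#' Executes the generational loop from random (or supplied) initial
#' populations, recording the population-mean interaction coefficient per
#' edge every generation and the population consensus every
#' `sample_interval` generations, from which the per-protein, per-domain
#' ka/ks (omega) stream is computed (see [omega_stream()]).
#'
#' `engine = "cpp"` (default) runs the whole loop in compiled code and is the
#' production path; `engine = "r"` loops [step_generation()] and is intended
#' for small cross-validation runs. Both are deterministic given
#' `config$seed` (each consumes the R random number stream in its own order,
#' so the two engines are reproducible individually, not bitwise-identical
#' to each other).
#'
#' @param config An [evolution_config()].
#' @param init Optional list with `hosts`/`pathogens` population matrices to
#'   start from (defaults to [random_population()]).
#' @param engine `"cpp"` or `"r"`.
#' @return An object of class `nflevo_run`: list with `records` (one row per
#'   generation), `omega` (the rate-estimator stream, see [omega_stream()]),
#'   `consensus` (host/pathogen consensus samples and the generations at
#'   which they were taken), final `hosts` and `pathogens`, and `config`.
#' @export
run_simulation <- function(config, init = NULL, engine = c("cpp", "r")) {
  stopifnot(inherits(config, "evolution_config"))
  engine <- match.arg(engine)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(init)) init <- random_population(config$n, config$L)
  hosts <- init$hosts
  paths <- init$pathogens
  if (nrow(hosts) != config$n) stop("initial population size differs from config$n")

  dyn <- config$dynamics
  ov <- rep(NA_real_, length(edge_names()))
  names(ov) <- edge_names()
  ov[names(config$mu_overrides)] <- config$mu_overrides

  if (engine == "cpp") {
    res <- cpp_run_engine(hosts, paths, config$L, config$generations,
                          config$theta, config$alpha, config$beta,
                          config$MH, config$MP,
                          unname(dyn$phi), dyn$pi, dyn$P0, dyn$steps, dyn$dt,
                          dyn$force_inhibitory_IP, unname(ov),
                          config$sample_interval)
    records <- res$records
    colnames(records) <- record_columns()
    host_cons <- res$host_consensus
    path_cons <- res$path_consensus
    sample_gens <- res$sample_generations
    hosts <- new_population(res$hosts, config$L, "host_population")
    paths <- new_population(res$pathogens, config$L, "pathogen_population")
  } else {
    records <- matrix(NA_real_, config$generations, length(record_columns()),
                      dimnames = list(NULL, record_columns()))
    n_samples <- config$generations %/% config$sample_interval + 1L
    host_cons <- matrix(NA_real_, n_samples, ncol(hosts))
    path_cons <- matrix(NA_real_, n_samples, ncol(paths))
    sample_gens <- integer(n_samples)
    host_cons[1L, ] <- population_consensus(hosts)
    path_cons[1L, ] <- population_consensus(paths)
    s <- 1L
    state <- list(hosts = hosts, pathogens = paths)
    for (g in seq_len(config$generations)) {
      out <- step_generation(state, config)
      state <- out$state
      records[g, ] <- as.numeric(out$record[1L, ])
      if (g %% config$sample_interval == 0L) {
        s <- s + 1L
        host_cons[s, ] <- population_consensus(state$hosts)
        path_cons[s, ] <- population_consensus(state$pathogens)
        sample_gens[s] <- g
      }
    }
    host_cons <- host_cons[seq_len(s), , drop = FALSE]
    path_cons <- path_cons[seq_len(s), , drop = FALSE]
    sample_gens <- sample_gens[seq_len(s)]
    hosts <- state$hosts
    paths <- state$pathogens
  }

  records <- as.data.frame(records)
  if (config$generations > 0L) records$generation <- seq_len(config$generations)
  else records$generation <- integer(0)
  records <- records[, c("generation", setdiff(names(records), "generation"))]

  omega <- omega_stream(host_cons, sample_gens, config$L,
                        saturation_threshold = config$saturation_threshold)

  structure(list(records = records, omega = omega,
                 consensus = list(hosts = host_cons, pathogens = path_cons,
                                  generations = sample_gens),
                 hosts = hosts, pathogens = paths, config = config),
            class = "nflevo_run")
}

#' Run independent replicate simulations
#'
#' Replicate `r` runs with seed `master_seed + 7919 * r` (a fixed
#' counter-based derivation), so each replicate is reproducible in isolation.
#'
#' @param config An [evolution_config()]; its own `seed` field is ignored.
#' @param replicates Number of replicates.
#' @param master_seed Integer master seed.
#' @param engine Passed to [run_simulation()].
#' @return List of `nflevo_run` objects.
#' @export
run_replicates <- function(config, replicates, master_seed, engine = "cpp") {
  lapply(seq_len(replicates), function(r) {
    cfg <- config
    cfg$seed <- as.integer(master_seed + 7919 * r)
    run_simulation(cfg, engine = engine)
  })
}

#' @export
print.nflevo_run <- function(x, ...) {
  cat("<nflevo_run> ", x$config$generations, " generations, n = ",
      x$config$n, "\n", sep = "")
  if (nrow(x$records)) {
    w <- max(1L, floor(0.1 * nrow(x$records)))
    tail_mu <- colMeans(x$records[(nrow(x$records) - w + 1L):nrow(x$records),
                                  paste0("mu_", edge_names()), drop = FALSE],
                        na.rm = TRUE)
    cat("final-window mean interaction coefficients:\n")
    print(round(tail_mu, 3))
  }
  invisible(x)
}
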