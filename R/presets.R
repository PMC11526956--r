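#' Named scenario presets for the model's study conditions
#'
#' Bundles the model's standard parameter regimes as ready-made
#' configurations:
#' \describe{
#'   \item{no_degradation}{Baseline: `alpha = 2`, `beta = 1`, no protein
#'     degradation (`phi = 0`), `theta = 1`. The downstream NFL evolves; the
#'     upstream one does not.}
#'   \item{high_response_cost}{As `no_degradation` with `beta = 2`. Produces
#'     polymorphic outcomes (A or D as the downstream NFL).}
#'   \item{degradation_fixed_input}{Degradation plus fixed receptor input:
#'     `phi = 0.15` for all host proteins, receptor-pathogen coefficient
#'     pinned at 1 (no receptor-pathogen coevolution).}
#'   \item{stable_receptor}{As `degradation_fixed_input` but the receptor
#'     does not degrade (`phi_R = 0`). The upstream NFL evolves most
#'     readily here.}
#'   \item{partial_infection}{As `stable_receptor` with infection
#'     probability `theta = 0.7` (population size 2000 by default; pass
#'     `n = 5000` for the large-population variant).}
#'   \item{stable_receptor_high_cost}{As `stable_receptor` with `beta = 2`.}
#' }
#'
#' The pathogen replication rate `pi` has no preset value and must always be
#' supplied.
#'
#' @param name Preset name.
#' @param pi Pathogen replication rate (required, no default).
#' @param n,generations,seed Optional overrides of the preset's population
#'   size, generation count and seed.
#' @param scale Convenience multiplier applied to both `n` and `generations`
#'   for desk-scale runs (e.g. `scale = 0.25`).
#' @param ... Further fields passed to [evolution_config()] (e.g. `MP = 0`).
#' @return An [evolution_config()].
#' @examples
#' cfg <- scenario_preset("no_degradation", pi = 0.2, n = 100, generations = 50)
#' @export
scenario_preset <- function(name, pi, n = NULL, generations = NULL,
                            seed = NULL, scale = 1, ...) {
  specs <- list(
    no_degradation            = list(alpha = 2, beta = 1, phi = 0,    phi_R = 0,    theta = 1,   override = FALSE),
    high_response_cost        = list(alpha = 2, beta = 2, phi = 0,    phi_R = 0,    theta = 1,   override = FALSE),
    degradation_fixed_input   = list(alpha = 2, beta = 1, phi = 0.15, phi_R = 0.15, theta = 1,   override = TRUE),
    stable_receptor           = list(alpha = 2, beta = 1, phi = 0.15, phi_R = 0,    theta = 1,   override = TRUE),
    partial_infection         = list(alpha = 2, beta = 1, phi = 0.15, phi_R = 0,    theta = 0.7, override = TRUE),
    stable_receptor_high_cost = list(alpha = 2, beta = 2, phi = 0.15, phi_R = 0,    theta = 1,   override = TRUE)
  )
  if (!name %in% names(specs)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(specs), collapse = ", "))
  }
  s <- specs[[name]]
  phi <- stats::setNames(c(s$phi_R, rep(s$phi, 4L)), host_proteins())
  dyn <- dynamics_params(phi = phi, pi = pi)
  n <- if (is.null(n)) 2000L else as.integer(n)
  generations <- if (is.null(generations)) 20000L else as.integer(generations)
  if (scale != 1) {
    n <- max(2L, as.integer(round(n * scale)))
    generations <- as.integer(round(generations * scale))
  }
  evolution_config(
    dynamics = dyn, alpha = s$alpha, beta = s$beta,
    n = n, generations = generations, theta = s$theta,
    mu_overrides = if (s$override) c(R_P = 1) else NULL,
    seed = seed, ...
  )
}

#' Load a run configuration from a JSON file
#'
#' The file holds the fields of [evolution_config()] plus a nested
#' `dynamics` section with the fields of [dynamics_params()]. Unknown keys
#' are rejected; `pi` must be present (it has no default).
#'
#' @param path Path to a JSON configuration file.
#' @return An [evolution_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$dynamics)) stop("config must contain a `dynamics` section")
  dyn_known <- c("phi", "pi", "P0", "T", "dt", "force_inhibitory_IP")
  top_known <- c("dynamics", "alpha", "beta", "n", "generations", "theta",
                 "MH", "MP", "mu_overrides", "L", "sample_interval",
                 "saturation_threshold", "seed")
  bad <- c(setdiff(names(raw), top_known), setdiff(names(raw$dynamics), dyn_known))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (is.null(raw$dynamics$pi)) {
    stop("the pathogen replication rate `pi` must be set in the `dynamics` ",
         "section; it has no default")
  }
  dynargs <- raw$dynamics
  if (!is.null(dynargs$phi)) dynargs$phi <- unlist(dynargs$phi)
  dyn <- do.call(dynamics_params, dynargs)
  args <- raw[setdiff(names(raw), "dynamics")]
  if (!is.null(args$mu_overrides)) args$mu_overrides <- unlist(args$mu_overrides)
  do.call(evolution_config, c(list(dynamics = dyn), args))
}

#' Hand-crafted genotype fixtures
#'
#' Deterministic or seeded genotype pairs with known interaction geometry,
#' for tests and examples:
#' \describe{
#'   \item{aligned}{Every sender matches every receiver: all coefficients 1.}
#'   \item{anti_aligned}{Every sender is the complement of every receiver:
#'     all coefficients -1.}
#'   \item{near_threshold}{Hamming distance `L/2 + offset` on every edge
#'     (`offset = 0` gives coefficient exactly 0); requires even `L`.}
#'   \item{random}{Every bit i.i.d. Bernoulli(0.5).}
#' }
#'
#' @param kind Fixture kind.
#' @param L Sites per domain (even for `near_threshold`).
#' @param offset Hamming offset from `L/2` for `near_threshold`
#'   (-1, 0 or 1).
#' @return List with elements `host` and `pathogen`.
#' @export
make_fixture <- function(kind = c("aligned", "anti_aligned", "random",
                                  "near_threshold"),
                         L = 10L, offset = 0L) {
  kind <- match.arg(kind)
  L <- as.integer(L)
  zeros_h <- integer(15L * L)
  zeros_p <- integer(3L * L)
  set_domains <- function(bits, proteins, domain, value_fn) {
    for (p in proteins) {
      idx <- domain_cols(domain = domain, protein = p, L = L,
                         proteins = if (identical(proteins, "P")) "P" else host_proteins())
      bits[idx] <- value_fn(L)
    }
    bits
  }
  switch(kind,
    aligned = list(host = host_genotype(zeros_h, L),
                   pathogen = pathogen_genotype(zeros_p, L)),
    anti_aligned = {
      hb <- set_domains(zeros_h, host_proteins(), "sender", function(L) rep(1L, L))
      pb <- set_domains(zeros_p, "P", "sender", function(L) rep(1L, L))
      list(host = host_genotype(hb, L), pathogen = pathogen_genotype(pb, L))
    },
    near_threshold = {
      if (L %% 2L != 0L) stop("near_threshold requires an even L")
      h <- L %/% 2L + as.integer(offset)
      if (h < 0L || h > L) stop("offset places the Hamming distance outside 0..L")
      one_part <- function(L) c(rep(1L, h), rep(0L, L - h))
      hb <- set_domains(zeros_h, host_proteins(), "sender", one_part)
      pb <- set_domains(zeros_p, "P", "sender", one_part)
      list(host = host_genotype(hb, L), pathogen = pathogen_genotype(pb, L))
    },
    random = list(
      host = host_genotype(sample(0:1, 15L * L, replace = TRUE), L),
      pathogen = pathogen_genotype(sample(0:1, 3L * L, replace = TRUE), L)
    )
  )
}
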