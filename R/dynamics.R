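#' Parameters of the within-host signaling dynamics
#'
#' The within-host model tracks concentrations of the pathogen `P` and the
#' five host proteins over the host lifetime `T`. Host proteins degrade at
#' rate `phi` (per protein); the pathogen replicates logistically at rate `pi`
#' and does not degrade spontaneously. All concentrations live in `[0, 1]`.
#'
#' `pi` has no default: it must be chosen explicitly for every run.
#'
#' @param phi Degradation rate(s) of the host proteins: a single non-negative
#'   number applied to all five, or a named vector over `R, A, I, U, D`.
#' @param pi Pathogen logistic replication rate (>= 0). Required.
#' @param P0 Initial pathogen concentration in an infected host, in `[0, 1]`.
#' @param T Host lifetime (default 1000 time units).
#' @param dt Forward-Euler step (default 1); `T / dt` must be a whole number
#'   of steps.
#' @param infected Logical; an uninfected host has the identically zero
#'   trajectory (no constitutive investment in immunity).
#' @param force_inhibitory_IP If `TRUE` (default), the immunity-on-pathogen
#'   coefficient enters the pathogen equation as `|mu[P,I]|`: the
#'   immunity-pathogen interaction is constrained to act inhibitory, with the
#'   evolved Hamming matching setting only its strength. This is required for
#'   immunity to be selectable at all: under the signed alternative
#'   (`FALSE`, the equation read literally) the faster-mutating pathogen wins
#'   the matching race, pins the coefficient near zero and immunity becomes
#'   pure cost, so no functional pathway can evolve.
#' @return A validated list of class `dynamics_params`.
#' @export
dynamics_params <- function(phi, pi, P0 = 1, T = 1000, dt = 1,
                            infected = TRUE, force_inhibitory_IP = TRUE) {
  if (missing(pi) || is.null(pi)) {
    stop("the pathogen replication rate `pi` must be set explicitly; ",
         "it has no default")
  }
  phi <- expand_phi(phi)
  if (any(!is.finite(phi)) || any(phi < 0)) stop("phi must be finite and >= 0")
  if (!is.finite(pi) || pi < 0) stop("pi must be finite and >= 0")
  if (!is.finite(P0) || P0 < 0 || P0 > 1) stop("P0 must lie in [0, 1]")
  if (!is.finite(T) || T <= 0 || !is.finite(dt) || dt <= 0) {
    stop("T and dt must be positive")
  }
  steps <- T / dt
  if (abs(steps - round(steps)) > 1e-9) stop("T / dt must be a whole number of steps")
  structure(list(phi = phi, pi = pi, P0 = P0, T = T, dt = dt,
                 steps = as.integer(round(steps)),
                 infected = isTRUE(infected),
                 force_inhibitory_IP = isTRUE(force_inhibitory_IP)),
            class = "dynamics_params")
}

expand_phi <- function(phi) {
  prot <- host_proteins()
  if (length(phi) == 1L && is.null(names(phi))) {
    phi <- stats::setNames(rep(as.numeric(phi), 5L), prot)
  } else {
    if (is.null(names(phi)) || !setequal(names(phi), prot)) {
      stop("phi must be a single rate or a named vector over R, A, I, U, D")
    }
    phi <- as.numeric(phi[prot])
    names(phi) <- prot
  }
  phi
}

# Canonical species order of the state vector.
species_names <- function() c("P", "R", "A", "I", "U", "D")

#' Time derivative of the within-host state
#'
#' Pathogen: `dP/dt = -mu[P,I] * I * P + pi * P * (1 - P)` (clearance by
#' immunity plus logistic replication). Each host protein `i`:
#' `dyi/dt = -phi_i * yi + sum over incoming edges (i, j) of a saturating
#' interaction term`: `mu * yj * (1 - yi)` when `mu > 0` (activation
#' saturates as the target fills up) and `mu * yj * yi` when `mu < 0`
#' (inhibition removes what is there). The receptor receives input from both
#' the pathogen and the upstream regulator; immunity from both the activator
#' and the downstream regulator; contributions are summed.
#'
#' @param y Named numeric state vector over `P, R, A, I, U, D`, each in
#'   `[0, 1]`.
#' @param mu Named coefficient vector over all topology edges (see
#'   [compute_interactions()]).
#' @param params A [dynamics_params()] object.
#' @return Named derivative vector in the same species order.
#' @export
signaling_derivative <- function(y, mu, params) {
  sp <- species_names()
  y <- y[sp]
  mu_PI <- if (params$force_inhibitory_IP) abs(mu[["P_I"]]) else mu[["P_I"]]
  d <- numeric(6L)
  names(d) <- sp
  d[["P"]] <- -mu_PI * y[["I"]] * y[["P"]] + params$pi * y[["P"]] * (1 - y[["P"]])
  topo <- signaling_topology()
  for (p in host_proteins()) {
    acc <- -params$phi[[p]] * y[[p]]
    for (k in which(topo$target == p)) {
      m <- mu[[topo$name[k]]]
      yj <- y[[topo$source[k]]]
      if (m > 0) acc <- acc + m * yj * (1 - y[[p]])
      else if (m < 0) acc <- acc + m * yj * y[[p]]
    }
    d[[p]] <- acc
  }
  d
}

#' Integrate the within-host dynamics over one host lifetime
#'
#' Forward-Euler integration from `y(0) = (P0, 0, 0, 0, 0, 0)` (all host
#' proteins start at zero; the pathogen starts at `P0` if the host is
#' infected, else the trajectory is identically zero). After every step each
#' concentration is clamped to `[0, 1]`: the saturating interaction terms
#' bound growth intrinsically, clamping removes Euler overshoot.
#'
#' The time averages are `P_bar = dt * sum(P over the stored grid,
#' including t = 0) / T` and likewise `I_bar`; at the default `dt = 1` this is
#' exactly the lifetime sum divided by `T`.
#'
#' This is the plain-R reference integrator; [batch_integrate()] is the
#' compiled population-scale equivalent and is checked against this function.
#'
#' @param mu Named coefficient vector over all topology edges.
#' @param params A [dynamics_params()] object.
#' @return A list of class `state_trajectory` with elements `times`, `y`
#'   (matrix, one row per stored time, columns `P, R, A, I, U, D`), `P_bar`
#'   and `I_bar`.
#' @export
integrate_lifetime <- function(mu, params) {
  stopifnot(inherits(params, "dynamics_params"))
  sp <- species_names()
  steps <- params$steps
  Y <- matrix(0, nrow = steps + 1L, ncol = 6L, dimnames = list(NULL, sp))
  times <- seq(0, params$T, by = params$dt)
  if (!params$infected) {
    return(structure(list(times = times, y = Y, P_bar = 0, I_bar = 0),
                     class = "state_trajectory"))
  }
  y <- c(P = params$P0, R = 0, A = 0, I = 0, U = 0, D = 0)
  Y[1L, ] <- y
  for (s in seq_len(steps)) {
    y <- y + params$dt * signaling_derivative(y, mu, params)
    y <- pmin(pmax(y, 0), 1)
    if (any(!is.finite(y))) stop("non-finite state at step ", s)
    Y[s + 1L, ] <- y
  }
  structure(list(times = times, y = Y,
                 P_bar = params$dt * sum(Y[, "P"]) / params$T,
                 I_bar = params$dt * sum(Y[, "I"]) / params$T),
            class = "state_trajectory")
}

#' Integrate many individuals at once (compiled)
#'
#' Runs the same forward-Euler scheme as [integrate_lifetime()] for a whole
#' set of interaction states in compiled code. Results agree with mapping the
#' scalar integrator over the list to within floating-point noise (the test
#' suite requires 1e-12 per state per step).
#'
#' @param mu_list A list of named coefficient vectors (one per individual) or
#'   a numeric matrix with one row per individual and one column per topology
#'   edge in canonical order.
#' @param params A [dynamics_params()] object, shared across individuals.
#' @param trajectories If `TRUE` (default), full trajectories are stored and
#'   returned; if `FALSE`, only the time averages (much lighter at
#'   population scale).
#' @return A list with numeric vectors `P_bar` and `I_bar`, and, when
#'   `trajectories = TRUE`, a list `trajectories` of `state_trajectory`
#'   objects.
#' @export
batch_integrate <- function(mu_list, params, trajectories = TRUE) {
  stopifnot(inherits(params, "dynamics_params"))
  M <- as_mu_matrix(mu_list)
  if (nrow(M) == 0L) stop("batch_integrate needs at least one individual")
  res <- cpp_integrate_batch(M, unname(params$phi), params$pi, params$P0,
                             params$steps, params$dt, params$infected,
                             params$force_inhibitory_IP, isTRUE(trajectories))
  out <- list(P_bar = res$P_bar, I_bar = res$I_bar)
  if (isTRUE(trajectories)) {
    times <- seq(0, params$T, by = params$dt)
    out$trajectories <- lapply(seq_len(nrow(M)), function(i) {
      Y <- res$trajectories[[i]]
      colnames(Y) <- species_names()
      structure(list(times = times, y = Y,
                     P_bar = res$P_bar[i], I_bar = res$I_bar[i]),
                class = "state_trajectory")
    })
  }
  out
}

as_mu_matrix <- function(mu_list) {
  en <- edge_names()
  if (is.list(mu_list) && length(mu_list) == 0L) {
    return(matrix(numeric(0), 0L, length(en)))
  }
  if (is.matrix(mu_list)) {
    if (ncol(mu_list) != length(en)) stop("mu matrix needs one column per edge")
    M <- mu_list
    if (!is.null(colnames(M))) M <- M[, en, drop = FALSE]
  } else {
    if (!is.list(mu_list)) mu_list <- list(mu_list)
    M <- do.call(rbind, lapply(mu_list, function(m) m[en]))
  }
  storage.mode(M) <- "double"
  unname(M)
}

#' Export a trajectory as tab-separated text
#'
#' @param trajectory A `state_trajectory`.
#' @param path Output file.
#' @param thin Keep every `thin`-th stored time point (default 1 = all).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, thin = 1L) {
  keep <- seq(1L, length(trajectory$times), by = as.integer(thin))
  df <- data.frame(time = trajectory$times[keep], trajectory$y[keep, , drop = FALSE])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
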