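#' Classify one interaction trajectory
#'
#' An interaction is considered evolved when its population-mean coefficient
#' stabilizes away from zero; "fluctuating around 0" means not evolved. The
#' deterministic rule used here: take the mean of the final
#' `window_fraction` of the trajectory and call the edge `activatory` if the
#' mean exceeds `threshold`, `inhibitory` if it is below `-threshold`, else
#' `not_evolved`.
#'
#' The two pathogen-facing edges oscillate under host-pathogen coevolution
#' rather than stabilizing; see [classify_run()], which reports their window
#' amplitude and labels them `coevolving` instead of `not_evolved` when the
#' amplitude is large.
#'
#' @param mu_trajectory Numeric time series of population-mean coefficients
#'   (at least 10 points; `NA`s are dropped).
#' @param window_fraction Fraction of the trajectory tail to average
#'   (default 0.1).
#' @param threshold Magnitude cutoff (default 0.25).
#' @return `"activatory"`, `"inhibitory"` or `"not_evolved"`.
#' @export
call_edge <- function(mu_trajectory, window_fraction = 0.1, threshold = 0.25) {
  if (window_fraction <= 0 || window_fraction > 1) {
    stop("window_fraction must be in (0, 1]")
  }
  if (threshold <= 0) stop("threshold must be positive")
  n <- length(mu_trajectory)
  if (n < 10L) stop("trajectory too short to classify (need >= 10 samples)")
  w <- max(1L, floor(window_fraction * n))
  m <- mean(mu_trajectory[(n - w + 1L):n], na.rm = TRUE)
  if (is.nan(m)) return("not_evolved")
  if (m > threshold) "activatory"
  else if (m < -threshold) "inhibitory"
  else "not_evolved"
}

#' Call the evolved signaling architecture of a finished run
#'
#' Applies [call_edge()] to the population-mean trajectory of every topology
#' edge and derives the architecture flags:
#' \describe{
#'   \item{functional_pathway}{R activates A and A activates I.}
#'   \item{downstream_NFL_D}{A activates D and D inhibits I: the downstream
#'     regulator evolved as a negative feedback loop (three signaling steps
#'     to downregulate immunity).}
#'   \item{downstream_NFL_A}{D activates I while A inhibits I: the activator
#'     itself evolved as the downstream NFL (two steps to downregulation);
#'     mutually exclusive with `downstream_NFL_D` by construction.}
#'   \item{upstream_NFL}{A activates U and U inhibits R: the upstream
#'     regulator evolved as a negative feedback loop.}
#'   \item{downstream_inhibition, upstream_inhibition}{The model's defining
#'     criterion for an evolved NFL -- the inhibitory edge alone
#'     (`mu[I,D] < 0`, resp. `mu[R,U] < 0`, beyond the threshold). The
#'     two-edge flags above additionally demand the activation leg of the
#'     loop; at `L = 10` that leg often fixes at the lattice value 0.2
#'     (any positive drive saturates a non-degrading regulator, so selection
#'     beyond weak activation is weak), just below the default 0.25
#'     threshold, so the single-edge criterion is the more faithful count of
#'     evolved feedback.}
#' }
#'
#' The pathogen-facing edges (`R_P`, `P_I`) oscillate under coevolution; for
#' them the window mean and amplitude (max - min over the window) are both
#' reported, and a large-amplitude edge whose mean is inside the threshold is
#' labelled `coevolving` rather than `not_evolved`.
#'
#' @param records A run's `records` data frame (from [run_simulation()]), or
#'   anything with `mu_<edge>` columns.
#' @param window_fraction,threshold Passed to [call_edge()].
#' @param amplitude_threshold Window amplitude above which a pathogen-facing
#'   edge counts as coevolving (default 0.5).
#' @return An object of class `architecture_call`: list with `edges` (named
#'   character vector of per-edge calls), `flags`, `steps_to_inhibition`
#'   (2, 3 or `NA`), `label` (a compact architecture name), `window_stats`
#'   (per-edge window mean and amplitude), `window` and `threshold`.
#' @export
classify_run <- function(records, window_fraction = 0.1, threshold = 0.25,
                         amplitude_threshold = 0.5) {
  en <- edge_names()
  cols <- paste0("mu_", en)
  if (!all(cols %in% names(records))) {
    stop("records must contain the per-edge mean columns ",
         paste(setdiff(cols, names(records)), collapse = ", "))
  }
  n <- nrow(records)
  w <- max(1L, floor(window_fraction * n))
  win <- (n - w + 1L):n
  calls <- character(length(en))
  names(calls) <- en
  stats <- data.frame(edge = en, window_mean = NA_real_,
                      window_amplitude = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(en)) {
    traj <- records[[cols[k]]]
    calls[k] <- call_edge(traj, window_fraction, threshold)
    tail_vals <- traj[win]
    stats$window_mean[k] <- mean(tail_vals, na.rm = TRUE)
    stats$window_amplitude[k] <- if (all(is.na(tail_vals))) NA_real_
      else diff(range(tail_vals, na.rm = TRUE))
    if (en[k] %in% c("R_P", "P_I") && calls[k] == "not_evolved" &&
        isTRUE(stats$window_amplitude[k] > amplitude_threshold)) {
      calls[k] <- "coevolving"
    }
  }
  flags <- architecture_flags(calls)
  structure(c(list(edges = calls), flags,
              list(window_stats = stats,
                   window = c(from = win[1L], to = win[length(win)]),
                   threshold = threshold)),
            class = "architecture_call")
}

# Derived flags are pure functions of the per-edge calls.
architecture_flags <- function(calls) {
  act <- function(e) identical(unname(calls[e]), "activatory")
  inh <- function(e) identical(unname(calls[e]), "inhibitory")
  flags <- list(
    functional_pathway = act("A_R") && act("I_A"),
    downstream_NFL_D = act("D_A") && inh("I_D"),
    downstream_NFL_A = act("I_D") && inh("I_A"),
    upstream_NFL = act("U_A") && inh("R_U"),
    downstream_inhibition = inh("I_D"),
    upstream_inhibition = inh("R_U")
  )
  flags$steps_to_inhibition <-
    if (flags$downstream_NFL_A) 2L else if (flags$downstream_NFL_D) 3L else NA_integer_
  flags$label <-
    if (!act("A_R")) "non_functional"   # signal never reaches the pathway
    else if (flags$downstream_NFL_A) {
      if (flags$upstream_NFL) "A_NFL_plus_upstream" else "A_as_downstream_NFL"
    } else if (flags$downstream_NFL_D) {
      if (flags$upstream_NFL) "U_and_D_NFL" else "D_as_downstream_NFL"
    } else "functional_no_NFL"
  flags
}

#' Tabulate architecture calls across replicates
#'
#' @param calls A list of `architecture_call` objects.
#' @return A list with `flag_counts` (how many replicates set each derived
#'   flag), `labels` (a table of architecture labels) and `n` (number of
#'   replicates).
#' @export
tabulate_replicates <- function(calls) {
  if (!length(calls)) stop("at least one architecture call is required")
  flags <- c("functional_pathway", "downstream_NFL_D", "downstream_NFL_A",
             "upstream_NFL", "downstream_inhibition", "upstream_inhibition")
  counts <- vapply(flags, function(f) {
    sum(vapply(calls, function(cl) isTRUE(cl[[f]]), logical(1)))
  }, integer(1))
  labels <- table(vapply(calls, `[[`, character(1), "label"))
  list(flag_counts = counts, labels = labels, n = length(calls))
}

#' Write an architecture call as JSON
#'
#' @param call An `architecture_call`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_architecture <- function(call, path) {
  obj <- list(edges = as.list(call$edges),
              flags = list(functional_pathway = call$functional_pathway,
                           downstream_NFL_D = call$downstream_NFL_D,
                           downstream_NFL_A = call$downstream_NFL_A,
                           upstream_NFL = call$upstream_NFL,
                           downstream_inhibition = call$downstream_inhibition,
                           upstream_inhibition = call$upstream_inhibition),
              steps_to_inhibition = call$steps_to_inhibition,
              label = call$label,
              window = as.list(call$window),
              threshold = call$threshold,
              window_stats = call$window_stats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.architecture_call <- function(x, ...) {
  cat("<architecture_call> ", x$label, "\n", sep = "")
  cat("edges: ", paste(names(x$edges), x$edges, sep = "=", collapse = ", "),
      "\n", sep = "")
  cat("functional_pathway=", x$functional_pathway,
      " downstream_NFL_D=", x$downstream_NFL_D,
      " downstream_NFL_A=", x$downstream_NFL_A,
      " upstream_NFL=", x$upstream_NFL, "\n", sep = "")
  invisible(x)
}
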