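#' Per-site divergence between two consensus sequences
#'
#' For focal consensus `FO` and temporal consensus `TE` (per-site frequencies
#' of 1s), the divergence is the per-site mean of
#' `FO * (1 - TE) + TE * (1 - FO)`: the first term is the expected proportion
#' of 1-to-0 changes, the second of 0-to-1 changes. Applied to the neutral
#' domain this is `ks`, the neutral rate of change; applied to a sender or
#' receiver domain it is `ka`, and `omega = ka / ks` measures selection
#' (below 1 purifying, near 1 neutral, above 1 positive).
#'
#' The printed sum over the `L` sites is divided by `L` so that divergence is
#' a per-site quantity in `[0, 1]`, directly comparable with the 0.5
#' saturation threshold regardless of `L`. Note that for a polymorphic
#' population the divergence of a consensus with itself is not zero:
#' `k(x, x) = 2 * mean(x * (1 - x))`, the expected heterozygosity, which
#' vanishes only when every site is fixed.
#'
#' @param FO,TE Numeric vectors of equal length with entries in `[0, 1]`.
#' @return Divergence in `[0, 1]`.
#' @examples
#' divergence_k(rep(0, 10), rep(1, 10))    # 1: every site flipped
#' divergence_k(rep(1, 10), rep(1, 10))    # 0: fixed and unchanged
#' divergence_k(rep(0.5, 10), rep(0.5, 10)) # 0.5: maximally polymorphic
#' @export
divergence_k <- function(FO, TE) {
  if (length(FO) != length(TE)) {
    stop("consensus vectors have different lengths (", length(FO), " vs ",
         length(TE), ")")
  }
  if (any(FO < 0 | FO > 1) || any(TE < 0 | TE > 1)) {
    stop("consensus entries must lie in [0, 1]")
  }
  mean(FO * (1 - TE) + TE * (1 - FO))
}

#' Start a consensus track for the rate-of-evolution estimator
#'
#' The tracker stores, per host protein and domain, the focal consensus `FO`
#' (the consensus at the start of the current epoch) and compares it to the
#' temporal consensus `TE` observed at each later sample. When the neutral
#' domain of a protein saturates (`ks` exceeding `saturation_threshold`), the
#' focal consensus of all three domains of that protein is reset to the
#' current consensus, so `ka` and `ks` always share a focal epoch.
#'
#' @param population A `host_population` matrix (or a precomputed consensus
#'   vector of length `15 * L`) defining the focal consensus at the first
#'   sample.
#' @param generation Generation of the first sample (default 0).
#' @param L Sites per domain.
#' @param sample_interval Generations between samples (default 5).
#' @param saturation_threshold Neutral-domain divergence that triggers a
#'   focal reset (default 0.5).
#' @return An object of class `consensus_track`.
#' @export
new_consensus_track <- function(population, generation = 0L, L = 10L,
                                sample_interval = 5L,
                                saturation_threshold = 0.5) {
  cons <- as_host_consensus(population, L)
  structure(list(FO = cons, L = as.integer(L),
                 sample_interval = as.integer(sample_interval),
                 saturation_threshold = saturation_threshold,
                 sample_index = 0L, generation = as.integer(generation),
                 records = list()),
            class = "consensus_track")
}

as_host_consensus <- function(population, L) {
  if (is.matrix(population)) population_consensus(population)
  else {
    if (length(population) != 15L * L) stop("consensus vector must have length 15 * L")
    as.numeric(population)
  }
}

#' Advance a consensus track by one sample
#'
#' Computes the temporal consensus of the supplied population and, per host
#' protein: if the neutral-domain divergence since the focal epoch exceeds
#' the saturation threshold, resets the focal consensus of all three domains
#' and records no rate; otherwise records `ks` (neutral), `ka` (sender and
#' receiver) and `omega = ka / ks`. When `ks = 0` (the neutral domain has
#' not moved) `omega` is undefined and recorded as `NA`, never as infinity.
#'
#' @param track A `consensus_track`.
#' @param population A `host_population` matrix or consensus vector.
#' @param generation Generation of this sample; must be
#'   `sample_interval` generations after the previous one.
#' @return The updated track; `track$records` accumulates one data frame per
#'   sample (see [omega_stream()] for the assembled stream).
#' @export
update_track <- function(track, population, generation) {
  stopifnot(inherits(track, "consensus_track"))
  generation <- as.integer(generation)
  if ((generation - track$generation) %% track$sample_interval != 0L ||
      generation <= track$generation) {
    stop("samples must arrive every ", track$sample_interval, " generations")
  }
  TE <- as_host_consensus(population, track$L)
  track$sample_index <- track$sample_index + 1L
  rows <- track_sample(track$FO, TE, track$L, track$saturation_threshold,
                       track$sample_index, generation)
  track$FO <- rows$FO
  track$generation <- generation
  track$records[[length(track$records) + 1L]] <- rows$records
  track
}

# One sample of the estimator: compare FO to TE per protein, apply the
# per-protein saturation reset, return updated FO and the record rows.
track_sample <- function(FO, TE, L, threshold, sample_index, generation) {
  prot <- host_proteins()
  out <- vector("list", length(prot))
  for (pi in seq_along(prot)) {
    p <- prot[pi]
    ncols <- domain_cols(p, "neutral", L)
    ks <- divergence_k(FO[ncols], TE[ncols])
    reset <- ks > threshold
    ka <- c(receiver = NA_real_, sender = NA_real_)
    omega <- c(receiver = NA_real_, sender = NA_real_)
    if (reset) {
      allc <- c(domain_cols(p, "receiver", L), ncols, domain_cols(p, "sender", L))
      FO[allc] <- TE[allc]
    } else {
      for (d in c("receiver", "sender")) {
        dc <- domain_cols(p, d, L)
        ka[[d]] <- divergence_k(FO[dc], TE[dc])
        omega[[d]] <- if (ks > 0) ka[[d]] / ks else NA_real_
      }
    }
    out[[pi]] <- data.frame(
      sample_index = sample_index, generation = generation,
      protein = p, domain = c("receiver", "sender"),
      ks = ks, ka = unname(ka), omega = unname(omega), reset = reset,
      stringsAsFactors = FALSE
    )
  }
  list(FO = FO, records = do.call(rbind, out))
}

#' Assemble the ka/ks stream from stored consensus samples
#'
#' Replays the consensus-track logic of [update_track()] over a matrix of
#' consensus samples (as stored by [run_simulation()]): the first row defines
#' the focal consensus, each later row is a temporal consensus.
#'
#' @param consensus_samples Numeric matrix, one consensus vector
#'   (length `15 * L`) per row.
#' @param generations Integer vector of the generations at which the rows
#'   were sampled.
#' @param L Sites per domain.
#' @param saturation_threshold Neutral-domain reset threshold.
#' @return A data frame with columns `sample_index`, `generation`, `protein`,
#'   `domain` (receiver/sender), `ks`, `ka`, `omega` and `reset`; `omega` is
#'   `NA` at resets and whenever `ks = 0`.
#' @export
omega_stream <- function(consensus_samples, generations, L = 10L,
                         saturation_threshold = 0.5) {
  S <- nrow(consensus_samples)
  if (is.null(S) || S == 0L) stop("no consensus samples")
  if (length(generations) != S) stop("one generation per consensus sample required")
  if (S == 1L) {
    return(data.frame(sample_index = integer(0), generation = integer(0),
                      protein = character(0), domain = character(0),
                      ks = numeric(0), ka = numeric(0), omega = numeric(0),
                      reset = logical(0), stringsAsFactors = FALSE))
  }
  FO <- as.numeric(consensus_samples[1L, ])
  recs <- vector("list", S - 1L)
  for (s in 2:S) {
    res <- track_sample(FO, as.numeric(consensus_samples[s, ]), L,
                        saturation_threshold, s - 1L, generations[s])
    FO <- res$FO
    recs[[s - 1L]] <- res$records
  }
  do.call(rbind, recs)
}

#' Average omega trajectories across replicate runs
#'
#' Aligns the omega streams of replicate simulations by sample index and
#' returns the pointwise mean and sample standard deviation (n - 1
#' denominator) of the recorded values for one protein and domain, skipping
#' missing values; indices at which no replicate recorded a value yield `NA`
#' with `n_valid = 0`.
#'
#' @param streams A list of omega-stream data frames (from [omega_stream()]
#'   or `run$omega`), one per replicate.
#' @param protein Host protein label.
#' @param domain `"receiver"` or `"sender"`.
#' @return Data frame with columns `sample_index`, `mean_omega`, `sd_omega`
#'   and `n_valid`.
#' @export
summarize_omega <- function(streams, protein, domain) {
  if (!length(streams)) stop("at least one replicate stream is required")
  vals <- lapply(streams, function(s) {
    s <- s[s$protein == protein & s$domain == domain, ]
    s[order(s$sample_index), c("sample_index", "omega")]
  })
  idx <- sort(unique(unlist(lapply(vals, `[[`, "sample_index"))))
  m <- sapply(vals, function(v) v$omega[match(idx, v$sample_index)])
  m <- matrix(m, nrow = length(idx))
  data.frame(
    sample_index = idx,
    mean_omega = apply(m, 1L, function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)),
    sd_omega = apply(m, 1L, function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0L) NA_real_
      else if (length(x) == 1L) 0
      else stats::sd(x)
    }),
    n_valid = apply(m, 1L, function(x) sum(!is.na(x)))
  )
}

#' Write an omega stream as tab-separated text
#'
#' @param stream An omega-stream data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_omega_stream <- function(stream, path) {
  utils::write.table(stream, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
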