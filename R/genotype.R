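#' Hamming distance between two bit domains
#'
#' The number of sites at which two equal-length binary vectors differ.
#' Distances between the sender domain of an acting protein and the receiver
#' domain of its target determine the signed interaction coefficient (see
#' [interaction_coefficient()]).
#'
#' @param a,b Integer vectors of 0/1 values with equal length.
#' @return Integer count of differing sites, between 0 and `length(a)`.
#' @examples
#' hamming_distance(c(1, 1, 1, 1, 1), c(1, 1, 0, 0, 0))  # 3
#' @export
hamming_distance <- function(a, b) {
  check_bits(a)
  check_bits(b)
  if (length(a) != length(b)) {
    stop("bit domains have different lengths (", length(a), " vs ", length(b), ")")
  }
  sum(a != b)
}

check_bits <- function(x) {
  if (length(x) == 0L || !all(x %in% c(0L, 1L))) {
    stop("a bit domain must be a non-empty vector of 0/1 values")
  }
  invisible(x)
}

#' Signed interaction coefficient from a sender/receiver domain pair
#'
#' The coefficient is `mu = 1 - 2 * H / L` where `H` is the Hamming distance
#' between the sender domain of the acting protein and the receiver domain of
#' the target, and `L` is the domain length. `mu > 0` is activatory (more than
#' half the sites match), `mu < 0` inhibitory, and `mu = 0` (exactly `L/2`
#' matches) means no interaction takes place.
#'
#' @param sender_domain Bit vector of the acting protein's sender domain.
#' @param receiver_domain Bit vector of the target protein's receiver domain.
#' @return A number in `[-1, 1]`.
#' @examples
#' interaction_coefficient(rep(1, 10), rep(1, 10))          # 1
#' interaction_coefficient(rep(1, 10), rep(0, 10))          # -1
#' interaction_coefficient(rep(1, 10), rep(c(1, 0), 5))     # 0
#' @export
interaction_coefficient <- function(sender_domain, receiver_domain) {
  H <- hamming_distance(sender_domain, receiver_domain)
  1 - 2 * H / length(sender_domain)
}

#' Construct a host or pathogen genotype from raw bits
#'
#' A genotype is stored as a flat integer vector of 0/1 bits: proteins in
#' canonical order (`R, A, I, U, D` for hosts, `P` for the pathogen), the three
#' domains `receiver|neutral|sender` within each protein, `L` sites within each
#' domain. Individual domains are extracted with [gene_domain()].
#'
#' @param bits Integer vector of 0/1 values; length `15 * L` (host) or
#'   `3 * L` (pathogen).
#' @param L Sites per domain (default 10).
#' @return An object of class `host_genotype` or `pathogen_genotype`.
#' @export
host_genotype <- function(bits, L = 10L) {
  new_genotype(bits, L, host_proteins(), "host_genotype")
}

#' @rdname host_genotype
#' @export
pathogen_genotype <- function(bits, L = 10L) {
  new_genotype(bits, L, "P", "pathogen_genotype")
}

new_genotype <- function(bits, L, proteins, class) {
  bits <- as.integer(bits)
  check_bits(bits)
  want <- length(proteins) * 3L * L
  if (length(bits) != want) {
    stop("genotype needs ", want, " bits (", length(proteins),
         " proteins x 3 domains x L=", L, "), got ", length(bits))
  }
  structure(bits, L = as.integer(L), proteins = proteins,
            class = c(class, "genotype"))
}

genotype_L <- function(g) attr(g, "L")
genotype_proteins <- function(g) attr(g, "proteins")

#' Extract one domain of one protein from a genotype
#'
#' @param genotype A `host_genotype` or `pathogen_genotype`.
#' @param protein Protein label (`"R"`, `"A"`, `"I"`, `"U"`, `"D"` or `"P"`).
#' @param domain One of `"receiver"`, `"neutral"`, `"sender"`.
#' @return Integer vector of `L` bits.
#' @export
gene_domain <- function(genotype, protein, domain) {
  L <- genotype_L(genotype)
  idx <- domain_cols(protein, domain, L, genotype_proteins(genotype))
  unclass(genotype)[idx]
}

#' Interaction coefficients for one host-pathogen pairing
#'
#' Evaluates `mu = 1 - 2H/L` for every edge of the fixed network topology,
#' pairing the sender domain of the source protein with the receiver domain of
#' the target protein. Edges listed in `overrides` take the fixed value
#' verbatim instead (used e.g. to pin the receptor-pathogen interaction at
#' `mu = 1`, switching off receptor-pathogen coevolution).
#'
#' @param host A `host_genotype`.
#' @param pathogen A `pathogen_genotype`.
#' @param overrides Named numeric vector of fixed coefficients keyed by edge
#'   name (see [edge_names()]), each in `[-1, 1]`, or `NULL`.
#' @return Named numeric vector of coefficients, one per topology edge, in the
#'   canonical edge order.
#' @export
compute_interactions <- function(host, pathogen, overrides = NULL) {
  stopifnot(inherits(host, "host_genotype"), inherits(pathogen, "pathogen_genotype"))
  if (genotype_L(host) != genotype_L(pathogen)) {
    stop("host and pathogen genotypes have different L")
  }
  overrides <- check_overrides(overrides)
  topo <- signaling_topology()
  mu <- numeric(nrow(topo))
  names(mu) <- topo$name
  for (k in seq_len(nrow(topo))) {
    if (topo$name[k] %in% names(overrides)) {
      mu[k] <- overrides[[topo$name[k]]]
      next
    }
    src <- if (topo$source[k] == "P") pathogen else host
    tgt <- if (topo$target[k] == "P") pathogen else host
    mu[k] <- interaction_coefficient(
      gene_domain(src, topo$source[k], "sender"),
      gene_domain(tgt, topo$target[k], "receiver")
    )
  }
  mu
}

check_overrides <- function(overrides) {
  if (is.null(overrides) || length(overrides) == 0L) return(numeric(0))
  if (is.null(names(overrides)) || any(names(overrides) == "")) {
    stop("mu overrides must be a named vector keyed by edge name")
  }
  bad <- setdiff(names(overrides), edge_names())
  if (length(bad)) stop("unknown edge name(s) in overrides: ", paste(bad, collapse = ", "))
  if (any(!is.finite(overrides)) || any(overrides < -1) || any(overrides > 1)) {
    stop("override coefficients must lie in [-1, 1]")
  }
  overrides
}

#' Sexual reproduction of a host genotype
#'
#' For each of the five proteins independently, one of the three domains is
#' chosen uniformly at random to recombine: a cut site `k` is drawn uniformly
#' from `1..L-1`, sites strictly left of `k` come from `parent1` and sites `k`
#' and rightward from `parent2` (so `k = 1` inherits the whole domain from
#' `parent2`; the draw never produces a cut that silences one parent on both
#' flanks). The two non-recombining domains are each inherited whole from a
#' uniformly chosen parent. One recombination event per protein, as in the
#' model's single-crossover sexual reproduction.
#'
#' Uses the R random number generator; seed with [set.seed()] for
#' reproducibility.
#'
#' @param parent1,parent2 `host_genotype` objects sharing `L`.
#' @return A `host_genotype` offspring.
#' @export
recombine_host <- function(parent1, parent2) {
  stopifnot(inherits(parent1, "host_genotype"), inherits(parent2, "host_genotype"))
  L <- genotype_L(parent1)
  if (L != genotype_L(parent2)) stop("parents have different L")
  bits <- unclass(parent1)
  p2 <- unclass(parent2)
  for (p in seq_along(host_proteins())) {
    base <- (p - 1L) * 3L * L
    rd <- sample.int(3L, 1L)           # recombining domain
    for (d in 1:3) {
      idx <- base + (d - 1L) * L + seq_len(L)
      if (d == rd) {
        k <- sample.int(L - 1L, 1L)    # cut site in 1..L-1
        take2 <- seq_len(L) >= k
        bits[idx[take2]] <- p2[idx[take2]]
      } else if (sample.int(2L, 1L) == 2L) {
        bits[idx] <- p2[idx]
      }
    }
  }
  host_genotype(bits, L)
}

#' Point mutation of a genotype
#'
#' With probability `rate` the offspring receives exactly one bit flip at a
#' uniformly chosen (protein, domain, site); otherwise it is returned
#' unchanged. The neutral domain is mutable like any other -- it is the
#' benchmark for the neutral substitution rate.
#'
#' @param genotype A `host_genotype` or `pathogen_genotype`.
#' @param rate Per-offspring mutation probability in `[0, 1]` (the model's
#'   `MH` for hosts, `MP` for pathogens).
#' @return A genotype of the same class.
#' @export
mutate_genotype <- function(genotype, rate) {
  stopifnot(inherits(genotype, "genotype"))
  if (rate < 0 || rate > 1) stop("mutation rate must be in [0, 1]")
  if (rate > 0 && stats::runif(1) < rate) {
    i <- sample.int(length(genotype), 1L)
    genotype[i] <- 1L - unclass(genotype)[i]
  }
  genotype
}

#' Random initial populations
#'
#' Draws `n` host and `n` pathogen genotypes with every bit i.i.d.
#' Bernoulli(0.5) -- the maximum-entropy starting condition for "randomly
#' created" haploid individuals. Populations are stored as integer matrices
#' (one row per individual, flat genotype layout in the columns) so the
#' compiled engine and the consensus machinery can operate on them directly.
#'
#' @param n Population size (at least 2); the same for hosts and pathogens.
#' @param L Sites per domain.
#' @return A list with elements `hosts` (`n x 15L` matrix of class
#'   `host_population`) and `pathogens` (`n x 3L` matrix of class
#'   `pathogen_population`).
#' @export
random_population <- function(n, L = 10L) {
  if (n < 2) stop("population size n must be at least 2")
  n <- as.integer(n); L <- as.integer(L)
  hosts <- matrix(sample(0:1, n * 15L * L, replace = TRUE), nrow = n)
  paths <- matrix(sample(0:1, n * 3L * L, replace = TRUE), nrow = n)
  list(hosts = new_population(hosts, L, "host_population"),
       pathogens = new_population(paths, L, "pathogen_population"))
}

new_population <- function(m, L, class) {
  storage.mode(m) <- "integer"
  structure(m, L = as.integer(L), class = c(class, "population"))
}

population_L <- function(pop) attr(pop, "L")

#' Extract one individual from a population matrix as a genotype object
#'
#' @param pop A `host_population` or `pathogen_population`.
#' @param i Row index of the individual.
#' @return A `host_genotype` or `pathogen_genotype`.
#' @export
population_genotype <- function(pop, i) {
  L <- population_L(pop)
  bits <- as.integer(pop[i, ])
  if (inherits(pop, "host_population")) host_genotype(bits, L)
  else pathogen_genotype(bits, L)
}

#' Consensus sequence of a set of bit domains
#'
#' The per-site mean of bit values across individuals: the proportion of 1s at
#' each site. Applied every few generations to each (protein, domain) slice of
#' a population, consensus vectors are the raw material of the ka/ks
#' evolutionary-rate estimator (see [divergence_k()]).
#'
#' @param domains A matrix with one individual's domain per row (or a single
#'   bit vector, treated as a one-row matrix).
#' @return Numeric vector of per-site frequencies in `[0, 1]`.
#' @export
consensus <- function(domains) {
  if (is.null(dim(domains))) domains <- matrix(domains, nrow = 1L)
  if (nrow(domains) == 0L) stop("consensus of an empty population is undefined")
  colMeans(domains)
}

#' Full-genotype consensus of a population
#'
#' @param pop A population matrix.
#' @return Numeric vector of per-site 1-frequencies over the flat genotype
#'   layout (length `ncol(pop)`).
#' @export
population_consensus <- function(pop) {
  if (nrow(pop) == 0L) stop("consensus of an empty population is undefined")
  colMeans(pop)
}
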