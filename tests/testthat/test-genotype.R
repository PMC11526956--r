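test_that("hamming distance counts differing sites", {
  a <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  b <- rep(1, 10)
  expect_identical(hamming_distance(a, a), 0L)
  expect_identical(hamming_distance(a, 1 - a), 10L)
  expect_identical(hamming_distance(a, b), 5L)
  expect_error(hamming_distance(a, b[1:5]), "length")
  expect_error(hamming_distance(c(0, 2), c(0, 1)), "0/1")
})

test_that("interaction coefficient is the exact map 1 - 2H/L, decreasing in H", {
  L <- 10L
  mus <- vapply(0:L, function(H) {
    sender <- rep(1L, L)
    receiver <- c(rep(0L, H), rep(1L, L - H))
    interaction_coefficient(sender, receiver)
  }, numeric(1))
  expect_equal(mus, 1 - 2 * (0:L) / L)
  expect_true(all(diff(mus) < 0))          # strictly decreasing bijection of H
  expect_identical(mus[L / 2 + 1], 0)      # exactly L/2 matches: no interaction
  expect_identical(mus[1], 1)
  expect_identical(mus[L + 1], -1)
})

test_that("compute_interactions matches a brute-force per-edge oracle", {
  set.seed(71)
  for (rep in 1:5) {
    fx <- make_fixture("random")
    mu <- compute_interactions(fx$host, fx$pathogen)
    expect_equal(unname(mu), brute_force_mu(fx$host, fx$pathogen))
    expect_true(all(mu >= -1 & mu <= 1))
  }
})

test_that("fixture geometries give the expected coefficients", {
  al <- make_fixture("aligned")
  expect_equal(unname(compute_interactions(al$host, al$pathogen)), rep(1, 8))
  an <- make_fixture("anti_aligned")
  expect_equal(unname(compute_interactions(an$host, an$pathogen)), rep(-1, 8))
  nt <- make_fixture("near_threshold")
  expect_equal(unname(compute_interactions(nt$host, nt$pathogen)), rep(0, 8))
  expect_equal(unname(compute_interactions(make_fixture("near_threshold", offset = 1)$host,
                                           make_fixture("near_threshold", offset = 1)$pathogen)),
               rep(-0.2, 8))
  expect_error(make_fixture("near_threshold", L = 9), "even")
})

test_that("overrides replace evolved coefficients verbatim and are validated", {
  set.seed(5)
  fx <- make_fixture("random")
  mu <- compute_interactions(fx$host, fx$pathogen, overrides = c(R_P = 1))
  expect_identical(mu[["R_P"]], 1)
  free <- compute_interactions(fx$host, fx$pathogen)
  expect_equal(mu[edge_names() != "R_P"], free[edge_names() != "R_P"])
  expect_error(compute_interactions(fx$host, fx$pathogen, overrides = c(R_P = 1.5)),
               "\\[-1, 1\\]")
  expect_error(compute_interactions(fx$host, fx$pathogen, overrides = c(bogus = 1)),
               "unknown edge")
})

test_that("the neutral domain never influences interaction coefficients", {
  set.seed(9)
  fx <- make_fixture("random")
  mu0 <- compute_interactions(fx$host, fx$pathogen)
  bits <- unclass(fx$host)
  for (p in host_proteins()) {
    idx <- nflevo:::domain_cols(p, "neutral", 10L)
    bits[idx] <- 1L - bits[idx]
  }
  flipped <- host_genotype(bits, 10L)
  expect_identical(compute_interactions(flipped, fx$pathogen), mu0)
})

test_that("recombination of identical parents is the identity", {
  set.seed(2)
  fx <- make_fixture("random")
  off <- recombine_host(fx$host, fx$host)
  expect_identical(unclass(off), unclass(fx$host))
})

test_that("recombination conserves per-site parental provenance", {
  set.seed(31)
  p1 <- make_fixture("random")$host
  p2 <- make_fixture("random")$host
  for (trial in 1:500) {
    off <- recombine_host(p1, p2)
    ok <- unclass(off) == unclass(p1) | unclass(off) == unclass(p2)
    expect_true(all(ok))
  }
})

test_that("recombination mixes both parents across trials", {
  set.seed(8)
  p1 <- host_genotype(rep(0L, 150))
  p2 <- host_genotype(rep(1L, 150))
  counts <- rowSums(vapply(1:200, function(i) unclass(recombine_host(p1, p2)),
                           integer(150)))
  # every site is inherited from parent2 a non-trivial fraction of the time
  expect_true(all(counts > 0) && all(counts < 200))
})

test_that("mutation flips at most one bit, at the requested rate", {
  set.seed(4)
  fx <- make_fixture("random")
  expect_identical(unclass(mutate_genotype(fx$host, 0)), unclass(fx$host))
  for (i in 1:50) {
    m <- mutate_genotype(fx$host, 1)
    expect_identical(sum(unclass(m) != unclass(fx$host)), 1L)
  }
  rate <- 0.02
  hits <- sum(vapply(1:20000, function(i) {
    any(unclass(mutate_genotype(fx$pathogen, rate)) != unclass(fx$pathogen))
  }, logical(1)))
  expect_lt(abs(hits / 20000 - rate), 4 * sqrt(rate * (1 - rate) / 20000))
})

test_that("random populations have the right shape and unbiased bits", {
  set.seed(12)
  pop <- random_population(2000, 10)
  expect_identical(dim(pop$hosts), c(2000L, 150L))
  expect_identical(dim(pop$pathogens), c(2000L, 30L))
  freqs <- colMeans(pop$hosts)
  expect_true(all(abs(freqs - 0.5) < 4 * sqrt(0.25 / 2000)))
  set.seed(99); a <- random_population(50, 10)
  set.seed(99); b <- random_population(50, 10)
  expect_identical(a, b)
  expect_error(random_population(1), "at least 2")
})

test_that("consensus is the per-site mean and ignores row order", {
  m <- rbind(rep(1L, 5), rep(1L, 5))
  expect_equal(consensus(m), rep(1, 5))
  half <- rbind(rep(0L, 4), rep(1L, 4))
  expect_equal(consensus(half), rep(0.5, 4))
  set.seed(3)
  r <- matrix(sample(0:1, 60, replace = TRUE), nrow = 6)
  expect_equal(consensus(r), apply(r, 2, mean))
  expect_equal(consensus(r[sample(6), ]), consensus(r))
  expect_error(consensus(r[0, , drop = FALSE]), "empty")
})
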