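test_that("consensus divergence follows the two-term change formula", {
  expect_identical(divergence_k(rep(0, 10), rep(1, 10)), 1)   # all sites flipped
  expect_identical(divergence_k(rep(1, 10), rep(1, 10)), 0)   # fixed, unchanged
  expect_identical(divergence_k(rep(0, 10), rep(0, 10)), 0)
  # a polymorphic consensus diverges from itself by its heterozygosity
  expect_identical(divergence_k(rep(0.5, 10), rep(0.5, 10)), 0.5)
  x <- c(0.2, 0.8, 1, 0)
  y <- c(0.4, 0.4, 0.9, 0.1)
  expect_equal(divergence_k(x, y), mean(x * (1 - y) + y * (1 - x)))
  expect_equal(divergence_k(x, y), divergence_k(y, x))        # symmetric
  expect_error(divergence_k(x, y[1:2]), "length")
  expect_error(divergence_k(c(-0.1, 0), c(0, 0)), "\\[0, 1\\]")
})

# build a consensus vector with chosen per-domain values for protein R and
# binary elsewhere
cons_vec <- function(neutral, sender, receiver = 0, L = 10L) {
  v <- rep(0, 15 * L)
  v[nflevo:::domain_cols("R", "neutral", L)] <- neutral
  v[nflevo:::domain_cols("R", "sender", L)] <- sender
  v[nflevo:::domain_cols("R", "receiver", L)] <- receiver
  v
}

test_that("omega is ka/ks, equal rates give omega 1", {
  samples <- rbind(cons_vec(0, 0), cons_vec(0.3, 0.3))
  st <- omega_stream(samples, c(0, 5))
  r <- st[st$protein == "R" & st$domain == "sender", ]
  expect_equal(r$ks, 0.3)
  expect_equal(r$ka, 0.3)
  expect_equal(r$omega, 1)
})

test_that("engineered divergences give the expected omega", {
  # neutral moved by 0.2 per site, sender by 0.1: omega = 0.5
  samples <- rbind(cons_vec(0, 0), cons_vec(0.2, 0.1))
  st <- omega_stream(samples, c(0, 5))
  r <- st[st$protein == "R" & st$domain == "sender", ]
  expect_equal(r$ks, 0.2)
  expect_equal(r$ka, 0.1)
  expect_equal(r$omega, 0.5)
  expect_false(r$reset)
})

test_that("neutral saturation resets the focal consensus of all domains", {
  s1 <- cons_vec(0, 0, receiver = 0)
  s2 <- cons_vec(0.8, 0.4, receiver = 0.4)  # neutral k = 0.8 > 0.5: reset
  s3 <- cons_vec(0.8, 0.4, receiver = 0.4)  # identical to new focal
  st <- omega_stream(rbind(s1, s2, s3), c(0, 5, 10))
  first <- st[st$sample_index == 1 & st$protein == "R", ]
  expect_true(all(first$reset))
  expect_true(all(is.na(first$omega)))
  # after the reset the focal epoch restarts: divergence is the (unchanged)
  # heterozygosity of the polymorphic consensus, shared by both domains
  second <- st[st$sample_index == 2 & st$protein == "R", ]
  expect_false(any(second$reset))
  expect_equal(second$ks, rep(2 * 0.8 * 0.2, 2))
  expect_equal(second$ka, rep(2 * 0.4 * 0.6, 2))
})

test_that("omega is missing, not infinite, when the neutral domain is static", {
  samples <- rbind(cons_vec(0, 0), cons_vec(0, 0.3))
  st <- omega_stream(samples, c(0, 5))
  r <- st[st$protein == "R" & st$domain == "sender", ]
  expect_identical(r$ks, 0)
  expect_true(is.na(r$omega))
  expect_false(r$reset)
})

test_that("the incremental track matches the batch replay", {
  set.seed(61)
  pops <- lapply(1:4, function(i) random_population(40, 10)$hosts)
  track <- new_consensus_track(pops[[1]], generation = 0)
  for (s in 2:4) track <- update_track(track, pops[[s]], generation = (s - 1) * 5)
  batch <- omega_stream(do.call(rbind, lapply(pops, population_consensus)),
                        c(0, 5, 10, 15))
  expect_equal(do.call(rbind, track$records), batch)
  expect_error(update_track(track, pops[[1]], generation = 17), "every 5")
})

test_that("replicate omega summaries use mean and sample sd, skipping NAs", {
  mk <- function(om) data.frame(sample_index = 1:3, generation = c(5, 10, 15),
                                protein = "D", domain = "sender",
                                ks = 0.2, ka = om * 0.2, omega = om,
                                reset = FALSE)
  s <- summarize_omega(list(mk(c(1, 1, NA)), mk(c(3, 3, NA))), "D", "sender")
  expect_equal(s$mean_omega[1:2], c(2, 2))
  expect_equal(s$sd_omega[1:2], c(sd(c(1, 3)), sd(c(1, 3))))
  expect_identical(s$n_valid, c(2L, 2L, 0L))
  expect_true(is.na(s$mean_omega[3]))
  one <- summarize_omega(list(mk(c(1, 1, 1))), "D", "sender")
  expect_equal(one$mean_omega, c(1, 1, 1))
  expect_equal(one$sd_omega, c(0, 0, 0))
  # a replicate with no recorded omega is skipped without error
  s2 <- summarize_omega(list(mk(c(2, 2, 2)), mk(c(NA, NA, NA))), "D", "sender")
  expect_equal(s2$mean_omega, c(2, 2, 2))
})
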