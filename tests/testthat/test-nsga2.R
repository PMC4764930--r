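test_that("dominance is component-wise with strictness in one", {
  expect_true(dominates(c(0.1, 0.2), c(0.2, 0.3)))
  expect_false(dominates(c(0.1, 0.2), c(0.1, 0.2)))
  expect_false(dominates(c(0.1, 0.3), c(0.2, 0.2)))
})

test_that("non-dominated sorting matches the definitional oracle", {
  expect_equal(fast_nondominated_sort(rbind(c(1, 2)))$fronts, list(1L))

  chain <- cbind(1:5, 1:5)   # strictly dominated chain
  expect_equal(fast_nondominated_sort(chain)$fronts, as.list(1:5))

  for (d in 2:3) {
    obj <- withr::with_seed(d, matrix(runif(200 * d), 200, d))
    got <- fast_nondominated_sort(obj)
    want <- oracle_fronts(obj)
    expect_equal(length(got$fronts), length(want))
    for (k in seq_along(want)) {
      expect_setequal(got$fronts[[k]], want[[k]])
    }
    expect_equal(got$rank, rep(seq_along(want), lengths(want))[order(unlist(want))])
  }
})

test_that("crowding distance follows Deb's formula", {
  expect_equal(crowding_distance(rbind(c(1, 2), c(3, 4))), c(Inf, Inf))
  colinear <- rbind(c(0, 0), c(1, 1), c(2, 2))
  expect_equal(crowding_distance(colinear), c(Inf, 2, Inf))
  dup <- rbind(c(0, 2), c(1, 1), c(1, 1), c(2, 0))
  d <- crowding_distance(dup)
  expect_equal(d[2:3], c(0, 0) + 1)  # interior duplicates share both gaps
  # exact-duplicate interior points in a 4-front: each neighbor gap spans the
  # same vectors, giving identical finite distances
  expect_equal(d[2], d[3])
  trip <- rbind(c(0, 2), c(1, 1), c(1, 1), c(1, 1), c(2, 0))
  expect_equal(crowding_distance(trip)[3], 0)
})

test_that("tournament prefers rank, then crowding, then a fair coin", {
  expect_equal(tournament_select(c(1, 2), c(0, 5), contestants = c(1, 2)), 1)
  expect_equal(tournament_select(c(1, 2), c(0, 5), contestants = c(2, 1)), 1)
  expect_equal(tournament_select(c(1, 1), c(Inf, 0.3), contestants = c(1, 2)), 1)
  picks <- withr::with_seed(2,
    replicate(1e4, tournament_select(c(1, 1), c(1, 1))))
  freq <- mean(picks == 1)
  expect_lt(abs(freq - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("uniform crossover swaps half the positions at the given rate", {
  a <- rep(TRUE, 40); b <- rep(FALSE, 40)
  withr::with_seed(3, {
    same <- uniform_crossover(a, a, rate = 1)
    expect_equal(same[[1]], a)
    expect_equal(same[[2]], a)
    off <- uniform_crossover(a, b, rate = 0)
    expect_equal(off[[1]], a)
    expect_equal(off[[2]], b)
  })
  nswap <- withr::with_seed(4, {
    sum(replicate(2000, sum(uniform_crossover(a, b, rate = 1)[[1]] == FALSE)))
  })
  ntot <- 2000 * 40
  expect_lt(abs(nswap / ntot - 0.5), 3 * sqrt(0.25 / ntot))
})

test_that("bit-flip mutation hits its per-bit rate", {
  s <- withr::with_seed(5, runif(304) < 0.05)
  expect_equal(bitflip_mutation(s, 0), s)
  withr::with_seed(6, expect_equal(bitflip_mutation(s, 1), !s))
  nflip <- withr::with_seed(7, {
    sum(replicate(1e4, sum(bitflip_mutation(s, 0.01) != s)))
  })
  mean_flips <- nflip / 1e4
  se <- sqrt(304 * 0.01 * 0.99 / 1e4)
  expect_lt(abs(mean_flips - 3.04), 3 * se)
})

test_that("repair enforces the feasible size range", {
  withr::with_seed(8, {
    expect_equal(sum(repair_subset(rep(FALSE, 10), 2)), 2)
    ok <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
    expect_equal(repair_subset(ok, 2), ok)
    expect_equal(sum(repair_subset(rep(TRUE, 10), 2)), 9)
  })
})

test_that("the search is deterministic and respects its output contracts", {
  w1 <- withr::with_seed(9, runif(30))
  w2 <- withr::with_seed(10, runif(30))
  ev <- function(bits) c(sum(w1[bits]), sum(w2[bits]))
  cfg <- moo_config(population_size = 40, max_generations = 15, seed = 99)
  p1 <- run_nsga2(ev, 30, cfg)
  p2 <- run_nsga2(ev, 30, cfg)
  expect_identical(p1, p2)
  expect_lte(nrow(p1), ceiling(0.2 * 40))
  expect_true(all(p1$size >= 2 & p1$size < 30))
  expect_false(any(duplicated(sapply(p1$bits, paste, collapse = ""))))
  # returned individuals are mutually non-dominated
  for (i in seq_len(nrow(p1))) for (j in seq_len(nrow(p1))) {
    if (i != j) expect_false(dominates(c(p1$f1[j], p1$f2[j]),
                                       c(p1$f1[i], p1$f2[i])))
  }
})

test_that("on an exhaustively enumerable landscape the front is globally optimal", {
  n <- 12
  w1 <- withr::with_seed(11, runif(n))
  w2 <- withr::with_seed(12, runif(n))
  # conflicting objectives over subsets with non-trivial structure
  ev <- function(bits) {
    k <- sum(bits)
    c(sum(w1[bits]) / k + 0.05 * k, sum(w2[bits]) / k + 0.6 / k)
  }
  # enumerate every feasible subset (2 <= size < n)
  all_bits <- lapply(1:(2^n - 1), function(x) as.logical(intToBits(x)[1:n]))
  all_bits <- Filter(function(b) sum(b) >= 2 && sum(b) < n, all_bits)
  landscape <- t(vapply(all_bits, ev, numeric(2)))
  f1 <- landscape[, 1]; f2 <- landscape[, 2]
  global_nd <- which(!vapply(seq_along(f1), function(i) {
    any(f1 <= f1[i] & f2 <= f2[i] & (f1 < f1[i] | f2 < f2[i]))
  }, logical(1)))
  nd_keys <- sapply(all_bits[global_nd], paste, collapse = "")

  res <- run_nsga2(ev, n, moo_config(population_size = 60,
                                     max_generations = 40, seed = 13))
  res_keys <- sapply(res$bits, function(b) paste(as.logical(b), collapse = ""))
  expect_true(all(res_keys %in% nd_keys))
})
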