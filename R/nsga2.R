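#' NSGA-II configuration
#'
#' Parameters of the binary-encoded NSGA-II search. Defaults follow the
#' study settings: population 500, crossover rate 0.8, per-bit uniform
#' mutation rate 0.01, 100 generations, Pareto-front fraction 20%.
#'
#' @param population_size Even number of individuals (default 500).
#' @param crossover_rate Probability a parent pair is recombined (default 0.8).
#' @param mutation_rate Per-bit flip probability (default 0.01).
#' @param max_generations Number of generational cycles (default 100).
#' @param pareto_fraction Maximum fraction of the population returned as the
#'   final front (default 0.2).
#' @param min_size Minimum subset size (default 2; a correlation needs a pair).
#' @param seed Integer root seed driving all randomness.
#' @return A list of class `moo_config`.
#' @export
moo_config <- function(population_size = 500, crossover_rate = 0.8,
                       mutation_rate = 0.01, max_generations = 100,
                       pareto_fraction = 0.2, min_size = 2, seed = 1L) {
  stopifnot(population_size >= 2, population_size %% 2 == 0,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            max_generations >= 1,
            pareto_fraction > 0, pareto_fraction <= 1,
            min_size >= 2)
  structure(list(population_size = as.integer(population_size),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 max_generations = as.integer(max_generations),
                 pareto_fraction = pareto_fraction,
                 min_size = as.integer(min_size),
                 seed = as.integer(seed)),
            class = "moo_config")
}

#' Pareto dominance (minimization)
#'
#' @param a,b Numeric objective vectors of equal length.
#' @return `TRUE` iff `a` is no worse than `b` in every objective and
#'   strictly better in at least one.
#' @export
dominates <- function(a, b) {
  stopifnot(length(a) == length(b))
  all(a <= b) && any(a < b)
}

#' Fast non-dominated sorting
#'
#' Deb's bookkeeping algorithm: front 1 is the non-dominated set; front k is
#' dominated only by members of earlier fronts. Works for any number of
#' objectives >= 2.
#'
#' @param objectives Numeric matrix, one row per individual, one column per
#'   objective (minimization).
#' @return A list with `fronts` (list of integer row indices) and `rank`
#'   (integer vector, one rank per row).
#' @export
fast_nondominated_sort <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  dominated_by <- vector("list", n)   # who i dominates
  n_dom <- integer(n)                 # how many dominate i
  for (i in seq_len(n)) {
    oi <- objectives[i, ]
    for (j in seq_len(n)) {
      if (i == j) next
      oj <- objectives[j, ]
      if (all(oi <= oj) && any(oi < oj)) {
        dominated_by[[i]] <- c(dominated_by[[i]], j)
      } else if (all(oj <= oi) && any(oj < oi)) {
        n_dom[i] <- n_dom[i] + 1L
      }
    }
  }
  rank <- integer(n)
  fronts <- list()
  current <- which(n_dom == 0L)
  k <- 0L
  while (length(current) > 0) {
    k <- k + 1L
    rank[current] <- k
    fronts[[k]] <- current
    nxt <- integer(0)
    for (i in current) {
      for (j in dominated_by[[i]]) {
        n_dom[j] <- n_dom[j] - 1L
        if (n_dom[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- nxt
  }
  list(fronts = fronts, rank = rank)
}

#' Crowding distance within a front
#'
#' Deb's density estimate: per objective, the front is sorted, boundary
#' individuals get `+Inf`, and interior individuals accumulate the
#' range-normalized gap between their two neighbors. Objectives with zero
#' range contribute nothing.
#'
#' @param objectives Numeric matrix of the front's objective vectors
#'   (one row per individual).
#' @return Numeric vector of crowding distances (may contain `Inf`).
#' @export
crowding_distance <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (m in seq_len(ncol(objectives))) {
    o <- objectives[, m]
    ord <- order(o)
    rng <- o[ord[n]] - o[ord[1]]
    d[ord[1]] <- Inf
    d[ord[n]] <- Inf
    if (rng > 0) {
      for (i in 2:(n - 1)) {
        d[ord[i]] <- d[ord[i]] + (o[ord[i + 1]] - o[ord[i - 1]]) / rng
      }
    }
  }
  d
}

#' Binary tournament selection index
#'
#' Draws two contestants uniformly at random; the lower rank wins, ties in
#' rank go to the larger crowding distance, and full ties are resolved by a
#' fair coin. Uses the current RNG stream.
#'
#' @param rank Integer vector of ranks.
#' @param crowding Numeric vector of crowding distances.
#' @param contestants Optional pair of indices to pit against each other;
#'   by default two are drawn uniformly (with replacement).
#' @return The index of the winner.
#' @export
tournament_select <- function(rank, crowding, contestants = NULL) {
  n <- length(rank)
  ij <- if (is.null(contestants)) sample.int(n, 2, replace = TRUE)
        else contestants
  i <- ij[1]; j <- ij[2]
  if (rank[i] < rank[j]) return(i)
  if (rank[j] < rank[i]) return(j)
  if (crowding[i] > crowding[j]) return(i)
  if (crowding[j] > crowding[i]) return(j)
  if (stats::runif(1) < 0.5) i else j
}

#' Uniform crossover of two bit-strings
#'
#' With probability `rate` the pair is recombined: each position swaps
#' between the two children independently with probability 0.5; otherwise
#' the children are exact copies. The search engine repairs children to the
#' feasible size range afterwards.
#'
#' @param a,b Logical membership vectors of equal length.
#' @param rate Crossover probability.
#' @return A list of two logical vectors.
#' @export
uniform_crossover <- function(a, b, rate) {
  stopifnot(length(a) == length(b))
  if (stats::runif(1) >= rate) return(list(a, b))
  swap <- stats::runif(length(a)) < 0.5
  c1 <- a; c2 <- b
  c1[swap] <- b[swap]
  c2[swap] <- a[swap]
  list(c1, c2)
}

#' Per-bit flip mutation
#'
#' @param bits Logical membership vector.
#' @param per_bit_rate Independent flip probability per position.
#' @return Mutated logical vector (pre-repair).
#' @export
bitflip_mutation <- function(bits, per_bit_rate) {
  flip <- stats::runif(length(bits)) < per_bit_rate
  xor(bits, flip)
}

#' Repair a subset to the feasible size range
#'
#' Variation can produce subsets that are too small for a correlation (or
#' cover every gene, leaving no complement). Undersized subsets gain
#' uniformly random unset bits up to `min_size`; a full subset loses one
#' uniformly random bit.
#'
#' @param bits Logical membership vector.
#' @param min_size Minimum feasible size.
#' @return A feasible logical vector.
#' @export
repair_subset <- function(bits, min_size) {
  k <- sum(bits)
  n <- length(bits)
  if (k < min_size) {
    unset <- which(!bits)
    add <- if (length(unset) == 1) unset else sample(unset, min_size - k)
    bits[add] <- TRUE
  } else if (k == n) {
    drop <- if (n == 1) 1L else sample.int(n, 1)
    bits[drop] <- FALSE
  }
  bits
}

bits_key <- function(bits) paste(as.integer(bits), collapse = "")

#' Run the binary-encoded NSGA-II search
#'
#' Canonical elitist NSGA-II over gene subsets: sparse seeded
#' initialization, binary tournament selection on (rank, crowding), uniform
#' crossover, per-bit mutation, repair, then (mu + lambda) environmental
#' selection by rank and crowding. The final rank-1 front is de-duplicated
#' (identical bit-strings collapse) and truncated by crowding distance to at
#' most `ceiling(pareto_fraction * population_size)` individuals.
#'
#' Initialization sets each bit with probability `min_size * 5 / n` (then
#' repairs), so early populations contain small, interpretable modules
#' rather than ~n/2-gene sets whose composite indices are uninformative.
#'
#' All randomness is driven by `config$seed`; the global RNG state is left
#' untouched, and identical (evaluator, n, config) triples give bit-identical
#' results.
#'
#' @param evaluate Function mapping a logical membership vector of length `n`
#'   to a numeric objective vector (minimization).
#' @param n Number of genes (bit-string length).
#' @param config A [moo_config()].
#' @return A tibble of class `dnb_pareto` with one row per returned
#'   solution: `solution_id`, `size`, objective columns `f1`, `f2`, ...,
#'   `distance_to_ideal`, and a list-column `bits`.
#' @export
run_nsga2 <- function(evaluate, n, config = moo_config()) {
  stopifnot(inherits(config, "moo_config"), n > config$min_size)
  withr::with_seed(config$seed, run_nsga2_impl(evaluate, n, config))
}

run_nsga2_impl <- function(evaluate, n, config) {
  np <- config$population_size
  p_init <- min(1, config$min_size * 5 / n)

  new_ind <- function(bits) {
    obj <- evaluate(bits)
    list(bits = bits, obj = as.numeric(obj))
  }

  pop <- lapply(seq_len(np), function(i) {
    bits <- repair_subset(stats::runif(n) < p_init, config$min_size)
    new_ind(bits)
  })

  objmat <- function(p) do.call(rbind, lapply(p, `[[`, "obj"))

  rank_pop <- function(p) {
    nd <- fast_nondominated_sort(objmat(p))
    crowd <- numeric(length(p))
    om <- objmat(p)
    for (f in nd$fronts) {
      crowd[f] <- crowding_distance(om[f, , drop = FALSE])
    }
    list(rank = nd$rank, crowding = crowd, fronts = nd$fronts)
  }

  rc <- rank_pop(pop)

  for (gen in seq_len(config$max_generations)) {
    offspring <- vector("list", np)
    i <- 1L
    while (i <= np) {
      pa <- pop[[tournament_select(rc$rank, rc$crowding)]]$bits
      pb <- pop[[tournament_select(rc$rank, rc$crowding)]]$bits
      ch <- uniform_crossover(pa, pb, config$crossover_rate)
      for (b in ch) {
        if (i > np) break
        b <- bitflip_mutation(b, config$mutation_rate)
        b <- repair_subset(b, config$min_size)
        offspring[[i]] <- new_ind(b)
        i <- i + 1L
      }
    }
    combined <- c(pop, offspring)
    nd <- fast_nondominated_sort(objmat(combined))
    om <- objmat(combined)
    keep <- integer(0)
    for (f in nd$fronts) {
      if (length(keep) + length(f) <= np) {
        keep <- c(keep, f)
      } else {
        cd <- crowding_distance(om[f, , drop = FALSE])
        need <- np - length(keep)
        keep <- c(keep, f[order(cd, decreasing = TRUE)[seq_len(need)]])
        break
      }
    }
    pop <- combined[keep]
    rc <- rank_pop(pop)
  }

  # final rank-1 front, de-duplicated, truncated by crowding
  front <- pop[rc$fronts[[1]]]
  keys <- vapply(front, function(x) bits_key(x$bits), character(1))
  front <- front[!duplicated(keys)]
  cap <- ceiling(config$pareto_fraction * np)
  if (length(front) > cap) {
    cd <- crowding_distance(objmat(front))
    front <- front[order(cd, decreasing = TRUE)[seq_len(cap)]]
  }
  pareto_tibble(front)
}

pareto_tibble <- function(front) {
  om <- do.call(rbind, lapply(front, `[[`, "obj"))
  colnames(om) <- paste0("f", seq_len(ncol(om)))
  out <- tibble::as_tibble(as.data.frame(om))
  out <- dplyr::bind_cols(
    tibble::tibble(solution_id = seq_along(front),
                   size = vapply(front, function(x) sum(x$bits), numeric(1))),
    out
  )
  out$distance_to_ideal <- sqrt(rowSums(om^2))
  out$bits <- lapply(front, `[[`, "bits")
  class(out) <- c("dnb_pareto", class(out))
  out
}
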