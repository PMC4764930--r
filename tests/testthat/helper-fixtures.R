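# Shared fixtures and independent oracles for the suite.

# Small random dataset built directly from tibbles.
make_random_dataset <- function(n = 10, T = 2, k_case = 5, k_ctrl = 4,
                                seed = 1) {
  withr::with_seed(seed, {
    ids <- character(0)
    meta <- list()
    for (t in seq_len(T)) {
      for (grp in c("case", "control")) {
        k <- if (grp == "case") k_case else k_ctrl
        s <- sprintf("t%d_%s_%d", t, grp, seq_len(k))
        ids <- c(ids, s)
        meta[[length(meta) + 1]] <- tibble::tibble(
          sample_id = s, time_hours = t, group = grp)
      }
    }
    expr <- tibble::as_tibble(
      as.data.frame(matrix(rnorm(n * length(ids), mean = 5),
                           n, length(ids), dimnames = list(NULL, ids))))
    expr <- dplyr::bind_cols(tibble::tibble(gene = sprintf("g%02d", 1:n)), expr)
    dnb_dataset(expr, dplyr::bind_rows(meta))
  })
}

# Brute-force double-loop composite-index oracle.
oracle_composite <- function(mat, idx, eps = 1e-8) {
  n <- nrow(mat)
  out <- setdiff(seq_len(n), idx)
  rin <- c()
  for (i in idx) for (j in idx) if (i < j) {
    rin <- c(rin, abs(cor(mat[i, ], mat[j, ])))
  }
  rout <- c()
  for (i in idx) for (j in out) {
    rout <- c(rout, abs(cor(mat[i, ], mat[j, ])))
  }
  sds <- sapply(idx, function(i) sd(mat[i, ]))
  list(sd_in = mean(sds), pcc_in = mean(rin), pcc_out = mean(rout),
       index = mean(sds) * mean(rin) / max(mean(rout), eps))
}

# Definition-based non-dominated sorting: peel off the set of points not
# dominated by any remaining point.
oracle_fronts <- function(obj) {
  obj <- as.matrix(obj)
  remaining <- seq_len(nrow(obj))
  fronts <- list()
  dom <- function(a, b) all(a <= b) && any(a < b)
  while (length(remaining) > 0) {
    nd <- remaining[sapply(remaining, function(i) {
      !any(sapply(remaining, function(j) {
        j != i && dom(obj[j, ], obj[i, ])
      }))
    })]
    fronts[[length(fronts) + 1]] <- nd
    remaining <- setdiff(remaining, nd)
  }
  fronts
}

# Exact Wilcoxon-Mann-Whitney p by full enumeration of rank arrangements
# (tie-free samples only).
oracle_wmw_exact <- function(x, y, alternative = "less") {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  all_u <- apply(utils::combn(n + m, n), 2, function(pos) {
    sum(seq_len(n + m)[pos]) - n * (n + 1) / 2
  })
  if (alternative == "less") {
    mean(all_u <= u_obs)
  } else {
    mu <- n * m / 2
    mean(abs(all_u - mu) >= abs(u_obs - mu))
  }
}

# Log-space hypergeometric right tail, written independently of phyper.
oracle_hyper_tail <- function(N, K, n, k) {
  j <- k:min(n, K)
  terms <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  mx <- max(terms)
  exp(mx) * sum(exp(terms - mx))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
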