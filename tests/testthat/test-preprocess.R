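test_that("probe aggregation averages mapped probes and drops the rest", {
  probes <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                       s1 = c(2, 4, 7, 1), s2 = c(1, 3, 9, 2))
  map <- data.frame(probe_id = c("p1", "p2", "p3"),
                    gene_symbol = c("G", "G", "H"))
  out <- aggregate_probes(probes, map)
  expect_equal(out$gene, c("G", "H"))       # lexicographic
  expect_equal(out$s1, c(3, 7))             # mean of p1,p2; identity for p3
  expect_equal(out$s2, c(2, 9))
  expect_false("p4" %in% out$gene)          # unmapped probe screened out

  map_blank <- data.frame(probe_id = "p4", gene_symbol = "")
  expect_error(aggregate_probes(probes, map_blank), "no probe maps")
})

test_that("moderated t-test recovers Welch at s0 = 0 and shrinks otherwise", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  ours <- modified_t_test(x, y, s0 = 0)
  ref <- t.test(x, y, var.equal = FALSE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)

  same <- modified_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  shrunk <- modified_t_test(x, y, s0 = 0.5)
  expect_lt(abs(shrunk$t), abs(ours$t))

  expect_error(modified_t_test(c(1, 1), c(2, 2), s0 = 0), "zero variance")
})

test_that("FDR adjustment implements the BH step-up", {
  expect_equal(fdr_adjust(rep(0.03, 7)), rep(0.03, 7))
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- withr::with_seed(1, runif(100)^2)
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))
})

# 20-gene fixture: 5 genes with a clean 3-fold case shift and tight variance,
# 15 background genes with no shift. The filter's survivors are unambiguous.
make_de_fixture <- function(seed = 11) {
  withr::with_seed(seed, {
    n <- 20; k <- 10
    planted <- paste0("g", 1:5)
    build <- function(t) {
      ctrl <- matrix(rnorm(n * k, mean = 10, sd = 0.5), n, k)
      case <- matrix(rnorm(n * k, mean = 10, sd = 0.5), n, k)
      case[1:5, ] <- matrix(rnorm(5 * k, mean = 30, sd = 0.5), 5, k)
      list(case = case, ctrl = ctrl)
    }
    mats <- lapply(1:2, build)
    ids <- c(outer(sprintf("t%d", 1:2),
                   c(sprintf("case_%d", 1:k), sprintf("ctrl_%d", 1:k)),
                   paste, sep = "_"))
    expr <- cbind(mats[[1]]$case, mats[[1]]$ctrl, mats[[2]]$case, mats[[2]]$ctrl)
    expr_df <- dplyr::bind_cols(tibble::tibble(gene = paste0("g", 1:n)),
                                tibble::as_tibble(as.data.frame(expr)))
    names(expr_df)[-1] <- ids
    meta <- tibble::tibble(
      sample_id = ids,
      time_hours = rep(1:2, each = 2 * k),
      group = rep(rep(c("case", "control"), each = k), 2)
    )
    list(dataset = dnb_dataset(expr_df, meta), planted = planted)
  })
}

test_that("the informative-gene filter keeps exactly the planted DE genes", {
  fix <- make_de_fixture()
  de <- informative_gene_filter(fix$dataset)
  expect_setequal(de$genes, fix$planted)
  st <- tidy(de)
  expect_true(all(st$q_value >= st$p_value))
  expect_true(all(st$fold_change > 0))

  # significant-but-small changes are removed by the fold-change rule:
  # planted rows pass both rules, background q-values are large AND fc ~ 1
  bg <- st[!(st$gene %in% fix$planted), ]
  expect_true(all(bg$fold_change > 0.5 & bg$fold_change < 2))
})

test_that("filtering is idempotent", {
  fix <- make_de_fixture()
  de1 <- informative_gene_filter(fix$dataset)
  de2 <- informative_gene_filter(subset_genes(fix$dataset, de1$genes))
  expect_equal(de2$genes, de1$genes)
})

test_that("control-referenced normalization matches its definition", {
  ds <- make_random_dataset(n = 12, T = 2, k_case = 6, k_ctrl = 5, seed = 9)
  norm <- normalize_to_controls(ds)
  expect_true(norm$normalized)
  for (t in 1:2) {
    mu <- rowMeans(ds$control[[t]])
    sdv <- apply(ds$control[[t]], 1, sd)
    expect_equal(norm$case[[t]], (ds$case[[t]] - mu) / sdv)
    # the same transform applied to the controls standardizes them
    z <- (ds$control[[t]] - mu) / sdv
    expect_equal(unname(rowMeans(z)), rep(0, 12), tolerance = 1e-12)
    expect_equal(unname(apply(z, 1, sd)), rep(1, 12), tolerance = 1e-12)
  }

  # shift-invariance: adding a constant to case and control of a gene
  shifted <- ds
  shifted$case[[1]][3, ] <- shifted$case[[1]][3, ] + 100
  shifted$control[[1]][3, ] <- shifted$control[[1]][3, ] + 100
  norm2 <- normalize_to_controls(shifted)
  expect_equal(norm2$case[[1]][3, ], norm$case[[1]][3, ], tolerance = 1e-10)

  flat <- ds
  flat$control[[2]][5, ] <- 7
  expect_error(normalize_to_controls(flat), "'g05' at t = 2")
})
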