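test_that("pearson_corr matches the closed form and guards zero variance", {
  u <- c(1, 2, 3, 4); v <- c(1, 2, 3, 5)
  manual <- sum((u - mean(u)) * (v - mean(v))) /
    sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  expect_equal(pearson_corr(u, v), manual, tolerance = 1e-12)
  expect_equal(pearson_corr(u, u), 1)
  expect_equal(pearson_corr(u, -u), -1)
  expect_error(pearson_corr(u, c(1, 2)), "length")
  expect_warning(r0 <- pearson_corr(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_equal(r0, 0)
})

test_that("subset correlation averages match the brute-force double loop", {
  for (seed in 1:5) {
    mat <- withr::with_seed(seed, matrix(rnorm(30 * 8), 30, 8))
    idx <- withr::with_seed(seed + 100, sort(sample(30, 6)))
    o <- oracle_composite(mat, idx)
    expect_equal(intra_class_corr(mat, idx), o$pcc_in, tolerance = 1e-12)
    expect_equal(inter_class_corr(mat, idx), o$pcc_out, tolerance = 1e-12)
    expect_equal(mean_sd(mat, idx), o$sd_in, tolerance = 1e-12)
    expect_equal(composite_from_matrix(mat, idx)$index, o$index,
                 tolerance = 1e-12)
  }
})

test_that("degenerate subset inputs behave as specified", {
  mat <- matrix(c(1, 2, 3, 1, 2, 3, 5, 1, 4), 3, 3, byrow = TRUE)
  expect_equal(intra_class_corr(mat, c(1, 2)), 1)   # duplicated gene rows
  expect_error(intra_class_corr(mat, 1), ">= 2")
  expect_error(inter_class_corr(mat, 1:3), "complement")
  two <- rbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(inter_class_corr(two, 1), 1)
  expect_equal(mean_sd(rbind(rep(2, 4)), 1), 0)
  expect_equal(mean_sd(rbind(c(1, 2, 3)), 1), 1)
})

test_that("correlation criteria are invariant to sample order and affine maps", {
  mat <- withr::with_seed(4, matrix(rnorm(10 * 6), 10, 6))
  idx <- c(2, 5, 9)
  perm <- withr::with_seed(5, sample(6))
  expect_equal(intra_class_corr(mat[, perm], idx), intra_class_corr(mat, idx))
  expect_equal(inter_class_corr(mat[, perm], idx), inter_class_corr(mat, idx))
  aff <- mat
  aff[3, ] <- 2.5 * aff[3, ] + 7   # positive-slope affine on one gene
  expect_equal(intra_class_corr(aff, idx), intra_class_corr(mat, idx),
               tolerance = 1e-12)
  expect_equal(inter_class_corr(aff, idx), inter_class_corr(mat, idx),
               tolerance = 1e-12)
})

test_that("composite index obeys its algebraic identities", {
  # all four genes identical: pcc_in = pcc_out = 1, so I = sd_in
  u <- c(0, 4, 8)   # sample SD = 4
  mat <- rbind(u, u, u, u)
  expect_equal(composite_from_matrix(mat, 1:2)$index, 4, tolerance = 1e-12)

  # scaling the subset genes by c > 0 scales I by exactly c
  mat2 <- withr::with_seed(8, matrix(rnorm(20 * 10), 20, 10))
  idx <- 1:5
  i1 <- composite_from_matrix(mat2, idx)$index
  mat2[idx, ] <- 3.7 * mat2[idx, ]
  expect_equal(composite_from_matrix(mat2, idx)$index, 3.7 * i1,
               tolerance = 1e-10)
})

test_that("adding an outside copy of a subset gene weakly decreases I", {
  mat <- withr::with_seed(10, matrix(rnorm(8 * 12), 8, 12))
  idx <- 1:3
  base <- composite_from_matrix(mat, idx)
  withcopy <- rbind(mat, mat[2, ])
  after <- composite_from_matrix(withcopy, idx)
  expect_gte(after$pcc_out, base$pcc_out)
  expect_lte(after$index, base$index)
})

test_that("objectives transform the two composite indices as designed", {
  # all genes identical up to scale: I_t = sd at t; arrange I_2 = 4, I_1 = 0.5
  base <- c(0, 1, 2)  # SD 1
  mk <- function(s) rbind(s * base, s * base, s * base, s * base)
  expr <- dplyr::bind_cols(
    tibble::tibble(gene = paste0("g", 1:4)),
    tibble::as_tibble(as.data.frame(cbind(mk(0.5), mk(4))))
  )
  names(expr)[-1] <- c(paste0("a", 1:3), paste0("b", 1:3))
  meta <- tibble::tibble(sample_id = names(expr)[-1],
                         time_hours = rep(1:2, each = 3),
                         group = "case")
  ds <- dnb_dataset(expr, meta)
  ob <- dnb_objectives(ds, 1:2, t = 2)
  expect_equal(unname(ob), c(1 / (1 + 4), 0.5), tolerance = 1e-12)
  expect_error(dnb_objectives(ds, 1:2, t = 1), "preceding")

  # pure function: repeated calls agree exactly
  ds2 <- normalize_to_controls(make_random_dataset(n = 15, seed = 21))
  bits <- ds2$genes %in% c("g02", "g07", "g11")
  expect_identical(dnb_objectives(ds2, bits, 2), dnb_objectives(ds2, bits, 2))
})

test_that("the fast evaluator agrees with the definitional computation", {
  mat <- withr::with_seed(13, matrix(rnorm(40 * 9), 40, 9))
  st <- time_stats(mat)
  for (seed in 1:5) {
    idx <- withr::with_seed(seed, sort(sample(40, sample(2:10, 1))))
    expect_equal(index_from_stats(st, idx),
                 composite_from_matrix(mat, idx)$index, tolerance = 1e-12)
  }
})
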