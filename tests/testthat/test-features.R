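test_that("column_means and marginal sums follow their definitions", {
  m0 <- pssm_matrix("Z", matrix(0, 5L, 20L))
  expect_equal(unname(column_means(m0)), rep(0, 20L))

  M <- matrix(stats::runif(40), 2L, 20L)
  M[, 1L] <- c(0.2, 0.6)
  m <- pssm_matrix("P", M)
  expect_equal(unname(column_means(m)[1L]), 0.4)

  M2 <- matrix(3, 4L, 20L); M2[, 7L] <- 9
  expect_equal(unname(column_means(pssm_matrix("C", M2))[7L]), 9)

  ms <- marginal_sums(m)
  expect_equal(sum(ms$row_sums), sum(ms$col_sums))
  expect_equal(sum(ms$row_sums), sum(M))
})

test_that("dimension law holds across the xi sweep for every encoder", {
  m <- rand_pssm("P", 50L, seed = 3)
  for (xi in 1:15) {
    expect_length(psepssm(m, xi), 20L + 20L * xi)
    imlen <- (20L + 20L * xi) - xi * (xi + 1L) / 2L
    expect_length(im_psepssm(m, xi), imlen)
    expect_length(t1_im_pssm(m, xi), imlen)
    expect_length(t2_im_pssm(m, xi), imlen)
    expect_length(t3_im_pssm(m, xi), imlen)
    expect_identical(feature_dimension("im_psepssm", xi = xi),
                     as.integer(imlen))
  }
  for (S in c(1L, 5L, 29L)) expect_length(bid_cc(m, S), 400L)
})

test_that("encoders agree with naive loop oracles to 1e-10", {
  set.seed(20240915)
  for (trial in 1:100) {
    M <- matrix(stats::runif(30L * 20L, -5, 5), 30L, 20L)
    m <- pssm_matrix(sprintf("T%03d", trial), M)
    xi <- sample(1:6, 1L)
    S <- sample(1:8, 1L)
    expect_equal(unname(psepssm(m, xi)$values), naive_psepssm(M, xi),
                 tolerance = 1e-10)
    expect_equal(unname(im_psepssm(m, xi)$values), naive_im(M, xi),
                 tolerance = 1e-10)
    expect_equal(unname(t1_im_pssm(m, xi)$values), naive_t1(M, xi),
                 tolerance = 1e-10)
    expect_equal(unname(t2_im_pssm(m, xi)$values), naive_t2(M, xi),
                 tolerance = 1e-10)
    expect_equal(unname(t3_im_pssm(m, xi)$values), naive_t3(M, xi),
                 tolerance = 1e-10)
    expect_equal(unname(bid_cc(m, S)$values), naive_bidcc(M, S),
                 tolerance = 1e-10)
  }
})

test_that("alternative normalisation prefactors match their oracles", {
  M <- matrix(stats::runif(25L * 20L, -3, 3), 25L, 20L)
  m <- pssm_matrix("N", M)
  expect_equal(unname(im_psepssm(m, 4L, norm = "max_lag")$values),
               naive_im(M, 4L, "max_lag"), tolerance = 1e-12)
  expect_equal(unname(im_psepssm(m, 4L, norm = "global")$values),
               naive_im(M, 4L, "global"), tolerance = 1e-12)
})

test_that("trivial structural cases behave as the formulas dictate", {
  # identical rows: every sequence-lag difference vanishes
  M <- matrix(rep(stats::runif(20L), each = 10L), 10L, 20L)
  expect_equal(unname(psepssm(pssm_matrix("R", M), 4L)$values[21:100]),
               rep(0, 80L))
  # identical columns: every column-lag difference vanishes
  Mc <- matrix(rep(stats::runif(10L), 20L), 10L, 20L)
  v <- im_psepssm(pssm_matrix("C", Mc), 5L)$values
  expect_equal(unname(v[-(1:20)]), rep(0, length(v) - 20L))
  # all-ones matrix, global norm 1/L: every T1 cross term is exactly 1
  ones <- pssm_matrix("O", matrix(1, 8L, 20L))
  t1v <- t1_im_pssm(ones, 3L, norm = "global")$values
  expect_equal(unname(t1v[-(1:20)]), rep(1, length(t1v) - 20L))
  # constant matrix c: T2 centre is 20c, factor norm(d)*L*(c-20c)^2 != 0
  cc <- 0.3; L <- 6L
  t2v <- t2_im_pssm(pssm_matrix("K", matrix(cc, L, 20L)), 2L)$values
  for (d in 1:2)
    expect_equal(unname(t2v[20L + sum(20 - seq_len(d - 1)) + 1L]),
                 L * (cc - 20 * cc)^2 / (L - d), tolerance = 1e-12)
  # constant matrix: T3 centre is L*c
  t3v <- t3_im_pssm(pssm_matrix("K", matrix(cc, L, 20L)), 1L)$values
  expect_equal(unname(t3v[21L]), L * (cc - L * cc)^2 / (L - 1L),
               tolerance = 1e-12)
  # L = 3, S = 1, all ones: two summands of 1*1 in every cross term
  b <- bid_cc(pssm_matrix("B", matrix(1, 3L, 20L)), 1L)
  expect_equal(unname(b$values), rep(2, 400L))
  # all-zero matrix: Bid-CC identically zero
  expect_equal(unname(bid_cc(pssm_matrix("Z", matrix(0, 5L, 20L)), 2L)$values),
               rep(0, 400L))
})

test_that("translation behaviour: im invariant to constant shift, t1 not", {
  m <- rand_pssm("P", 30L, seed = 11)
  shifted <- pssm_matrix("P", m$scores + 3.7)
  im1 <- im_psepssm(m, 5L)$values[-(1:20)]
  im2 <- im_psepssm(shifted, 5L)$values[-(1:20)]
  expect_equal(unname(im1), unname(im2), tolerance = 1e-10)
  t1a <- t1_im_pssm(m, 5L)$values[-(1:20)]
  t1b <- t1_im_pssm(shifted, 5L)$values[-(1:20)]
  expect_gt(max(abs(t1a - t1b)), 1e-3)
})

test_that("permuting PSSM columns permutes the means block identically", {
  m <- rand_pssm("P", 25L, seed = 5)
  perm <- sample(20L)
  mp <- pssm_matrix("P", m$scores[, perm])
  expect_equal(unname(im_psepssm(mp, 3L)$values[1:20]),
               unname(im_psepssm(m, 3L)$values[perm]))
})

test_that("feature width is independent of protein length", {
  short <- rand_pssm("S", 25L, seed = 8)
  long <- rand_pssm("L", 500L, seed = 9)
  expect_equal(length(im_psepssm(short, 13L)), length(im_psepssm(long, 13L)))
  expect_equal(length(bid_cc(short, 3L)), length(bid_cc(long, 3L)))
  expect_equal(length(psepssm(short, 13L)), length(psepssm(long, 13L)))
})

test_that("parameter preconditions are enforced", {
  m <- rand_pssm("P", 10L, seed = 1)
  expect_error(psepssm(m, 10L), "smaller than sequence length")
  expect_error(im_psepssm(m, 20L), "xi")
  expect_error(bid_cc(m, 10L), "smaller than sequence length")
  expect_error(bid_cc(m, 0L), "positive")
})

test_that("fuse concatenates in order and checks protein identity", {
  m <- rand_pssm("P1", 30L, seed = 4)
  im <- im_psepssm(m, 13L)
  cc <- bid_cc(m, 1L)
  fused <- fuse(list(im, cc))
  expect_length(fused, 189L + 400L)
  expect_equal(fused$encoder, "bim_pssm")
  expect_equal(unname(fused$values), unname(c(im$values, cc$values)))
  single <- fuse(list(im))
  expect_equal(unname(single$values), unname(im$values))
  other <- bid_cc(rand_pssm("P2", 30L, seed = 6), 1L)
  expect_error(fuse(list(im, other)), "different proteins")
})

test_that("encode_collection is stable, constant-width and names offenders", {
  set.seed(10)
  ms <- list(rand_pssm("A", 40L), rand_pssm("B", 60L), rand_pssm("C", 35L))
  X <- encode_collection(ms, "bim_pssm", xi = 2L, S = 1L)
  expect_equal(rownames(X), c("A", "B", "C"))
  expect_equal(ncol(X), feature_dimension("bim_pssm", xi = 2L, S = 1L))
  expect_equal(ncol(X), 457L)  # 57 column-lag features + 400 cross terms
  expect_equal(feature_dimension("im_psepssm", xi = 2L), 57L)
  # a protein too short for the parameters is reported by id
  ms[[2L]] <- rand_pssm("B", 3L)
  expect_error(encode_collection(ms, "bim_pssm", xi = 2L, S = 5L),
               "protein 'B'")
})

test_that("feature CSV round-trips with names and ids", {
  set.seed(12)
  ms <- list(rand_pssm("A", 30L), rand_pssm("B", 30L))
  X <- encode_collection(ms, "im_psepssm", xi = 3L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(X, f)
  back <- read_feature_csv(f)
  expect_equal(back$X, X, tolerance = 1e-12)
})
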