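test_that("entropy of binary labels", {
  expect_equal(entropy(c(1, 1, 0, 0)), 1.0)
  expect_equal(entropy(c(1, 1, 1, 1)), 0.0)
  # 10 cases + 9 controls, hand formula
  expect_equal(entropy(c(rep(1, 10), rep(0, 9))), 0.9980008838723,
               tolerance = 1e-12)
  expect_error(entropy(integer(0)))
})

test_that("conditional entropy brackets and known values", {
  expect_equal(conditional_entropy(c(1L, 1L, 0L, 0L), c(1L, 1L, 0L, 0L)), 0)
  y <- c(rep(1L, 7), rep(0L, 5))
  expect_equal(conditional_entropy(y, rep(2L, 12)), entropy(y))
  # each genotype stratum 50/50
  expect_equal(conditional_entropy(c(1L, 1L, 0L, 0L), c(0L, 1L, 0L, 1L)), 1.0)
  expect_error(conditional_entropy(y, rep(NA_integer_, 12)))
})

test_that("mutual information identities", {
  y <- c(1L, 1L, 0L, 0L)
  expect_equal(mutual_information(y, y), entropy(y))
  # fully crossed independent design
  expect_equal(mutual_information(c(0L, 1L, 0L, 1L), y), 0)
  # B constant: composite collapses to A
  a <- c(0L, 1L, 2L, 0L, 1L, 2L)
  yy <- c(1L, 1L, 0L, 0L, 1L, 0L)
  expect_equal(joint_mutual_information(a, rep(1L, 6), yy),
               mutual_information(a, yy))
  # A == B == C
  z <- c(0L, 1L, 0L, 1L)
  expect_equal(joint_mutual_information(z, z, z), entropy(z))
})

test_that("XOR design: pure synergy of 1 bit, full redundancy of -1 bit", {
  a <- c(0L, 0L, 1L, 1L); b <- c(0L, 1L, 0L, 1L); y <- c(0L, 1L, 1L, 0L)
  expect_equal(mutual_information(a, y), 0, tolerance = 1e-12)
  expect_equal(mutual_information(b, y), 0, tolerance = 1e-12)
  expect_equal(joint_mutual_information(a, b, y), 1, tolerance = 1e-12)
  expect_equal(pairwise_information_gain(a, b, y), 1, tolerance = 1e-12)
  # B a copy of A, C == A: 1 - 1 - 1
  expect_equal(pairwise_information_gain(a, a, a), -1, tolerance = 1e-12)
})

test_that("fast implementations match the brute-force oracle on random instances", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(5:200, 1)
    a <- sample(0:2, n, replace = TRUE)
    b <- sample(0:2, n, replace = TRUE)
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    # absolute agreement: tiny scores make relative tolerance meaningless
    expect_lt(abs(entropy(y) - oracle_entropy(y)), 1e-12)
    expect_lt(abs(conditional_entropy(y, a) - oracle_cond_entropy(y, a)),
              1e-12)
    expect_lt(abs(mutual_information(a, y) - oracle_mi(a, y)), 1e-12)
    expect_lt(abs(joint_mutual_information(a, b, y) -
                    oracle_joint_mi(a, b, y)), 1e-12)
    expect_lt(abs(pairwise_information_gain(a, b, y) - oracle_ig(a, b, y)),
              1e-12)
  }
})

test_that("information measures respect their analytic inequalities", {
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(20:120, 1)
    a <- sample(0:2, n, replace = TRUE)
    b <- sample(0:2, n, replace = TRUE)
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    expect_gte(mutual_information(a, y), -1e-12)
    expect_lte(conditional_entropy(y, a), entropy(y) + 1e-12)
    jmi <- joint_mutual_information(a, b, y)
    expect_gte(jmi, max(mutual_information(a, y),
                        mutual_information(b, y)) - 1e-12)
    # symmetry of IG in its variant arguments
    expect_equal(pairwise_information_gain(a, b, y),
                 pairwise_information_gain(b, a, y), tolerance = 1e-12)
    # invariance under relabelling genotype categories
    perm <- sample(0:2)
    expect_equal(mutual_information(perm[a + 1], y),
                 mutual_information(a, y), tolerance = 1e-12)
    expect_equal(pairwise_information_gain(perm[a + 1], b, y),
                 pairwise_information_gain(a, b, y), tolerance = 1e-12)
  }
})

test_that("all-pairs scoring is symmetric, complete and oracle-consistent", {
  ds <- random_dataset(60, 6, seed = 9)
  ps <- all_pairs_information_gain(ds)
  expect_identical(ps$variant_ids, colnames(ds$genotypes))
  expect_true(all(is.na(diag(ps$ig))))
  expect_equal(ps$ig, t(ps$ig))
  expect_identical(nrow(pair_table(ps)), 15L)  # choose(6, 2)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(ps$ig[i, j],
                 oracle_ig(ds$genotypes[, i], ds$genotypes[, j],
                           ds$phenotype),
                 tolerance = 1e-12)
  }
})

test_that("the XOR pair dominates noise and scores are permutation-equivariant", {
  set.seed(12)
  n <- 400
  a <- sample(0:1, n, replace = TRUE)
  b <- sample(0:1, n, replace = TRUE)
  y <- as.integer(xor(a, b))
  noise <- sample(0:2, n, replace = TRUE)
  g <- cbind(A = a, B = b, N = noise)
  rownames(g) <- paste0("S", 1:n)
  ds <- geno_dataset(g, y)
  ps <- all_pairs_information_gain(ds)
  pt <- pair_table(ps)
  top <- pt[which.max(pt$ig), ]
  expect_setequal(c(top$variant_a, top$variant_b), c("A", "B"))
  # permuting variant order relabels but does not change scores
  ds2 <- subset_dataset(ds, variants = c(3, 1, 2))
  ps2 <- all_pairs_information_gain(ds2)
  expect_equal(ps2$ig["A", "B"], ps$ig["A", "B"])
  expect_equal(ps2$ig["N", "A"], ps$ig["A", "N"])
})

test_that("pairwise-complete deletion drops only rows missing in the pair", {
  a <- c(0L, 1L, NA, 2L, 1L, 0L)
  b <- c(1L, 1L, 0L, NA, 2L, 0L)
  y <- c(1L, 0L, 1L, 0L, 1L, 0L)
  keep <- !is.na(a) & !is.na(b)
  expect_equal(pairwise_information_gain(a, b, y),
               oracle_ig(a[keep], b[keep], y[keep]), tolerance = 1e-12)
})
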