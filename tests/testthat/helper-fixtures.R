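# Small fixtures built in code.

# 4 subjects x 3 variants with a phenotype column.
fixture_small <- function() {
  g <- matrix(c(0L, 1L, 2L, 0L,
                1L, 1L, 0L, 2L,
                2L, 0L, 1L, 1L), nrow = 4,
              dimnames = list(paste0("S", 1:4), c("rs1", "rs2", "rs3")))
  geno_dataset(g, c(1L, 1L, 0L, 0L))
}

write_small_csv <- function(path) {
  writeLines(c("subject_id,rs1,rs2,rs3,phenotype",
               "S1,0,1,2,1",
               "S2,1,1,0,1",
               "S3,2,0,1,0",
               "S4,0,2,1,0"), path)
  path
}

write_small_raw <- function(path) {
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE rs1_A rs2_C rs3_G",
               "F1 S1 0 0 1 2 0 1 2",
               "F2 S2 0 0 2 2 1 1 0",
               "F3 S3 0 0 1 1 2 0 1",
               "F4 S4 0 0 2 1 0 2 1"), path)
  path
}

# 19-subject, 3-variant dataset with 10 cases / 9 controls: the class
# sizes that make the control-count weight exactly 10/9.
fixture_unbalanced <- function(seed = 5) {
  set.seed(seed)
  g <- matrix(sample(0:2, 19 * 3, replace = TRUE), nrow = 19,
              dimnames = list(sprintf("S%02d", 1:19),
                              c("rsA", "rsB", "rsC")))
  geno_dataset(g, c(rep(1L, 10), rep(0L, 9)))
}

# pair_scores object built directly from a named symmetric matrix
scores_from_matrix <- function(m) {
  structure(list(variant_ids = colnames(m), ig = m), class = "pair_scores")
}

# random complete genotype dataset with labels, for property tests
random_dataset <- function(n, m, seed) {
  set.seed(seed)
  g <- matrix(sample(0:2, n * m, replace = TRUE), nrow = n,
              dimnames = list(paste0("S", seq_len(n)),
                              paste0("V", seq_len(m))))
  geno_dataset(g, c(rep(1L, ceiling(n / 2)),
                    rep(0L, floor(n / 2)))[sample.int(n)])
}
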