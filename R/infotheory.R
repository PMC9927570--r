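# Entropy-based association scores for case-control genotypes, in bits.
# All probabilities are plug-in (observed-frequency) estimates with the
# 0 * log(1/0) := 0 convention; no pseudocounts.

plogp <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Mutual information from a joint count table (rows = one variable's
# categories, cols = the other's).
mi_from_counts <- function(tab) {
  n <- sum(tab)
  if (n == 0) return(0)
  p <- tab / n
  plogp(rowSums(p)) + plogp(colSums(p)) - plogp(p)
}

#' Shannon entropy of a label vector (bits)
#'
#' @param labels Vector of discrete labels (for a phenotype, 0/1).
#' @return Entropy in bits; in \[0, 1\] for a binary vector.
#' @export
entropy <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (!length(labels)) stop("entropy of an empty vector is undefined")
  plogp(table(labels) / length(labels))
}

#' Conditional entropy H(C | A) in bits
#'
#' Uncertainty left in the phenotype once a single variant's genotype is
#' known. Rows with a missing genotype are dropped (pairwise-complete).
#'
#' @param labels Phenotype vector (0/1).
#' @param genotypes Genotype code vector of equal length.
#' @return H(C|A) in bits; always between 0 and H(C).
#' @export
conditional_entropy <- function(labels, genotypes) {
  stopifnot(length(labels) == length(genotypes))
  keep <- !is.na(genotypes) & !is.na(labels)
  if (!any(keep)) stop("no complete observations")
  a <- genotypes[keep]
  c_ <- labels[keep]
  tab <- table(a, c_)
  # H(C|A) = H(A,C) - H(A)
  plogp(tab / sum(tab)) - plogp(rowSums(tab) / sum(tab))
}

#' Mutual information I(A; C) between a variant and the phenotype (bits)
#'
#' @inheritParams conditional_entropy
#' @return I(A;C) = H(C) - H(C|A), non-negative up to floating error.
#' @export
mutual_information <- function(genotypes, labels) {
  stopifnot(length(labels) == length(genotypes))
  keep <- !is.na(genotypes) & !is.na(labels)
  if (!any(keep)) stop("no complete observations")
  mi_from_counts(table(genotypes[keep], labels[keep]))
}

#' Joint mutual information I(A, B; C) of a variant pair (bits)
#'
#' The ordered genotype pair (a, b) is treated as one composite variable
#' with up to nine categories. Rows missing either genotype are dropped.
#'
#' @param genotypes_a,genotypes_b Genotype code vectors.
#' @param labels Phenotype vector (0/1).
#' @return I(A,B;C) in bits.
#' @export
joint_mutual_information <- function(genotypes_a, genotypes_b, labels) {
  stopifnot(length(genotypes_a) == length(genotypes_b),
            length(genotypes_a) == length(labels))
  keep <- !is.na(genotypes_a) & !is.na(genotypes_b) & !is.na(labels)
  if (!any(keep)) stop("no complete observations")
  ab <- interaction(genotypes_a[keep], genotypes_b[keep], drop = TRUE)
  mi_from_counts(table(ab, labels[keep]))
}

#' Pairwise information gain IG(A; B; C) (bits)
#'
#' The synergy of a variant pair: the phenotype information carried by the
#' pair jointly beyond the sum of what each variant carries alone,
#' IG = I(A,B;C) - I(A;C) - I(B;C). Positive values indicate epistatic
#' synergy; negative values indicate redundancy and are returned as-is.
#' All three terms are computed on the same pairwise-complete rows.
#'
#' @inheritParams joint_mutual_information
#' @return IG in bits (may be negative).
#' @export
pairwise_information_gain <- function(genotypes_a, genotypes_b, labels) {
  stopifnot(length(genotypes_a) == length(genotypes_b),
            length(genotypes_a) == length(labels))
  keep <- !is.na(genotypes_a) & !is.na(genotypes_b) & !is.na(labels)
  if (!any(keep)) stop("no complete observations")
  ga <- genotypes_a[keep]; gb <- genotypes_b[keep]; y <- labels[keep]
  ig_from_vectors(ga, gb, y)
}

# Core IG computation on complete 0/1/2 vectors and a 0/1 label.
ig_from_vectors <- function(ga, gb, y) {
  idx <- 3L * ga + gb + 9L * y + 1L            # 1..18
  cnt <- tabulate(idx, nbins = 18L)
  tab <- array(cnt, dim = c(3L, 3L, 2L))       # [b+1, a+1, y+1]
  n <- sum(tab)
  p <- tab / n
  pj <- matrix(p, nrow = 9L)                   # 9 x 2 composite table
  pa <- apply(tab, 2L, sum) / n                # marginal over A (cols)
  pb <- apply(tab, 1L, sum) / n
  pc <- apply(tab, 3L, sum) / n
  pac <- apply(tab, c(2L, 3L), sum) / n
  pbc <- apply(tab, c(1L, 3L), sum) / n
  hc <- plogp(pc)
  i_ab_c <- plogp(rowSums(pj)) + hc - plogp(pj)
  i_a_c <- plogp(pa) + hc - plogp(pac)
  i_b_c <- plogp(pb) + hc - plogp(pbc)
  i_ab_c - i_a_c - i_b_c
}

#' Information gain for every unordered variant pair
#'
#' Scores all m(m-1)/2 variant pairs of a dataset with
#' [pairwise_information_gain()]. Rows with a missing genotype at either
#' member of a pair are dropped for that pair only.
#'
#' @param dataset A [geno_dataset] with at least two variants.
#' @return An object of class `pair_scores`: a list with `variant_ids` and
#'   `ig`, a symmetric matrix of information-gain values in bits with `NA`
#'   on the diagonal.
#' @export
all_pairs_information_gain <- function(dataset) {
  g <- dataset$genotypes
  y <- dataset$phenotype
  m <- ncol(g)
  if (m < 2L) stop("at least two variants required")
  if (length(unique(y)) < 2L) stop("both phenotype classes must be present")
  audit_record("pair_scores", rownames(g))
  ig <- matrix(NA_real_, m, m, dimnames = list(colnames(g), colnames(g)))
  any_na <- anyNA(g)
  for (a in seq_len(m - 1L)) {
    ga <- g[, a]
    for (b in (a + 1L):m) {
      gb <- g[, b]
      if (any_na) {
        keep <- !is.na(ga) & !is.na(gb)
        val <- ig_from_vectors(ga[keep], gb[keep], y[keep])
      } else {
        val <- ig_from_vectors(ga, gb, y)
      }
      ig[a, b] <- val
      ig[b, a] <- val
    }
  }
  structure(list(variant_ids = colnames(g), ig = ig), class = "pair_scores")
}

#' @export
print.pair_scores <- function(x, ...) {
  m <- length(x$variant_ids)
  cat(sprintf("pair_scores: %d variants, %d pairs; IG range [%.4g, %.4g] bits\n",
              m, m * (m - 1) / 2,
              min(x$ig, na.rm = TRUE), max(x$ig, na.rm = TRUE)))
  invisible(x)
}

#' Flatten pair scores to an edge table
#'
#' @param scores A `pair_scores` object.
#' @return data.frame with `variant_a`, `variant_b`, `ig`, one row per
#'   unordered pair, in column-major upper-triangle order.
#' @export
pair_table <- function(scores) {
  idx <- which(upper.tri(scores$ig), arr.ind = TRUE)
  data.frame(variant_a = scores$variant_ids[idx[, 1]],
             variant_b = scores$variant_ids[idx[, 2]],
             ig = scores$ig[idx], stringsAsFactors = FALSE)
}

#' Write pair scores as a TSV edge list
#'
#' @param scores A `pair_scores` object.
#' @param path Output path.
#' @export
write_pair_scores <- function(scores, path) {
  data.table::fwrite(pair_table(scores), path, sep = "\t")
  invisible(path)
}
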