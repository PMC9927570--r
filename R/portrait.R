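# Subject portraits: per-edge class-conditional genotype-pair proportions
# fitted on training subjects, the chi sign function marking each edge as
# risk- ('+') or protection-enriched ('-') for a subject's genotype pair,
# and the delta-degree feature transform.

edge_key <- function(u, v) paste(u, v, sep = "\r")

#' Fit per-edge class-conditional genotype-pair proportions
#'
#' For every edge (u, v) of the network, tabulates the training subjects'
#' ordered genotype pairs (a_u, a_v) within each phenotype class and
#' converts the counts to within-class proportions: P(a_u, a_v, l) is the
#' fraction of class-l training subjects (with complete data for the pair)
#' carrying that genotype pair. These proportions drive the chi sign
#' function and hence the transform. Subjects missing either genotype of a
#' pair are excluded from that pair's tables only.
#'
#' @param training A [geno_dataset]; both classes must be non-empty.
#' @param network An `epi_network`.
#' @return An object of class `pair_class_stats`: list with `edges` (the
#'   network's edge table), `counts` (per edge, a 3x3x2 count array indexed
#'   by a_u, a_v, class with class 1 = control, 2 = case), `prop` (the
#'   within-class proportions), `n_case`, `n_control`, and `flagged`
#'   (edges where one class had zero complete observations).
#' @export
fit_pair_statistics <- function(training, network) {
  y <- training$phenotype
  n_case <- sum(y == 1L)
  n_control <- sum(y == 0L)
  if (n_case == 0L || n_control == 0L)
    stop("both phenotype classes must be non-empty in the training set")
  g <- training$genotypes
  missing_vars <- setdiff(network$nodes, colnames(g))
  if (length(missing_vars))
    stop("training data lacks network variants: ",
         paste(head(missing_vars, 3), collapse = ", "))
  audit_record("pair_stats", rownames(g))
  et <- network$edges
  counts <- vector("list", nrow(et))
  prop <- vector("list", nrow(et))
  flagged <- character(0)
  for (i in seq_len(nrow(et))) {
    gu <- g[, et$from[i]]
    gv <- g[, et$to[i]]
    keep <- !is.na(gu) & !is.na(gv)
    idx <- gu[keep] + 3L * gv[keep] + 9L * y[keep] + 1L
    cnt <- array(tabulate(idx, nbins = 18L), dim = c(3L, 3L, 2L),
                 dimnames = list(0:2, 0:2, c("control", "case")))
    cls_tot <- apply(cnt, 3L, sum)
    if (any(cls_tot == 0L))
      flagged <- c(flagged, edge_key(et$from[i], et$to[i]))
    pr <- cnt
    for (l in 1:2) pr[, , l] <- if (cls_tot[l] > 0) cnt[, , l] / cls_tot[l] else 0
    counts[[i]] <- cnt
    prop[[i]] <- pr
  }
  keys <- edge_key(et$from, et$to)
  names(counts) <- keys
  names(prop) <- keys
  structure(list(edges = et, counts = counts, prop = prop,
                 n_case = n_case, n_control = n_control, flagged = flagged),
            class = "pair_class_stats")
}

#' @export
print.pair_class_stats <- function(x, ...) {
  cat(sprintf(
    "pair_class_stats: %d edges fitted on %d cases / %d controls\n",
    nrow(x$edges), x$n_case, x$n_control))
  if (length(x$flagged))
    cat(sprintf("  %d edges with an empty class (flagged)\n",
                length(x$flagged)))
  invisible(x)
}

#' Case:control weight for count-based sign comparison
#'
#' The multiplier by which raw control counts are amplified so they are
#' directly comparable with raw case counts under class imbalance:
#' n_case / n_control. Comparing weighted counts is algebraically identical
#' to comparing within-class proportions.
#'
#' @param n_case,n_control Positive class sizes.
#' @return n_case / n_control.
#' @export
class_balance_weight <- function(n_case, n_control) {
  if (n_case <= 0 || n_control <= 0) stop("both classes must be non-empty")
  n_case / n_control
}

# Per-edge 3x3 sign matrix over genotype pairs: +1 for a '+' (risk) cell,
# -1 for a '-' cell, 0 for a zero-evidence cell (or, in literal mode, the
# tie rule "case >= control" applied everywhere, so 0/0 cells are '+').
sign_matrix <- function(stats, key, mode = c("proportion", "count"),
                        zero_evidence = c("absent", "positive")) {
  mode <- match.arg(mode)
  zero_evidence <- match.arg(zero_evidence)
  if (mode == "proportion") {
    pr <- stats$prop[[key]]
    plus <- pr[, , "case"] >= pr[, , "control"]
  } else {
    cnt <- stats$counts[[key]]
    w <- class_balance_weight(stats$n_case, stats$n_control)
    plus <- cnt[, , "case"] >= w * cnt[, , "control"]
  }
  s <- ifelse(plus, 1L, -1L)
  if (zero_evidence == "absent") {
    cnt <- stats$counts[[key]]
    s[cnt[, , "case"] + cnt[, , "control"] == 0L] <- 0L
  }
  s
}

#' Sign of one edge for a genotype pair (chi function)
#'
#' An edge is '+' (risk-enriched) when the within-class proportion of
#' training cases carrying the subject's genotype pair is at least that of
#' controls, and '-' otherwise; ties go to '+'. A genotype pair never
#' observed in training in either class yields `"absent"` by default
#' (`zero_evidence = "positive"` restores the literal tie rule, which
#' marks such cells '+').
#'
#' @param stats A `pair_class_stats` object.
#' @param edge Character vector `c(u, v)` naming a fitted edge (in the
#'   orientation stored in the network).
#' @param a_u,a_v Genotype codes in `{0, 1, 2}`.
#' @param mode `"proportion"` compares within-class proportions;
#'   `"count"` compares raw counts with the [class_balance_weight()]
#'   multiplier. The two are algebraically identical.
#' @param zero_evidence `"absent"` (default) or `"positive"`.
#' @return `"+"`, `"-"` or `"absent"`.
#' @export
edge_sign <- function(stats, edge, a_u, a_v,
                      mode = c("proportion", "count"),
                      zero_evidence = c("absent", "positive")) {
  stopifnot(a_u %in% 0:2, a_v %in% 0:2)
  key <- edge_key(edge[1], edge[2])
  if (!key %in% names(stats$prop)) {
    key_rev <- edge_key(edge[2], edge[1])
    if (key_rev %in% names(stats$prop)) {
      key <- key_rev
      tmp <- a_u; a_u <- a_v; a_v <- tmp
    } else stop("unknown edge: ", edge[1], " -- ", edge[2])
  }
  s <- sign_matrix(stats, key, mode, zero_evidence)[a_u + 1L, a_v + 1L]
  c("-", "absent", "+")[s + 2L]
}

#' Signed subject network
#'
#' Builds the per-subject signed graph: every network edge, signed by the
#' chi function at the subject's genotype pair. Edges touching a missing
#' genotype are `"absent"`.
#'
#' @param subject_genotypes Named genotype vector covering all network
#'   variants (`NA` allowed).
#' @param network An `epi_network`.
#' @param stats A `pair_class_stats` fitted on training subjects.
#' @param zero_evidence Passed to the sign rule; see [edge_sign()].
#' @return data.frame with `from`, `to`, `sign` — one row per network
#'   edge.
#' @export
build_subject_network <- function(subject_genotypes, network, stats,
                                  zero_evidence = c("absent", "positive")) {
  zero_evidence <- match.arg(zero_evidence)
  missing_vars <- setdiff(network$nodes, names(subject_genotypes))
  if (length(missing_vars))
    stop("subject genotypes lack network variants: ",
         paste(head(missing_vars, 3), collapse = ", "))
  et <- network$edges
  sgn <- character(nrow(et))
  for (i in seq_len(nrow(et))) {
    au <- subject_genotypes[[et$from[i]]]
    av <- subject_genotypes[[et$to[i]]]
    if (is.na(au) || is.na(av)) {
      sgn[i] <- "absent"
    } else {
      sgn[i] <- edge_sign(stats, c(et$from[i], et$to[i]), au, av,
                          zero_evidence = zero_evidence)
    }
  }
  data.frame(from = et$from, to = et$to, sign = sgn,
             stringsAsFactors = FALSE)
}

#' Delta-degree feature transform
#'
#' Transforms every connected variant of every subject into its delta
#' degree: the number of incident '-' (protective) edges minus the number
#' of incident '+' (risk) edges in the subject's signed network. Absent
#' edges (missing genotype or zero-evidence cell) contribute 0. The result
#' is an integer matrix bounded per cell by the variant's network degree.
#'
#' @param dataset A [geno_dataset] whose subjects are to be transformed
#'   (may be the training set, a test fold, or held-out subjects — the
#'   caller controls leakage by choosing what `stats` was fitted on).
#' @param network An `epi_network`.
#' @param stats A `pair_class_stats` fitted on training subjects.
#' @param zero_evidence See [edge_sign()].
#' @return Integer matrix, subjects x network nodes, with dimnames.
#' @export
delta_degree_transform <- function(dataset, network, stats,
                                   zero_evidence = c("absent", "positive")) {
  zero_evidence <- match.arg(zero_evidence)
  g <- dataset$genotypes
  missing_vars <- setdiff(network$nodes, colnames(g))
  if (length(missing_vars))
    stop("dataset lacks network variants: ",
         paste(head(missing_vars, 3), collapse = ", "))
  nodes <- network$nodes
  out <- matrix(0L, nrow(g), length(nodes),
                dimnames = list(rownames(g), nodes))
  et <- network$edges
  for (i in seq_len(nrow(et))) {
    u <- et$from[i]; v <- et$to[i]
    s <- sign_matrix(stats, edge_key(u, v), "proportion", zero_evidence)
    gu <- g[, u]; gv <- g[, v]
    ok <- !is.na(gu) & !is.na(gv)
    # '+' edge lowers the delta degree of both endpoints; '-' raises it
    contrib <- integer(nrow(g))
    contrib[ok] <- -s[cbind(gu[ok] + 1L, gv[ok] + 1L)]
    out[, u] <- out[, u] + contrib
    out[, v] <- out[, v] + contrib
  }
  out
}

#' Export per-subject signed edge lists
#'
#' @param dataset A [geno_dataset].
#' @param network An `epi_network`.
#' @param stats A `pair_class_stats`.
#' @param path Output TSV path (`subject`, `variant_a`, `variant_b`,
#'   `sign`).
#' @param zero_evidence See [edge_sign()].
#' @export
write_subject_networks <- function(dataset, network, stats, path,
                                   zero_evidence = c("absent", "positive")) {
  zero_evidence <- match.arg(zero_evidence)
  rows <- lapply(rownames(dataset$genotypes), function(sid) {
    sn <- build_subject_network(dataset$genotypes[sid, ], network, stats,
                                zero_evidence)
    data.frame(subject = sid, variant_a = sn$from, variant_b = sn$to,
               sign = sn$sign, stringsAsFactors = FALSE)
  })
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t")
  invisible(path)
}
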