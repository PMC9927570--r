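# Independent brute-force oracles used to cross-check the fast
# implementations. These enumerate joint tables directly and never call
# the package's own information-theory or graph code.

oracle_entropy <- function(x) {
  p <- as.numeric(table(x)) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_mi <- function(x, y) {
  n <- length(x)
  tab <- table(x, y) / n
  px <- rowSums(tab)
  py <- colSums(tab)
  s <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (tab[i, j] > 0)
      s <- s + tab[i, j] * log2(tab[i, j] / (px[i] * py[j]))
  }
  unname(s)
}

oracle_cond_entropy <- function(labels, g) {
  n <- length(labels)
  tab <- table(g, labels) / n
  s <- 0
  for (i in seq_len(nrow(tab))) {
    pa <- sum(tab[i, ])
    for (j in seq_len(ncol(tab))) {
      if (tab[i, j] > 0) s <- s - tab[i, j] * log2(tab[i, j] / pa)
    }
  }
  unname(s)
}

oracle_joint_mi <- function(a, b, y) {
  oracle_mi(paste(a, b, sep = "_"), y)
}

oracle_ig <- function(a, b, y) {
  oracle_joint_mi(a, b, y) - oracle_mi(a, y) - oracle_mi(b, y)
}

# union-find connected components over an edge data.frame (from, to)
oracle_components <- function(edges, nodes) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$from[i]); rb <- find(edges$to[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  parts <- split(nodes, roots)
  parts <- lapply(parts, sort)
  ord <- order(-lengths(parts), vapply(parts, `[`, character(1), 1L))
  unname(parts[ord])
}

# sign of a contingency cell by direct weighted-count comparison
oracle_sign <- function(count_case, count_control, n_case, n_control) {
  if (count_case + count_control == 0) return("absent")
  if (count_case / n_case >= count_control / n_control) "+" else "-"
}
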