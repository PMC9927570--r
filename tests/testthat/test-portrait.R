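two_edge_network <- function() {
  structure(list(edges = data.frame(from = c("rsA", "rsB"),
                                    to = c("rsB", "rsC"),
                                    ig = c(0.3, 0.2),
                                    stringsAsFactors = FALSE),
                 nodes = c("rsA", "rsB", "rsC"), tau = 0.1),
            class = "epi_network")
}

test_that("pair statistics count genotype pairs within each class", {
  g <- matrix(c(0L, 0L, 1L, 1L,
                0L, 0L, 1L, 1L), nrow = 4,
              dimnames = list(paste0("S", 1:4), c("rsA", "rsB")))
  ds <- geno_dataset(g, c(1L, 1L, 0L, 0L))
  net <- structure(list(edges = data.frame(from = "rsA", to = "rsB",
                                           ig = 0.5),
                        nodes = c("rsA", "rsB"), tau = 0),
                   class = "epi_network")
  st <- fit_pair_statistics(ds, net)
  pr <- st$prop[[1]]
  expect_equal(pr["0", "0", "case"], 1.0)
  expect_equal(pr["1", "1", "control"], 1.0)
  expect_equal(sum(pr[, , "case"]), 1.0)
  expect_equal(sum(pr[, , "control"]), 1.0)
  expect_equal(sum(pr) - 2, 0)   # nothing outside the two observed cells
  expect_identical(st$n_case, 2L)
  expect_identical(st$n_control, 2L)
})

test_that("class proportions on an unbalanced cohort equal counts scaled by class size", {
  ds <- fixture_unbalanced()
  net <- two_edge_network()
  st <- fit_pair_statistics(ds, net)
  y <- ds$phenotype
  for (e in 1:2) {
    u <- net$edges$from[e]; v <- net$edges$to[e]
    cnt_case <- table(factor(ds$genotypes[y == 1, u], levels = 0:2),
                      factor(ds$genotypes[y == 1, v], levels = 0:2))
    cnt_ctl <- table(factor(ds$genotypes[y == 0, u], levels = 0:2),
                     factor(ds$genotypes[y == 0, v], levels = 0:2))
    expect_equal(unname(st$prop[[e]][, , "case"]),
                 unname(unclass(cnt_case / 10)))
    expect_equal(unname(st$prop[[e]][, , "control"]),
                 unname(unclass(cnt_ctl / 9)))
  }
})

test_that("edge sign follows the >= comparison with ties to '+'", {
  ds <- fixture_unbalanced()
  net <- two_edge_network()
  st <- fit_pair_statistics(ds, net)
  # every observed cell: sign equals the weighted-count oracle
  for (e in 1:2) {
    u <- net$edges$from[e]; v <- net$edges$to[e]
    cnt <- st$counts[[e]]
    for (a in 0:2) for (b in 0:2) {
      got <- edge_sign(st, c(u, v), a, b)
      want <- oracle_sign(cnt[a + 1, b + 1, "case"],
                          cnt[a + 1, b + 1, "control"], 10, 9)
      expect_identical(got, want)
    }
  }
})

test_that("tie and zero-evidence handling", {
  # 2 cases and 2 controls all at (0,0): tie -> '+'
  g <- matrix(0L, 4, 2, dimnames = list(paste0("S", 1:4), c("u", "v")))
  ds <- geno_dataset(g, c(1L, 1L, 0L, 0L))
  net <- structure(list(edges = data.frame(from = "u", to = "v", ig = 1),
                        nodes = c("u", "v"), tau = 0),
                   class = "epi_network")
  st <- fit_pair_statistics(ds, net)
  expect_identical(edge_sign(st, c("u", "v"), 0, 0), "+")
  # unseen cell: absent by default, '+' under the literal rule
  expect_identical(edge_sign(st, c("u", "v"), 2, 2), "absent")
  expect_identical(edge_sign(st, c("u", "v"), 2, 2,
                             zero_evidence = "positive"), "+")
  expect_error(edge_sign(st, c("u", "nope"), 0, 0), "unknown edge")
})

test_that("proportion-mode and count-mode signs are identical (chi/weight equivalence)", {
  expect_equal(class_balance_weight(10, 9), 10 / 9)
  expect_equal(class_balance_weight(7, 7), 1.0)
  expect_error(class_balance_weight(0, 5))
  set.seed(61)
  for (rep in 1:100) {
    n_case <- sample(3:40, 1); n_ctl <- sample(3:40, 1)
    ds <- geno_dataset(
      matrix(sample(0:2, (n_case + n_ctl) * 2, replace = TRUE), ncol = 2,
             dimnames = list(paste0("S", 1:(n_case + n_ctl)), c("u", "v"))),
      c(rep(1L, n_case), rep(0L, n_ctl)))
    net <- structure(list(edges = data.frame(from = "u", to = "v", ig = 1),
                          nodes = c("u", "v"), tau = 0),
                     class = "epi_network")
    st <- fit_pair_statistics(ds, net)
    for (a in 0:2) for (b in 0:2) {
      expect_identical(edge_sign(st, c("u", "v"), a, b, mode = "proportion"),
                       edge_sign(st, c("u", "v"), a, b, mode = "count"))
    }
  }
})

test_that("subject networks sign every edge and handle missing genotypes", {
  ds <- fixture_unbalanced()
  net <- two_edge_network()
  st <- fit_pair_statistics(ds, net)
  sn <- build_subject_network(ds$genotypes[1, ], net, st)
  expect_identical(nrow(sn), nrow(net$edges))
  expect_true(all(sn$sign %in% c("+", "-", "absent")))
  # missing genotype at rsB (degree 2) silences both its edges
  geno <- ds$genotypes[1, ]
  geno["rsB"] <- NA
  sn2 <- build_subject_network(geno, net, st)
  expect_identical(sn2$sign, c("absent", "absent"))
})

test_that("delta degree equals an independent sign-then-count recount", {
  set.seed(71)
  ds <- random_dataset(40, 6, seed = 71)
  sc <- all_pairs_information_gain(ds)
  net <- build_network(sc, stats::quantile(pair_table(sc)$ig, 0.5))
  st <- fit_pair_statistics(ds, net)
  x <- delta_degree_transform(ds, net, st)
  expect_identical(colnames(x), net$nodes)
  deg <- network_degrees(net)
  for (sid in sample(rownames(ds$genotypes), 10)) {
    sn <- build_subject_network(ds$genotypes[sid, ], net, st)
    for (v in net$nodes) {
      inc <- sn[sn$from == v | sn$to == v, ]
      want <- sum(inc$sign == "-") - sum(inc$sign == "+")
      expect_identical(x[sid, v], as.integer(want))
      expect_lte(abs(x[sid, v]), deg[[v]])
    }
  }
})

test_that("transform is invariant to subject order and isolated variants", {
  ds <- random_dataset(30, 5, seed = 81)
  sc <- all_pairs_information_gain(ds)
  net <- build_network(sc, stats::quantile(pair_table(sc)$ig, 0.6))
  st <- fit_pair_statistics(ds, net)
  x <- delta_degree_transform(ds, net, st)
  # subject reordering permutes rows only
  perm <- sample(nrow(ds$genotypes))
  x2 <- delta_degree_transform(subset_dataset(ds, subjects = perm), net, st)
  expect_identical(x2, x[perm, , drop = FALSE])
  # adding an unconnected variant changes nothing
  g3 <- cbind(ds$genotypes, extra = rep(0:2, length.out = 30))
  ds3 <- geno_dataset(g3, ds$phenotype)
  expect_identical(delta_degree_transform(ds3, net, st), x)
  # determinism
  expect_identical(delta_degree_transform(ds, net, st), x)
})

test_that("removing an edge changes only its endpoints by at most one", {
  ds <- random_dataset(30, 5, seed = 91)
  sc <- all_pairs_information_gain(ds)
  net <- build_network(sc, min(pair_table(sc)$ig) - 0.01)  # complete graph
  st <- fit_pair_statistics(ds, net)
  x_full <- delta_degree_transform(ds, net, st)
  net2 <- net
  dropped <- net$edges[1, ]
  net2$edges <- net$edges[-1, ]
  st2 <- fit_pair_statistics(ds, net2)
  x_red <- delta_degree_transform(ds, net2, st2)
  diffs <- abs(x_full[, net2$nodes] - x_red[, net2$nodes])
  touched <- c(dropped$from, dropped$to)
  expect_true(all(diffs[, setdiff(colnames(diffs), touched)] == 0))
  expect_true(all(diffs[, touched] <= 1))
})
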