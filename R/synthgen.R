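# Penetrance-table simulator for case-control genotype data with planted
# epistatic interactions: two-locus models defined by a 3x3 penetrance
# table under Hardy-Weinberg genotype frequencies and linkage equilibrium,
# a three-locus parity model for the higher-order negative control, and a
# case-control sampler with independent noise variants.

#' Construct a two-locus penetrance model
#'
#' @param table 3x3 matrix of penetrances (disease probabilities) indexed
#'   by the genotype codes of locus A (rows) and locus B (columns), values
#'   in \[0, 1\].
#' @param maf_a,maf_b Alternate-allele frequencies in (0, 0.5\].
#' @return A `penetrance_model` object.
#' @export
penetrance_model <- function(table, maf_a, maf_b) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(3L, 3L)))
  if (any(table < 0 | table > 1)) stop("penetrances must lie in [0, 1]")
  if (maf_a <= 0 || maf_a > 0.5 || maf_b <= 0 || maf_b > 0.5)
    stop("allele frequencies must lie in (0, 0.5]")
  dimnames(table) <- list(0:2, 0:2)
  structure(list(table = table, maf = c(maf_a, maf_b), loci = 2L),
            class = "penetrance_model")
}

#' XOR (parity) two-locus epistasis model
#'
#' Penetrance is `base + lift` when exactly one of the two genotypes is
#' heterozygous (genotype parity 1) and `base` otherwise. At maf 0.5 the
#' heterozygote probability is 1/2, both loci's marginal penetrances are
#' flat and the model is purely epistatic (no main effects).
#'
#' @param maf Allele frequency for both loci (default 0.5).
#' @param base Baseline penetrance (default 0.1).
#' @param lift Penetrance increase on parity-1 genotype pairs
#'   (default 0.8).
#' @return A `penetrance_model`.
#' @export
xor_model <- function(maf = 0.5, base = 0.1, lift = 0.8) {
  if (base < 0 || base + lift > 1 || base + lift < 0)
    stop("base and base + lift must lie in [0, 1]")
  par_g <- (0:2) %% 2
  tab <- base + lift * outer(par_g, par_g, function(a, b) as.numeric(xor(a, b)))
  penetrance_model(tab, maf, maf)
}

#' Three-locus parity model (higher-order negative control)
#'
#' Penetrance is `base + lift` when the parity of the three heterozygosity
#' indicators is odd. At maf 0.5 every *pair* of loci is exactly
#' uninformative about the phenotype (each pairwise conditional table is
#' flat), while the three loci jointly determine risk — the construction
#' used to show that second-order information gain cannot detect
#' third-order interactions.
#'
#' @param maf Allele frequency for all three loci (default 0.5).
#' @param base,lift As in [xor_model()].
#' @return A `penetrance_model3` object with a 3x3x3 penetrance array.
#' @export
threeway_model <- function(maf = 0.5, base = 0.1, lift = 0.8) {
  if (base < 0 || base + lift > 1 || base + lift < 0)
    stop("base and base + lift must lie in [0, 1]")
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  par_g <- (0:2) %% 2
  arr <- array(0, dim = c(3, 3, 3), dimnames = list(0:2, 0:2, 0:2))
  for (a in 1:3) for (b in 1:3) for (cc in 1:3)
    arr[a, b, cc] <- base +
      lift * ((par_g[a] + par_g[b] + par_g[cc]) %% 2)
  structure(list(table = arr, maf = rep(maf, 3), loci = 3L),
            class = "penetrance_model3")
}

hwe_freqs <- function(maf) c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)

pen_array <- function(model) {
  if (inherits(model, "penetrance_model")) model$table else model$table
}

#' Exact population summary of a penetrance model
#'
#' Computes, under Hardy-Weinberg genotype frequencies and independent
#' loci, the disease prevalence K, the per-locus marginal penetrances, the
#' broad-sense heritability Var_g(penetrance) / (K (1 - K)), and the
#' main-effect size of each locus (maximum deviation of its marginal
#' penetrance from K).
#'
#' @param model A `penetrance_model` or `penetrance_model3`.
#' @return A list with `prevalence`, `heritability`, `marginal_penetrance`
#'   (loci x 3 matrix) and `main_effect` (per-locus).
#' @export
model_summary <- function(model) {
  tab <- pen_array(model)
  L <- model$loci
  freqs <- lapply(model$maf, hwe_freqs)
  # joint genotype probability array, same shape as the penetrance table
  joint <- Reduce(outer, freqs)
  joint <- array(joint, dim = rep(3L, L))
  K <- sum(joint * tab)
  varg <- sum(joint * (tab - K)^2)
  h2 <- if (K > 0 && K < 1) varg / (K * (1 - K)) else 0
  marg <- matrix(NA_real_, L, 3, dimnames = list(NULL, 0:2))
  for (l in seq_len(L)) {
    pg <- apply(joint, l, sum)
    num <- apply(joint * tab, l, sum)
    marg[l, ] <- num / pg
  }
  list(prevalence = K, heritability = h2, marginal_penetrance = marg,
       main_effect = apply(abs(marg - K), 1, max))
}

#' Simulate a case-control dataset with planted epistasis
#'
#' Draws genotypes per locus as Binomial(2, maf) counts (Hardy-Weinberg,
#' linkage equilibrium), assigns disease status from the planted
#' penetrance models — with several models, a subject's disease
#' probability is `1 - prod_j (1 - pen_j)`, i.e. independent causal routes
#' — and uses per-class rejection sampling until exactly `n_cases` cases
#' and `n_controls` controls are collected (a case-control design, not a
#' cohort). Noise variants are generated independently of the phenotype at
#' frequencies drawn uniformly from `noise_maf_range`.
#'
#' @param models List of `penetrance_model` / `penetrance_model3` objects
#'   (may be empty for pure-noise data).
#' @param n_cases,n_controls Exact class sizes.
#' @param n_noise_variants Number of phenotype-independent variants.
#' @param noise_maf_range Length-2 interval for noise allele frequencies
#'   (default `c(0.05, 0.5)`).
#' @param seed Integer seed; the output is a deterministic function of all
#'   arguments.
#' @param max_batches Rejection-sampling safety cap.
#' @return A [geno_dataset] with planted loci named `pair<j>_a`/`_b` (or
#'   `trip<j>_a/_b/_c`) followed by `noise<i>` variants. The attribute
#'   `"planted"` lists the planted locus ids per model; `"noise_maf"`
#'   holds the drawn noise frequencies.
#' @export
simulate_dataset <- function(models, n_cases, n_controls,
                             n_noise_variants,
                             noise_maf_range = c(0.05, 0.5),
                             seed = 1L, max_batches = 10000L) {
  stopifnot(n_cases >= 0, n_controls >= 0, n_noise_variants >= 0)
  n <- n_cases + n_controls
  if (n == 0L) stop("no subjects requested")
  n_planted <- sum(vapply(models, `[[`, integer(1), "loci"))
  if (n_planted + n_noise_variants < 1L) stop("no variants requested")
  rng <- local_rng(seed)
  planted_ids <- unlist(lapply(seq_along(models), function(j) {
    l <- models[[j]]$loci
    prefix <- if (l == 2L) "pair" else "trip"
    paste0(prefix, j, "_", letters[seq_len(l)])
  }))
  rng$with_state(function() {
    case_pool <- list(); ctl_pool <- list()
    need_cases <- n_cases; need_ctls <- n_controls
    batch <- max(256L, 2L * n)
    tries <- 0L
    while ((need_cases > 0L || need_ctls > 0L)) {
      tries <- tries + 1L
      if (tries > max_batches)
        stop("requested class sizes unreachable under the given models")
      if (n_planted > 0L) {
        gp <- matrix(0L, batch, n_planted)
        col <- 0L
        p_healthy <- rep(1, batch)
        for (mod in models) {
          gm <- vapply(mod$maf, function(f)
            stats::rbinom(batch, 2L, f), integer(batch))
          tab <- pen_array(mod)
          pen <- if (mod$loci == 2L)
            tab[cbind(gm[, 1] + 1L, gm[, 2] + 1L)]
          else
            tab[cbind(gm[, 1] + 1L, gm[, 2] + 1L, gm[, 3] + 1L)]
          p_healthy <- p_healthy * (1 - pen)
          gp[, col + seq_len(mod$loci)] <- gm
          col <- col + mod$loci
        }
        status <- as.integer(stats::runif(batch) < (1 - p_healthy))
      } else {
        gp <- matrix(0L, batch, 0L)
        status <- stats::rbinom(batch, 1L, 0.5)
      }
      for (i in seq_len(batch)) {
        if (status[i] == 1L && need_cases > 0L) {
          case_pool[[length(case_pool) + 1L]] <- gp[i, ]
          need_cases <- need_cases - 1L
        } else if (status[i] == 0L && need_ctls > 0L) {
          ctl_pool[[length(ctl_pool) + 1L]] <- gp[i, ]
          need_ctls <- need_ctls - 1L
        }
        if (need_cases == 0L && need_ctls == 0L) break
      }
    }
    g_planted <- do.call(rbind, c(case_pool, ctl_pool))
    if (is.null(g_planted)) g_planted <- matrix(0L, n, 0L)
    phenotype <- c(rep(1L, n_cases), rep(0L, n_controls))
    noise_maf <- if (n_noise_variants > 0L)
      stats::runif(n_noise_variants, noise_maf_range[1], noise_maf_range[2])
    else numeric(0)
    g_noise <- vapply(noise_maf, function(f) stats::rbinom(n, 2L, f),
                      integer(n))
    if (n_noise_variants > 0L && n == 1L)
      g_noise <- matrix(g_noise, nrow = 1L)
    g <- cbind(g_planted, g_noise)
    colnames(g) <- c(planted_ids,
                     if (n_noise_variants > 0L)
                       sprintf("noise%03d", seq_len(n_noise_variants)))
    # shuffle subject order so class blocks are not positional
    ord <- sample.int(n)
    g <- g[ord, , drop = FALSE]
    phenotype <- phenotype[ord]
    rownames(g) <- sprintf("S%04d", seq_len(n))
    ds <- geno_dataset(g, phenotype)
    attr(ds, "planted") <- lapply(seq_along(models), function(j) {
      l <- models[[j]]$loci
      prefix <- if (l == 2L) "pair" else "trip"
      paste0(prefix, j, "_", letters[seq_len(l)])
    })
    attr(ds, "noise_maf") <- noise_maf
    ds
  })
}

#' Read a PMLB-style GAMETES benchmark table
#'
#' Tab-separated layout with one column per attribute (genotype codes
#' 0/1/2) and a final `class` column (0/1), as distributed in the Penn
#' Machine Learning Benchmarks. The planted loci in those files are named
#' `M0P0`/`M0P1` (and so on); all other attributes (`N0`, `N1`, ...) are
#' noise.
#'
#' @param path Path to the TSV file.
#' @return A [geno_dataset].
#' @export
read_pmlb_gametes <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  cls <- intersect(c("class", "Class"), names(dt))[1]
  if (is.na(cls)) stop("no 'class' column in ", path)
  y <- dt[[cls]]
  dt[[cls]] <- NULL
  g <- as.matrix(dt)
  rownames(g) <- paste0("S", seq_len(nrow(g)))
  geno_dataset(g, y)
}

#' Write simulation metadata sidecar
#'
#' Records planted variant ids, model parameters and the seed next to a
#' simulated dataset as JSON.
#'
#' @param dataset A simulated [geno_dataset].
#' @param models The model list passed to [simulate_dataset()].
#' @param seed The seed used.
#' @param path Output JSON path.
#' @export
write_simulation_metadata <- function(dataset, models, seed, path) {
  meta <- list(
    seed = seed,
    planted = attr(dataset, "planted"),
    noise_maf = attr(dataset, "noise_maf"),
    models = lapply(models, function(m)
      list(loci = m$loci, maf = m$maf, penetrance = m$table))
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
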