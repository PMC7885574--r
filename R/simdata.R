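#' Configuration for the data simulator
#'
#' Parameters of the built-in gene-dropping simulator, which emulates a
#' multi-generation cattle population: discrete non-overlapping
#' generations of random mating, markers evenly spaced along autosomes
#' with Haldane recombination, units formed by k-medoids clustering of
#' the numerator relationship matrix, and a single phenotype with a sex
#' covariate. The defaults reproduce the shape of the package's
#' reference example: 2,500 individuals over 5 generations (500 founders
#' plus 4 generations of 500), 10,000 markers on 29 chromosome pairs of
#' 100 cM, heritability 0.6.
#'
#' @param n_founders founders in generation 1 (half male, half female).
#' @param generations total number of non-overlapping generations.
#' @param offspring_per_gen offspring born into each later generation.
#' @param n_markers total biallelic markers, spread evenly over
#'   chromosomes.
#' @param n_chromosomes number of autosome pairs.
#' @param chr_length_cM genetic length per chromosome, centimorgans.
#' @param founder_freq range of the uniform law for founder allele
#'   frequencies (length-2), or a single frequency applied to all
#'   markers.
#' @param h2 heritability of the simulated trait (phenotypic variance is
#'   normalized to 1, so `sigma2_u = h2`).
#' @param sex_effect additive fixed effect of the male sex on the
#'   phenotype, in phenotypic standard deviations.
#' @param n_units number of management units formed by clustering.
#' @param seed integer seed governing all randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 500L, generations = 5L,
                       offspring_per_gen = 500L, n_markers = 10000L,
                       n_chromosomes = 29L, chr_length_cM = 100,
                       founder_freq = c(0.1, 0.9), h2 = 0.6,
                       sex_effect = 1, n_units = 5L, seed = 42L) {
  stopifnot(n_founders >= 4L, generations >= 1L, offspring_per_gen >= 0L,
            n_markers >= 1L, n_chromosomes >= 1L, chr_length_cM > 0,
            h2 > 0, h2 < 1, n_units >= 2L,
            all(founder_freq > 0), all(founder_freq < 1))
  if (length(founder_freq) == 1L) founder_freq <- rep(founder_freq, 2L)
  structure(list(n_founders = as.integer(n_founders),
                 generations = as.integer(generations),
                 offspring_per_gen = as.integer(offspring_per_gen),
                 n_markers = as.integer(n_markers),
                 n_chromosomes = as.integer(n_chromosomes),
                 chr_length_cM = chr_length_cM,
                 founder_freq = founder_freq,
                 h2 = h2, sex_effect = sex_effect,
                 n_units = as.integer(n_units),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a multi-generation pedigree
#'
#' Non-overlapping generations: founders with unknown parents, then each
#' later generation of offspring whose sire and dam are drawn uniformly
#' at random from the males and females of the previous generation. Sex
#' alternates male/female in birth order, giving an even sex ratio.
#'
#' @param config a [sim_config()].
#' @return A [pedigree_table()] with extra columns `sex` (`"M"`/`"F"`)
#'   and `generation`; parents always precede offspring.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nf <- config$n_founders
  id <- as.character(seq_len(nf))
  sire <- dam <- rep(NA_character_, nf)
  sex <- rep(c("M", "F"), length.out = nf)
  gen <- rep(1L, nf)
  prev <- seq_len(nf)
  next_id <- nf + 1L
  for (g in seq_len(config$generations - 1L)) {
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    if (!length(males) || !length(females)) {
      stop("generation ", g, " has no available ",
           if (!length(males)) "sires" else "dams", call. = FALSE)
    }
    n_off <- config$offspring_per_gen
    off <- next_id:(next_id + n_off - 1L)
    id <- c(id, as.character(off))
    sire <- c(sire, id[sample(males, n_off, replace = TRUE)])
    dam <- c(dam, id[sample(females, n_off, replace = TRUE)])
    sex <- c(sex, rep(c("M", "F"), length.out = n_off))
    gen <- c(gen, rep(g + 1L, n_off))
    prev <- off
    next_id <- next_id + n_off
  }
  pedigree_table(data.frame(id = id, sire = sire, dam = dam,
                            sex = sex, generation = gen,
                            stringsAsFactors = FALSE))
}

## marker map: for each marker its chromosome and the recombination
## fraction with the previous marker (0.5 at a chromosome start, i.e.
## independent segregation across chromosomes; Haldane within).
.marker_map <- function(config) {
  m <- config$n_markers
  chr <- sort(rep_len(seq_len(config$n_chromosomes), m))
  r <- numeric(m)
  for (c_ in unique(chr)) {
    ix <- which(chr == c_)
    mc <- length(ix)
    d_cM <- if (mc > 1L) config$chr_length_cM / (mc - 1L) else 0
    rc <- 0.5 * (1 - exp(-2 * d_cM / 100))   # Haldane map function
    r[ix] <- c(0.5, rep(rc, mc - 1L))
  }
  list(chr = chr, r = r)
}

## one gamete from a parent's two haplotype rows: the carried haplotype
## switches with probability r[m] before marker m (r = 0.5 at chromosome
## starts randomizes the starting phase).
.gamete <- function(h1, h2, r) {
  phase <- cumsum(stats::runif(length(r)) < r) %% 2L
  ifelse(phase == 0L, h1, h2)
}

#' Gene-drop marker genotypes down a pedigree
#'
#' Founder haplotypes are drawn per locus in Hardy-Weinberg proportions
#' at frequencies from the configured founder law; each offspring
#' receives one recombinant gamete from each parent, with crossovers
#' following the Haldane mapping over the evenly spaced marker map.
#'
#' @param pedigree a [pedigree_table()].
#' @param config a [sim_config()].
#' @return Integer matrix (allele counts 0/1/2), individuals x markers,
#'   with individual ids as row names and `M1..Mm` as column names.
#' @export
drop_genotypes <- function(pedigree, config) {
  stopifnot(inherits(pedigree, "pedigree_table"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- nrow(pedigree)
  m <- config$n_markers
  map <- .marker_map(config)
  p <- stats::runif(m, config$founder_freq[1L], config$founder_freq[2L])

  ord <- attr(pedigree, "order")
  pos <- seq_len(n)
  names(pos) <- pedigree$id
  h1 <- matrix(0L, n, m)
  h2 <- matrix(0L, n, m)
  for (j in ord) {
    s <- pedigree$sire[j]
    d <- pedigree$dam[j]
    h1[j, ] <- if (is.na(s)) {
      as.integer(stats::runif(m) < p)
    } else {
      si <- pos[[s]]
      .gamete(h1[si, ], h2[si, ], map$r)
    }
    h2[j, ] <- if (is.na(d)) {
      as.integer(stats::runif(m) < p)
    } else {
      di <- pos[[d]]
      .gamete(h1[di, ], h2[di, ], map$r)
    }
  }
  geno <- h1 + h2
  dimnames(geno) <- list(pedigree$id, paste0("M", seq_len(m)))
  geno
}

#' Monte-Carlo additive relationships by gene dropping
#'
#' Drops unlinked loci with founder alleles uniquely labelled down the
#' pedigree and estimates the additive relationship between two
#' individuals as twice their kinship — the probability that alleles
#' sampled from each are identical by descent — averaged over loci; the
#' diagonal is `1 + F` with `F` the realized parental-allele IBD rate.
#' This is an independent, simulation-based estimate of the numerator
#' relationship matrix, useful for checking [build_A()].
#'
#' @param pedigree a [pedigree_table()].
#' @param n_loci number of independent replicate loci (default 20000).
#' @param seed integer seed.
#' @return Symmetric matrix of estimated relationships.
#' @export
genedrop_A <- function(pedigree, n_loci = 20000L, seed = 1L) {
  stopifnot(inherits(pedigree, "pedigree_table"))
  set.seed(seed)
  n <- nrow(pedigree)
  ord <- attr(pedigree, "order")
  pos <- seq_len(n)
  names(pos) <- pedigree$id
  a1 <- matrix(0L, n, n_loci)
  a2 <- matrix(0L, n, n_loci)
  for (j in ord) {
    s <- pedigree$sire[j]
    d <- pedigree$dam[j]
    a1[j, ] <- if (is.na(s)) {
      rep.int(2L * j - 1L, n_loci)
    } else {
      si <- pos[[s]]
      ifelse(stats::runif(n_loci) < 0.5, a1[si, ], a2[si, ])
    }
    a2[j, ] <- if (is.na(d)) {
      rep.int(2L * j, n_loci)
    } else {
      di <- pos[[d]]
      ifelse(stats::runif(n_loci) < 0.5, a1[di, ], a2[di, ])
    }
  }
  A <- matrix(0, n, n, dimnames = list(pedigree$id, pedigree$id))
  for (i in seq_len(n)) {
    A[i, i] <- 1 + mean(a1[i, ] == a2[i, ])
    if (i < n) {
      for (j in (i + 1L):n) {
        ibd <- (a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
          (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])
        A[i, j] <- A[j, i] <- mean(ibd) / 2
      }
    }
  }
  A
}

#' Assign individuals to units by relationship clustering
#'
#' Forms management units by k-medoids (PAM) clustering of a
#' dissimilarity derived from the relationship matrix:
#' `D = 1 - K / max(K)` by default (alternatively `D = max(K) - K`), so
#' closely related individuals fall into the same unit. PAM is
#' deterministic given the dissimilarity.
#'
#' @param K a relationship matrix.
#' @param n_units number of units (>= 2).
#' @param dissimilarity `"scaled"` for `1 - K/max(K)` (default) or
#'   `"shifted"` for `max(K) - K`.
#' @return Character vector of unit labels (`"1"` ... `"k"`) named by
#'   individual id.
#' @export
assign_units <- function(K, n_units, dissimilarity = c("scaled", "shifted")) {
  dissimilarity <- match.arg(dissimilarity)
  K <- as.matrix(K)
  if (n_units < 2L) stop("connectedness needs at least 2 units", call. = FALSE)
  if (n_units > nrow(K)) stop("more units than individuals", call. = FALSE)
  D <- switch(dissimilarity,
              scaled = 1 - K / max(K),
              shifted = max(K) - K)
  cl <- cluster::pam(stats::as.dist(D), k = n_units, pamonce = 5)
  stats::setNames(as.character(cl$clustering), rownames(K))
}

#' Simulate phenotypes over a pedigree
#'
#' Breeding values are drawn jointly from `N(0, K * sigma2_u)` with
#' `sigma2_u = h2` and `sigma2_e = 1 - h2` (phenotypic variance
#' normalized to 1), and the phenotype is `y = sex_effect * I(male) + u
#' + e`. The unit labels are carried along as the management grouping to
#' be fitted as a fixed effect; they do not shift the simulated
#' phenotype, so any estimated unit differences are purely structural.
#'
#' @param pedigree a [simulate_pedigree()] result (needs the `sex`
#'   column).
#' @param K relationship matrix over the pedigree's individuals.
#' @param units unit labels named by individual id (see
#'   [assign_units()]).
#' @param config a [sim_config()].
#' @return A [phenotype_table()] with columns `progeny`, `sire`, `dam`,
#'   `sex`, `unit`, `phenotype` (unknown parents coded `"0"`).
#' @export
simulate_phenotypes <- function(pedigree, K, units, config) {
  stopifnot(inherits(pedigree, "pedigree_table"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- nrow(pedigree)
  K <- as.matrix(K)
  stopifnot(nrow(K) == n)
  s2u <- config$h2
  s2e <- 1 - config$h2
  R <- chol(K + diag(1e-8, n))
  u <- drop(crossprod(R, stats::rnorm(n))) * sqrt(s2u)
  e <- stats::rnorm(n, sd = sqrt(s2e))
  sex <- pedigree$sex
  y <- config$sex_effect * (sex == "M") + u + e
  df <- data.frame(
    progeny = pedigree$id,
    sire = ifelse(is.na(pedigree$sire), "0", pedigree$sire),
    dam = ifelse(is.na(pedigree$dam), "0", pedigree$dam),
    sex = sex,
    unit = as.character(units[pedigree$id]),
    phenotype = y,
    stringsAsFactors = FALSE
  )
  out <- phenotype_table(df, id_col = "progeny")
  attr(out, "true_u") <- stats::setNames(u, pedigree$id)
  out
}

#' Generate the full reference example data set
#'
#' Runs the whole simulator: pedigree, gene-dropped genotypes, numerator
#' relationship matrix, k-medoids unit assignment and phenotypes. With
#' the default [sim_config()] this yields 2,500 individuals over five
#' generations, a 2,500 x 10,000 marker matrix, and a six-column
#' phenotype table (`progeny`, `sire`, `dam`, `sex`, `unit`,
#' `phenotype`).
#'
#' @param config a [sim_config()].
#' @return List with elements `pedigree`, `genotypes`, `A` (the
#'   [build_A()] relationship matrix), `units`, `phenotypes`, `config`.
#' @export
make_example <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  ped <- simulate_pedigree(config)
  geno <- drop_genotypes(ped, config)
  A <- build_A(ped)
  units <- assign_units(A, config$n_units)
  phe <- simulate_phenotypes(ped, A, units, config)
  list(pedigree = ped, genotypes = geno, A = A, units = units,
       phenotypes = phe, config = config)
}
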