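# Shared fixture builders: small populations and assembled MME systems.

# trio: two founders and their offspring
trio_pedigree <- function() {
  pedigree_table(data.frame(id = c("1", "2", "3"),
                            sire = c("0", "0", "1"),
                            dam = c("0", "0", "2")))
}

# founders 1,2; full sibs 3,4; 5 = offspring of the full sibs (F = 0.25)
fullsib_pedigree <- function() {
  pedigree_table(data.frame(id = as.character(1:5),
                            sire = c("0", "0", "1", "1", "3"),
                            dam = c("0", "0", "2", "2", "4")))
}

# random PD relationship-like matrix with unit diagonal scale
random_K <- function(n, seed = 1) {
  set.seed(seed)
  L <- matrix(rnorm(n * n, sd = 0.3), n)
  K <- crossprod(L) + diag(n)
  dimnames(K) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  relationship_matrix(K / mean(diag(K)), source = "genomic")
}

# simulated population with pedigree K, balanced-ish units
sim_population <- function(n_founders = 20, offspring_per_gen = 20,
                           generations = 3, n_units = 3, h2 = 0.5,
                           seed = 11) {
  cfg <- sim_config(n_founders = n_founders, generations = generations,
                    offspring_per_gen = offspring_per_gen,
                    n_markers = 50, n_chromosomes = 2, h2 = h2,
                    n_units = n_units, seed = seed)
  ped <- simulate_pedigree(cfg)
  A <- build_A(ped)
  units <- assign_units(A, n_units)
  phe <- simulate_phenotypes(ped, A, units, cfg)
  list(ped = ped, A = A, units = units, phe = phe, cfg = cfg)
}

# assembled MME system over a simulated population
sim_system <- function(fixed_effects = character(), h2 = 0.5, seed = 11,
                       n_units = 3, n_founders = 20, offspring_per_gen = 20,
                       generations = 3) {
  pop <- sim_population(n_founders = n_founders,
                        offspring_per_gen = offspring_per_gen,
                        generations = generations,
                        n_units = n_units, h2 = h2, seed = seed)
  vc <- variance_components(h2 = h2)
  Kinv <- regularize_and_invert(pop$A)
  des <- build_design(pop$phe, fixed_effects, ids = rownames(pop$A))
  sys <- build_mme(des, Kinv, vc)
  list(pop = pop, vc = vc, des = des, sys = sys, ps = pev(sys), K = pop$A)
}

# two-unit design with a configurable number of across-unit sire links:
# two disconnected founder groups; `links` of unit-B offspring are sired
# from unit A. Units are fixed by founder group, not clustered. Unit
# sizes are kept large relative to the link ladder so the designs stay
# in the sparse-linkage regime (with many links the units merge
# genetically and CD's similarity penalty takes over).
linked_design <- function(links, n_per_side = 30, h2 = 0.5) {
  sires_a <- paste0("SA", 1:3)
  dams_a <- paste0("DA", 1:6)
  sires_b <- paste0("SB", 1:3)
  dams_b <- paste0("DB", 1:6)
  off_a <- paste0("OA", seq_len(n_per_side))
  off_b <- paste0("OB", seq_len(n_per_side))
  sire_of_b <- rep(sires_b, length.out = n_per_side)
  if (links > 0) sire_of_b[seq_len(links)] <- rep(sires_a, length.out = links)
  ped <- pedigree_table(data.frame(
    id = c(sires_a, dams_a, sires_b, dams_b, off_a, off_b),
    sire = c(rep("0", 18), rep(sires_a, length.out = n_per_side), sire_of_b),
    dam = c(rep("0", 18), rep(dams_a, length.out = n_per_side),
            rep(dams_b, length.out = n_per_side))))
  A <- build_A(ped)
  phe <- phenotype_table(data.frame(
    id = c(off_a, off_b),
    unit = rep(c("A", "B"), each = n_per_side),
    phenotype = 0))
  vc <- variance_components(h2 = h2)
  des <- build_design(phe, ids = rownames(A))
  sys <- build_mme(des, regularize_and_invert(A), vc)
  list(A = A, sys = sys, ps = pev(sys), vc = vc)
}

# dense brute-force inverse of the full coefficient matrix (oracle)
dense_cinv <- function(sys) solve(sys$C)
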