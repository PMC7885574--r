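test_that("pairwise PEVD follows its defining quadratic form", {
  s <- sim_system(seed = 2)
  P <- s$ps$PEV
  expect_equal(pevd_pairwise(s$ps, 1, 1), 0)
  # quadratic-form oracle with the +/-1 indicator difference vector
  for (pair in list(c(1L, 5L), c(2L, 30L), c(11L, 40L))) {
    d <- numeric(nrow(P))
    d[pair[1]] <- 1
    d[pair[2]] <- -1
    expect_equal(pevd_pairwise(s$ps, pair[1], pair[2]),
                 drop(crossprod(d, P %*% d)))
  }
  # zero covariance: PEVD is the sum of the PEVs
  P0 <- P
  P0[1, 5] <- P0[5, 1] <- 0
  ps0 <- s$ps
  ps0$PEV <- P0
  expect_equal(pevd_pairwise(ps0, 1, 5), P0[1, 1] + P0[5, 5])
  # ids work as well as positions
  ids <- rownames(P)
  expect_equal(pevd_pairwise(s$ps, ids[3], ids[9]),
               pevd_pairwise(s$ps, 3, 9))
})

test_that("group-average equals contrast summary for PEVD and CD on every pair", {
  for (seed in c(1, 9, 23)) {
    s <- sim_system(seed = seed)
    g_pevd <- pevd_grpave(s$ps)
    g_cd <- cd_grpave(s$ps, s$K)
    units <- s$ps$units
    for (a in seq_along(units)) {
      for (b in seq_along(units)) {
        if (a < b) {
          x <- unit_contrast(s$ps, units[a], units[b])
          expect_lt(abs(g_pevd$matrix[a, b] - pevd_contrast(s$ps, x)), 1e-10)
          expect_lt(abs(g_cd$matrix[a, b] - cd_contrast(s$ps, s$K, x)), 1e-10)
        }
      }
    }
  }
})

test_that("group-average PEVD matches hand block-mean arithmetic on a 7x7 layout", {
  # synthetic PEV over 2 units of sizes 3 and 4
  set.seed(6)
  L <- matrix(rnorm(49, sd = 0.2), 7)
  P <- crossprod(L) + diag(7)
  dimnames(P) <- list(as.character(1:7), as.character(1:7))
  ps <- structure(list(PEV = P,
                       unit_index = list(`1` = 1:3, `2` = 4:7),
                       units = c("1", "2"), n_unit = c(3L, 4L),
                       varcomp = variance_components(h2 = 0.5)),
                  class = "pev_store")
  hand <- mean(P[1:3, 1:3]) + mean(P[4:7, 4:7]) - 2 * mean(P[1:3, 4:7])
  expect_equal(pevd_grpave(ps)$matrix["1", "2"], hand)
  # identical blocks with zero cross covariance give 2 * block mean
  P2 <- matrix(0, 6, 6, dimnames = list(as.character(1:6), as.character(1:6)))
  B <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  P2[1:3, 1:3] <- B
  P2[4:6, 4:6] <- B
  ps2 <- structure(list(PEV = P2, unit_index = list(a = 1:3, b = 4:6),
                        units = c("a", "b"), n_unit = c(3L, 3L),
                        varcomp = variance_components(h2 = 0.5)),
                   class = "pev_store")
  expect_equal(pevd_grpave(ps2)$matrix["a", "b"], 2 * mean(B))
  # and the flock-connectedness r is zero there, 1 when the units coincide
  expect_equal(r_grpave(ps2)$matrix["a", "b"], 0)
  ps3 <- ps2
  ps3$PEV[1:3, 4:6] <- B
  ps3$PEV[4:6, 1:3] <- B
  expect_equal(r_grpave(ps3)$matrix["a", "b"], 1)
})

test_that("individual-average summaries equal brute-force double loops", {
  s <- sim_system(seed = 12, n_units = 3)
  P <- s$ps$PEV
  ui <- s$ps$unit_index
  idave <- pevd_idave(s$ps)
  r_id <- r_idave(s$ps)
  for (a in 1:2) {
    for (b in (a + 1):3) {
      acc_p <- acc_r <- 0
      for (i in ui[[a]]) {
        for (j in ui[[b]]) {
          acc_p <- acc_p + (P[i, i] + P[j, j] - 2 * P[i, j])
          acc_r <- acc_r + P[i, j] / sqrt(P[i, i] * P[j, j])
        }
      }
      npair <- length(ui[[a]]) * length(ui[[b]])
      expect_equal(idave$matrix[a, b], acc_p / npair)
      expect_equal(r_id$matrix[a, b], acc_r / npair)
    }
  }
})

test_that("singleton units collapse all summaries to the pairwise value", {
  phe <- phenotype_table(data.frame(id = c("a", "b"), unit = c("1", "2"),
                                    phenotype = 0))
  des <- build_design(phe)
  K <- relationship_matrix(matrix(c(1, 0.25, 0.25, 1), 2,
                                  dimnames = list(c("a", "b"), c("a", "b"))),
                           source = "pedigree")
  vc <- variance_components(h2 = 0.5)
  sys <- build_mme(des, regularize_and_invert(K), vc)
  ps <- pev(sys)
  pw <- pevd_pairwise(ps, "a", "b")
  expect_equal(pevd_idave(ps)$matrix[1, 2], pw)
  expect_equal(pevd_grpave(ps)$matrix[1, 2], pw)
  expect_equal(cd_idave(ps, K)$matrix[1, 2], cd_pairwise(ps, K, "a", "b"))
  expect_equal(r_idave(ps)$matrix[1, 2], r_pairwise(ps, "a", "b"))
})

test_that("contrast statistics validate their input and are sign-invariant", {
  s <- sim_system(seed = 2)
  x <- unit_contrast(s$ps, "1", "2")
  expect_lt(abs(sum(x)), 1e-12)
  expect_equal(pevd_contrast(s$ps, x), pevd_contrast(s$ps, -x))
  expect_equal(cd_contrast(s$ps, s$K, x), cd_contrast(s$ps, s$K, -x))
  expect_equal(r_contrast(s$ps, x), r_contrast(s$ps, -x))
  expect_error(pevd_contrast(s$ps, numeric(s$sys$q)), "identically zero")
  expect_error(pevd_contrast(s$ps, rep(1, s$sys$q)), "sum to zero")
  expect_error(unit_contrast(s$ps, "1", "1"), "distinct")
})

test_that("r of a contrast over an identity r-matrix is 1/n1 + 1/n2", {
  ps <- structure(list(PEV = diag(7) * 0.3,
                       unit_index = list(`1` = 1:3, `2` = 4:7),
                       units = c("1", "2"), n_unit = c(3L, 4L),
                       varcomp = variance_components(h2 = 0.5)),
                  class = "pev_store")
  rownames(ps$PEV) <- colnames(ps$PEV) <- as.character(1:7)
  x <- unit_contrast(ps, "1", "2")
  expect_equal(r_contrast(ps, x), 1 / 3 + 1 / 4)
  # exchangeable individuals: IdAve PEVD is 2a for every pair
  expect_equal(pevd_idave(ps)$matrix["1", "2"], 0.6)
  expect_equal(r_idave(ps)$matrix["1", "2"], 0)
  expect_equal(r_pairwise(ps, 1, 1), 1)
})

test_that("CD is bounded, shrinks to 0 without data and grows to 1 with data", {
  phe <- phenotype_table(data.frame(id = letters[1:8],
                                    unit = rep(c("1", "2"), each = 4),
                                    phenotype = 0))
  des <- build_design(phe)
  K <- relationship_matrix(diag(8), source = "genomic")
  dimnames(K) <- list(letters[1:8], letters[1:8])
  # lambda huge: PEV = prior, CD -> 0
  vc_hi <- variance_components(sigma2_u = 1, sigma2_e = 1e8)
  ps_hi <- pev(build_mme(des, regularize_and_invert(K), vc_hi))
  expect_lt(abs(cd_pairwise(ps_hi, K, 1, 5)), 1e-4)
  x <- unit_contrast(ps_hi, "1", "2")
  expect_lt(abs(cd_contrast(ps_hi, K, x)), 1e-4)
  # lambda tiny: PEV -> 0 and CD -> 1 for a within-unit pair (an
  # across-unit difference keeps residual PEV from the confounded unit
  # effect, so the perfect-knowledge limit is a within-unit property)
  vc_lo <- variance_components(sigma2_u = 1, sigma2_e = 1e-8)
  ps_lo <- pev(build_mme(des, regularize_and_invert(K), vc_lo))
  expect_gt(cd_pairwise(ps_lo, K, 1, 2), 0.95)
  # toy oracle: 1 - PEVD / (sigma2_u * d'Kd)
  s <- sim_system(seed = 31)
  d <- numeric(s$sys$q)
  d[c(2, 9)] <- c(1, -1)
  expect_equal(cd_pairwise(s$ps, s$K, 2, 9),
               1 - pevd_pairwise(s$ps, 2, 9) /
                 (s$vc$sigma2_u * drop(crossprod(d, unclass(s$K) %*% d))))
})

test_that("CD group average matches a stepwise hand evaluation", {
  s <- sim_system(seed = 14, n_units = 3)
  K <- unclass(s$K)
  ui <- s$ps$unit_index
  kbar <- function(a, b) mean(K[ui[[a]], ui[[b]], drop = FALSE])
  hand <- 1 - pevd_grpave(s$ps)$matrix[1, 2] /
    (s$vc$sigma2_u * (kbar(1, 1) + kbar(2, 2) - 2 * kbar(1, 2)))
  expect_equal(cd_grpave(s$ps, s$K)$matrix[1, 2], hand)
})

test_that("CD individual average is the printed ratio of sums, not a mean of CDs", {
  s <- sim_system(seed = 12, n_units = 3)
  P <- s$ps$PEV
  K <- unclass(s$K)
  ui <- s$ps$unit_index
  num <- den <- 0
  cds <- c()
  for (i in ui[[1]]) {
    for (j in ui[[2]]) {
      pevd_ij <- P[i, i] + P[j, j] - 2 * P[i, j]
      kd_ij <- K[i, i] + K[j, j] - 2 * K[i, j]
      num <- num + pevd_ij
      den <- den + kd_ij
      cds <- c(cds, 1 - pevd_ij / (s$vc$sigma2_u * kd_ij))
    }
  }
  got <- cd_idave(s$ps, s$K)$matrix[1, 2]
  expect_equal(got, 1 - num / (s$vc$sigma2_u * den))
  expect_gt(abs(got - mean(cds)), 1e-6)  # the naive mean measurably differs
})

test_that("genetically degenerate pairs are reported as NA, not zero", {
  # duplicate an individual's K row: the pair has no prior contrast variance
  K <- diag(4)
  K[1, 2] <- K[2, 1] <- 1
  dimnames(K) <- list(letters[1:4], letters[1:4])
  phe <- phenotype_table(data.frame(id = letters[1:4],
                                    unit = c("1", "2", "1", "2"),
                                    phenotype = 0))
  des <- build_design(phe)
  vc <- variance_components(h2 = 0.5)
  Kinv <- suppressWarnings(regularize_and_invert(K))
  ps <- pev(build_mme(des, Kinv, vc))
  expect_warning(v <- cd_pairwise(ps, K, "a", "b"), "undefined")
  expect_true(is.na(v))
})

test_that("group-average r matches its block-mean definition and the VE bridge", {
  s <- sim_system(seed = 16)
  bm <- pev_blockmean(s$ps)
  expect_equal(r_grpave(s$ps)$matrix[1, 2],
               bm[1, 2] / sqrt(bm[1, 1] * bm[2, 2]))
  # r, CD, PEVD bridges through corrected VE on a unit-only model
  v1 <- ve1(s$sys)
  expect_lt(max(abs(ved(v1)$matrix - pevd_grpave(s$ps)$matrix)), 1e-8)
  expect_lt(max(abs(cdved(v1, s$K)$matrix - cd_grpave(s$ps, s$K)$matrix)),
            1e-8)
  expect_lt(max(abs(cr(v1)$matrix - r_grpave(s$ps)$matrix)), 1e-8)
})

test_that("VE-based statistics mirror their definitions and corrections", {
  s <- sim_system(seed = 16)
  v0 <- ve0(s$sys)
  v1 <- ve1(s$sys)
  # VED self-pairs vanish by construction
  expect_equal(diag(ved(v0)$matrix), rep(0, 3), ignore_attr = TRUE)
  # c=0 minus c=1 difference is exactly s2e * (1/n_i + 1/n_j)
  dd <- ved(v0)$matrix - ved(v1)$matrix
  n <- s$des$n_unit
  expected <- s$vc$sigma2_e * outer(1 / n, 1 / n, `+`)
  diag(expected) <- 0
  expect_lt(max(abs(dd - expected)), 1e-10)
  # CR diagonal is 1; constant VE gives CR 1 and CDVED 1 when VED = 0
  VEc <- matrix(0.2, 3, 3, dimnames = list(s$des$units, s$des$units))
  vfake <- v1
  vfake$VE <- VEc
  expect_equal(cr(vfake)$matrix[1, 2], 1)
  expect_equal(cdved(vfake, s$K)$matrix[1, 2], 1)
  # zero off-diagonal VE gives CR 0
  vdiag <- v1
  vdiag$VE <- diag(0.2, 3)
  dimnames(vdiag$VE) <- list(s$des$units, s$des$units)
  expect_equal(cr(vdiag)$matrix[1, 2], 0)
})

test_that("the c = 2 bridge holds on models with an extra fixed effect", {
  s <- sim_system("sex", seed = 19)
  v2 <- ve2(s$sys)
  expect_lt(max(abs(ved(v2)$matrix - pevd_grpave(s$ps)$matrix)), 1e-8)
  expect_lt(max(abs(cdved(v2, s$K)$matrix - cd_grpave(s$ps, s$K)$matrix)),
            1e-8)
  expect_lt(max(abs(cr(v2)$matrix - r_grpave(s$ps)$matrix)), 1e-8)
})

test_that("overall is the mean of the off-diagonal upper triangle", {
  m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  res <- unit_pair_result("PEVD", "GrpAve", matrix = m)
  expect_equal(overall(res), 2)
  expect_equal(res$overall, 2)
  m2 <- matrix(5, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unit_pair_result("X", matrix = m2)$overall, 5)
})

test_that("statistics are invariant to permuting individuals within the system", {
  s <- sim_system(seed = 25)
  set.seed(1)
  perm <- sample(s$sys$q)
  K2 <- unclass(s$K)[perm, perm]
  phe2 <- phenotype_table(as.data.frame(s$pop$phe), id_col = "progeny")
  des2 <- build_design(phe2, ids = rownames(K2))
  sys2 <- build_mme(des2, regularize_and_invert(K2), s$vc)
  ps2 <- pev(sys2)
  expect_equal(pevd_grpave(ps2)$matrix, pevd_grpave(s$ps)$matrix,
               tolerance = 1e-9)
  expect_equal(cd_grpave(ps2, K2)$matrix, cd_grpave(s$ps, s$K)$matrix,
               tolerance = 1e-9)
  expect_equal(r_grpave(ps2)$matrix, r_grpave(s$ps)$matrix,
               tolerance = 1e-9)
})

test_that("across-unit sire links strengthen connectedness monotonically", {
  ladder <- c(0, 2, 5, 10)
  rs <- cds <- pevds <- numeric(length(ladder))
  for (k in seq_along(ladder)) {
    d <- linked_design(ladder[k])
    rs[k] <- r_grpave(d$ps)$matrix["A", "B"]
    cds[k] <- cd_grpave(d$ps, d$A)$matrix["A", "B"]
    pevds[k] <- pevd_grpave(d$ps)$matrix["A", "B"]
  }
  expect_true(all(diff(rs) > 0))
  expect_true(all(diff(cds) > 0))
  expect_true(all(diff(pevds) < 0))
  # full disconnection: no prediction error correlation across units
  expect_lt(abs(rs[1]), 1e-10)
})
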