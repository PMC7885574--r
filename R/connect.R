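#' Unit-pair connectedness result
#'
#' Container for one connectedness statistic evaluated over all pairs of
#' units: a symmetric units x units matrix plus the overall scalar (the
#' unweighted mean of the strictly off-diagonal upper-triangle entries).
#' Difference-type statistics (PEVD, VED) have zero diagonal; ratio-type
#' statistics (CD, r, CDVED, CR) report 1 on the diagonal, where the
#' pairwise formula degenerates to a self-comparison. Pairs whose
#' denominator falls below the degeneracy tolerance are reported as `NA`
#' (undefined), never silently zeroed.
#'
#' @param statistic statistic name, e.g. `"PEVD"`.
#' @param summary `"IdAve"`, `"GrpAve"`, `"Contrast"` or `NA`.
#' @param correction 0, 1, 2 for VE-based statistics, else `NA`.
#' @param matrix symmetric units x units matrix with unit labels.
#' @return An object of class `unit_pair_result`.
#' @export
unit_pair_result <- function(statistic, summary = NA_character_,
                             correction = NA_integer_, matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  res <- structure(list(statistic = statistic, summary = summary,
                        correction = correction, matrix = matrix,
                        overall = NA_real_),
                   class = "unit_pair_result")
  res$overall <- overall(res)
  res
}

#' Overall connectedness across units
#'
#' The average of the pairwise connectedness statistics across units:
#' the unweighted mean of the strictly off-diagonal (upper-triangle)
#' entries of the unit-pair matrix.
#'
#' @param result a [unit_pair_result()].
#' @param na.rm drop undefined pairs before averaging (default `FALSE`).
#' @return Scalar.
#' @export
overall <- function(result, na.rm = FALSE) {
  stopifnot(inherits(result, "unit_pair_result"))
  mean(result$matrix[upper.tri(result$matrix)], na.rm = na.rm)
}

#' @export
print.unit_pair_result <- function(x, digits = 4, ...) {
  lab <- x$statistic
  if (!is.na(x$summary)) lab <- paste(lab, x$summary, sep = "_")
  if (!is.na(x$correction)) lab <- paste0(lab, x$correction)
  cat(lab, "connectedness across units\n")
  print(round(x$matrix, digits), ...)
  cat("overall:", format(x$overall, digits = digits), "\n")
  invisible(x)
}

## tolerance below which a contrast/denominator is treated as degenerate
.DEGEN_TOL <- 1e-10

.resolve_idx <- function(pev_store, i) {
  if (is.character(i)) {
    k <- match(i, rownames(pev_store$PEV))
    if (is.na(k)) stop("unknown individual id: ", i, call. = FALSE)
    k
  } else {
    as.integer(i)
  }
}

#' Contrast vector for a pair of units
#'
#' Builds the unit-pair contrast **x** over all individuals of the PEV
#' matrix: `1/n_i` for phenotyped members of unit `i`, `-1/n_j` for
#' members of unit `j`, 0 elsewhere, so the elements sum to zero and
#' `x'u` is the difference between the two unit means of breeding values.
#'
#' @param pev_store a [pev()] result.
#' @param i,j unit labels.
#' @return Numeric vector named by individual id.
#' @export
unit_contrast <- function(pev_store, i, j) {
  stopifnot(inherits(pev_store, "pev_store"))
  i <- as.character(i)
  j <- as.character(j)
  if (!all(c(i, j) %in% pev_store$units) || i == j) {
    stop("need two distinct unit labels among: ",
         paste(pev_store$units, collapse = ", "), call. = FALSE)
  }
  x <- numeric(nrow(pev_store$PEV))
  names(x) <- rownames(pev_store$PEV)
  x[pev_store$unit_index[[i]]] <- 1 / length(pev_store$unit_index[[i]])
  x[pev_store$unit_index[[j]]] <- -1 / length(pev_store$unit_index[[j]])
  x
}

.check_contrast <- function(x, n) {
  if (length(x) != n) {
    stop("contrast length ", length(x), " does not match the ", n,
         " individuals of the PEV matrix", call. = FALSE)
  }
  if (abs(sum(x)) > 1e-12) {
    stop("contrast elements must sum to zero (got ", format(sum(x)), ")",
         call. = FALSE)
  }
  if (all(x == 0)) {
    stop("contrast is identically zero: no units are compared", call. = FALSE)
  }
  invisible(x)
}

## --------------------------------------------------------------------
## PEVD: prediction error variance of the difference
## --------------------------------------------------------------------

#' Pairwise PEVD between two individuals
#'
#' `PEVD(u_i - u_j) = PEV_ii + PEV_jj - 2 PEC_ij`: the variance of the
#' error of the predicted difference in breeding values. Small PEVD means
#' the two individuals can be compared reliably.
#'
#' @param pev_store a [pev()] result.
#' @param i,j individual ids (character) or positions.
#' @return Scalar.
#' @export
pevd_pairwise <- function(pev_store, i, j) {
  stopifnot(inherits(pev_store, "pev_store"))
  i <- .resolve_idx(pev_store, i)
  j <- .resolve_idx(pev_store, j)
  P <- pev_store$PEV
  P[i, i] + P[j, j] - 2 * P[i, j]
}

#' Group-average PEVD across units
#'
#' Applies the PEVD formula to the within- and between-unit block means
#' of the PEV matrix: `PEVD_i'j' = PEVmean_i'i' + PEVmean_j'j' -
#' 2 PECmean_i'j'`. With diagonal-inclusive block means this equals the
#' contrast summary [pevd_contrast()] for the unit-pair contrast.
#'
#' @inheritParams pev_blockmean
#' @return A [unit_pair_result()].
#' @export
pevd_grpave <- function(pev_store, include_diagonal = TRUE) {
  bm <- pev_blockmean(pev_store, include_diagonal)
  d <- diag(bm)
  unit_pair_result("PEVD", "GrpAve",
                   matrix = outer(d, d, `+`) - 2 * bm)
}

#' Individual-average PEVD across units
#'
#' Averages [pevd_pairwise()] over all cross-unit pairs of individuals.
#'
#' @param pev_store a [pev()] result.
#' @return A [unit_pair_result()].
#' @export
pevd_idave <- function(pev_store) {
  stopifnot(inherits(pev_store, "pev_store"))
  P <- pev_store$PEV
  ui <- pev_store$unit_index
  k <- length(ui)
  out <- matrix(0, k, k, dimnames = list(names(ui), names(ui)))
  dmean <- vapply(ui, function(ix) mean(diag(P)[ix]), numeric(1))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a < b) {
        cross <- mean(P[ui[[a]], ui[[b]], drop = FALSE])
        out[a, b] <- out[b, a] <- dmean[a] + dmean[b] - 2 * cross
      }
    }
  }
  unit_pair_result("PEVD", "IdAve", matrix = out)
}

#' PEVD of a contrast
#'
#' The quadratic form `x' PEV x` for a zero-sum contrast vector **x**,
#' e.g. a unit-pair contrast from [unit_contrast()].
#'
#' @param pev_store a [pev()] result.
#' @param x contrast vector over the individuals of the PEV matrix.
#' @return Scalar.
#' @export
pevd_contrast <- function(pev_store, x) {
  stopifnot(inherits(pev_store, "pev_store"))
  .check_contrast(x, nrow(pev_store$PEV))
  drop(crossprod(x, pev_store$PEV %*% x))
}

## --------------------------------------------------------------------
## CD: coefficient of determination
## --------------------------------------------------------------------

.align_K <- function(K, pev_store) {
  K <- as.matrix(K)
  ids <- rownames(pev_store$PEV)
  if (is.null(rownames(K)) || !all(ids %in% rownames(K))) {
    if (nrow(K) != length(ids)) {
      stop("K does not cover the individuals of the PEV matrix",
           call. = FALSE)
    }
    dimnames(K) <- list(ids, ids)
  }
  K[ids, ids, drop = FALSE]
}

#' Pairwise coefficient of determination between two individuals
#'
#' `CD_ij = 1 - PEVD_ij / (sigma2_u * (K_ii + K_jj - 2 K_ij))`: the
#' PEVD scaled by the prior variance of the difference in breeding
#' values. Unlike PEVD, CD penalizes comparisons between individuals that
#' are genetically near-identical: when `K_ii + K_jj - 2 K_ij` falls
#' below the degeneracy tolerance the contrast has no prior variance and
#' the statistic is undefined (`NA`, with a warning).
#'
#' @param pev_store a [pev()] result (its variance components supply
#'   `sigma2_u`, keeping the scaling consistent with the MME).
#' @param K the relationship matrix used in the MME.
#' @param i,j individual ids or positions.
#' @return Scalar, at most 1; `NA` if the pair is genetically degenerate.
#' @export
cd_pairwise <- function(pev_store, K, i, j) {
  stopifnot(inherits(pev_store, "pev_store"))
  K <- .align_K(K, pev_store)
  i <- .resolve_idx(pev_store, i)
  j <- .resolve_idx(pev_store, j)
  den <- pev_store$varcomp$sigma2_u * (K[i, i] + K[j, j] - 2 * K[i, j])
  if (den <= .DEGEN_TOL) {
    warning("prior variance of the contrast is ~0 (genetically identical ",
            "pair): CD undefined", call. = FALSE)
    return(NA_real_)
  }
  1 - pevd_pairwise(pev_store, i, j) / den
}

#' Group-average CD across units
#'
#' Scales the group-average PEVD by the prior variance of the unit-mean
#' difference computed from the block means of **K**:
#' `CD_i'j' = 1 - PEVD_GrpAve_i'j' / (sigma2_u * (Kmean_i'i' +
#' Kmean_j'j' - 2 Kmean_i'j'))`. Equals [cd_contrast()] on the unit-pair
#' contrast under diagonal-inclusive block means.
#'
#' @inheritParams cd_pairwise
#' @inheritParams pev_blockmean
#' @return A [unit_pair_result()]; degenerate pairs are `NA`.
#' @export
cd_grpave <- function(pev_store, K, include_diagonal = TRUE) {
  K <- .align_K(K, pev_store)
  num <- pevd_grpave(pev_store, include_diagonal)$matrix
  Kbm <- .blockmean(K, pev_store$unit_index, include_diagonal)
  d <- diag(Kbm)
  den <- pev_store$varcomp$sigma2_u * (outer(d, d, `+`) - 2 * Kbm)
  out <- 1 - num / den
  bad <- den <= .DEGEN_TOL & upper.tri(den)
  if (any(bad)) {
    warning(sum(bad), " unit pair(s) have ~0 prior contrast variance: ",
            "CD undefined (NA)", call. = FALSE)
    out[den <= .DEGEN_TOL] <- NA_real_
  }
  diag(out) <- 1
  unit_pair_result("CD", "GrpAve", matrix = out)
}

#' Individual-average CD across units
#'
#' The printed ratio-of-sums form: `1 - sum(PEVD_ij) / (sigma2_u *
#' sum(K_ii + K_jj - 2 K_ij))` over all cross-unit pairs of individuals.
#' Note this averages numerator and denominator separately; it is not the
#' mean of pairwise CD values (the two differ whenever the pairwise
#' denominators vary).
#'
#' @inheritParams cd_pairwise
#' @return A [unit_pair_result()].
#' @export
cd_idave <- function(pev_store, K) {
  stopifnot(inherits(pev_store, "pev_store"))
  K <- .align_K(K, pev_store)
  P <- pev_store$PEV
  ui <- pev_store$unit_index
  k <- length(ui)
  out <- matrix(1, k, k, dimnames = list(names(ui), names(ui)))
  warned <- 0L
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a < b) {
        ia <- ui[[a]]
        ib <- ui[[b]]
        na <- length(ia)
        nb <- length(ib)
        num <- nb * sum(diag(P)[ia]) + na * sum(diag(P)[ib]) -
          2 * sum(P[ia, ib])
        den <- nb * sum(diag(K)[ia]) + na * sum(diag(K)[ib]) -
          2 * sum(K[ia, ib])
        den <- pev_store$varcomp$sigma2_u * den
        if (den <= .DEGEN_TOL) {
          warned <- warned + 1L
          out[a, b] <- out[b, a] <- NA_real_
        } else {
          out[a, b] <- out[b, a] <- 1 - num / den
        }
      }
    }
  }
  if (warned) {
    warning(warned, " unit pair(s) have ~0 summed prior contrast ",
            "variance: CD undefined (NA)", call. = FALSE)
  }
  unit_pair_result("CD", "IdAve", matrix = out)
}

#' CD of a contrast
#'
#' `CD(x) = 1 - x'PEV x / (sigma2_u * x'Kx)` for a zero-sum contrast
#' vector.
#'
#' @inheritParams cd_pairwise
#' @param x contrast vector over individuals.
#' @return Scalar; `NA` when `x'Kx` is below the degeneracy tolerance.
#' @export
cd_contrast <- function(pev_store, K, x) {
  stopifnot(inherits(pev_store, "pev_store"))
  K <- .align_K(K, pev_store)
  .check_contrast(x, nrow(pev_store$PEV))
  den <- pev_store$varcomp$sigma2_u * drop(crossprod(x, K %*% x))
  if (den <= .DEGEN_TOL) {
    warning("x'Kx is ~0: CD of this contrast is undefined", call. = FALSE)
    return(NA_real_)
  }
  1 - pevd_contrast(pev_store, x) / den
}

## --------------------------------------------------------------------
## r: prediction error correlation
## --------------------------------------------------------------------

#' Pairwise prediction error correlation
#'
#' `r_ij = PEC_ij / sqrt(PEV_ii * PEV_jj)`, the correlation between the
#' prediction errors of two breeding values.
#'
#' @inheritParams pevd_pairwise
#' @return Scalar in `[-1, 1]`; `NA` (with warning) if a diagonal PEV is
#'   zero.
#' @export
r_pairwise <- function(pev_store, i, j) {
  stopifnot(inherits(pev_store, "pev_store"))
  i <- .resolve_idx(pev_store, i)
  j <- .resolve_idx(pev_store, j)
  P <- pev_store$PEV
  den <- sqrt(P[i, i] * P[j, j])
  if (den <= .DEGEN_TOL) {
    warning("zero PEV diagonal: r undefined", call. = FALSE)
    return(NA_real_)
  }
  P[i, j] / den
}

#' Group-average r across units ("flock connectedness")
#'
#' `r_i'j' = PECmean_i'j' / sqrt(PEVmean_i'i' * PEVmean_j'j')` — the
#' block-sum and block-mean forms coincide because the `1/n` factors
#' cancel.
#'
#' @inheritParams pev_blockmean
#' @return A [unit_pair_result()] with unit diagonal.
#' @export
r_grpave <- function(pev_store, include_diagonal = TRUE) {
  bm <- pev_blockmean(pev_store, include_diagonal)
  d <- diag(bm)
  out <- bm / sqrt(outer(d, d))
  diag(out) <- 1
  unit_pair_result("r", "GrpAve", matrix = out)
}

#' Individual-average r across units
#'
#' Mean of [r_pairwise()] over all cross-unit pairs of individuals.
#'
#' @param pev_store a [pev()] result.
#' @return A [unit_pair_result()].
#' @export
r_idave <- function(pev_store) {
  stopifnot(inherits(pev_store, "pev_store"))
  R <- stats::cov2cor(pev_store$PEV)
  ui <- pev_store$unit_index
  k <- length(ui)
  out <- matrix(1, k, k, dimnames = list(names(ui), names(ui)))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a < b) {
        out[a, b] <- out[b, a] <- mean(R[ui[[a]], ui[[b]], drop = FALSE])
      }
    }
  }
  unit_pair_result("r", "IdAve", matrix = out)
}

#' r of a contrast
#'
#' The quadratic form `x' r x` of a zero-sum contrast over the full
#' pairwise prediction-error-correlation matrix (unit diagonal).
#' Implemented literally; it is not normalized to `[-1, 1]`.
#'
#' @param pev_store a [pev()] result.
#' @param x contrast vector over individuals.
#' @return Scalar.
#' @export
r_contrast <- function(pev_store, x) {
  stopifnot(inherits(pev_store, "pev_store"))
  .check_contrast(x, nrow(pev_store$PEV))
  R <- stats::cov2cor(pev_store$PEV)
  drop(crossprod(x, R %*% x))
}

## --------------------------------------------------------------------
## VE-based statistics: VED, CDVED, CR
## --------------------------------------------------------------------

#' Variance of differences in unit effects (VEDc)
#'
#' `VEDc_i'j' = VEc_i'i' + VEc_j'j' - 2 VEc_i'j'`, a PEVD-like
#' connectedness statistic computed directly from the variance of
#' unit-effect estimates — a single-step, unit-level analogue of
#' [pevd_grpave()]. With correction 1 (or 2, with extra fixed effects)
#' it reproduces the group-average PEVD exactly.
#'
#' @param ve a [ve0()], [ve1()] or [ve2()] result.
#' @return A [unit_pair_result()] with the VE correction tag.
#' @export
ved <- function(ve) {
  stopifnot(inherits(ve, "ve_store"))
  d <- diag(ve$VE)
  unit_pair_result("VED", correction = ve$correction,
                   matrix = outer(d, d, `+`) - 2 * ve$VE)
}

#' Coefficient of determination of VED (CDVEDc)
#'
#' `CDVEDc_i'j' = 1 - VEDc_i'j' / (sigma2_u * (Kmean_i'i' + Kmean_j'j' -
#' 2 Kmean_i'j'))` with diagonal-inclusive block means of **K** over the
#' phenotyped members of each unit.
#'
#' @param ve a `ve_store`.
#' @param K the relationship matrix used in the MME.
#' @param include_diagonal include diagonal elements in the **K** block
#'   means (default `TRUE`).
#' @return A [unit_pair_result()]; degenerate pairs are `NA`.
#' @export
cdved <- function(ve, K, include_diagonal = TRUE) {
  stopifnot(inherits(ve, "ve_store"))
  K <- as.matrix(K)
  Kbm <- .blockmean(K, ve$unit_index, include_diagonal)
  num <- ved(ve)$matrix
  d <- diag(Kbm)
  den <- ve$varcomp$sigma2_u * (outer(d, d, `+`) - 2 * Kbm)
  out <- 1 - num / den
  bad <- den <= .DEGEN_TOL & upper.tri(den)
  if (any(bad)) {
    warning(sum(bad), " unit pair(s) have ~0 prior contrast variance: ",
            "CDVED undefined (NA)", call. = FALSE)
    out[den <= .DEGEN_TOL] <- NA_real_
  }
  diag(out) <- 1
  unit_pair_result("CDVED", correction = ve$correction, matrix = out)
}

#' Connectedness rating (CRc)
#'
#' `CRc_i'j' = VEc_i'j' / sqrt(VEc_i'i' * VEc_j'j')`, the
#' correlation-form statistic over the variance of unit-effect
#' estimates. With no correction (c = 0) this is the classical
#' connectedness rating; with correction 1 it reproduces the
#' group-average prediction error correlation.
#'
#' @param ve a `ve_store`.
#' @return A [unit_pair_result()] with unit diagonal; pairs with a
#'   non-positive corrected VE diagonal are `NA` (flagged).
#' @export
cr <- function(ve) {
  stopifnot(inherits(ve, "ve_store"))
  d <- diag(ve$VE)
  if (any(d <= .DEGEN_TOL)) {
    warning("non-positive VE diagonal for unit(s): ",
            paste(ve$units[d <= .DEGEN_TOL], collapse = ", "),
            "; CR undefined there", call. = FALSE)
    d[d <= .DEGEN_TOL] <- NA_real_
  }
  out <- ve$VE / sqrt(outer(d, d))
  diag(out) <- ifelse(is.na(d), NA_real_, 1)
  unit_pair_result("CR", correction = ve$correction, matrix = out)
}
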