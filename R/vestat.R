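#' Block means of a PEV matrix over units
#'
#' Averages the PEV matrix within and between unit blocks: entry
#' (i', j') is the mean of all `n_i * n_j` elements of the block of
#' `PEV` formed by the phenotyped members of units i' and j'. Diagonal
#' PEV elements are included in the within-unit means by default
#' (the Kennedy-and-Trus convention, under which the unit-effect
#' corrections `ve1()`/`ve2()` recover these block means exactly and the
#' group-average and contrast summaries coincide); set
#' `include_diagonal = FALSE` to average off-diagonal elements only.
#'
#' @param pev_store a [pev()] result.
#' @param include_diagonal include the diagonal PEV elements in
#'   within-unit means (default `TRUE`).
#' @return units x units symmetric matrix of block means.
#' @export
pev_blockmean <- function(pev_store, include_diagonal = TRUE) {
  stopifnot(inherits(pev_store, "pev_store"))
  .blockmean(pev_store$PEV, pev_store$unit_index, include_diagonal)
}

.blockmean <- function(S, unit_index, include_diagonal = TRUE) {
  units <- names(unit_index)
  k <- length(units)
  out <- matrix(0, k, k, dimnames = list(units, units))
  for (i in seq_len(k)) {
    for (j in i:k) {
      B <- S[unit_index[[i]], unit_index[[j]], drop = FALSE]
      if (i == j && !include_diagonal) {
        n <- nrow(B)
        m <- if (n > 1L) (sum(B) - sum(diag(B))) / (n * (n - 1L)) else NA_real_
      } else {
        m <- mean(B)
      }
      out[i, j] <- out[j, i] <- m
    }
  }
  out
}

.ve_store <- function(VE, correction, system) {
  units <- system$design$units
  VE <- (VE + t(VE)) / 2
  dimnames(VE) <- list(units, units)
  structure(list(VE = VE, correction = correction,
                 units = units,
                 n_unit = system$design$n_unit,
                 unit_index = system$design$unit_index,
                 varcomp = system$varcomp),
            class = "ve_store")
}

#' @export
print.ve_store <- function(x, ...) {
  cat(sprintf("variance of unit-effect estimates, correction %d\n",
              x$correction))
  print(x$VE, ...)
  invisible(x)
}

#' Uncorrected variance of unit-effect estimates (VE0)
#'
#' The unit block of `Var(b_hat) = C11 * sigma2_e`. This is the classical
#' approximation to the mean PEV over units: it overstates the block
#' means by the sampling noise of the unit means (see [ve1()] for the
#' exact correction).
#'
#' @param system an [build_mme()] result.
#' @return A `ve_store` with `correction = 0`.
#' @export
ve0 <- function(system) {
  stopifnot(inherits(system, "mme_system"))
  Vb <- fixed_effect_covariance(system)
  ui <- seq_len(ncol(system$design$X1))
  .ve_store(Vb[ui, ui, drop = FALSE], 0L, system)
}

#' Corrected VE for a unit-only model (VE1)
#'
#' When unit is the only fixed effect, subtracting the record-number
#' correction `sigma2_e * (X'X)^{-1}` (a diagonal matrix with entries
#' `sigma2_e / n_i`) from `Var(b_hat)` recovers the block means of the
#' PEV matrix exactly: `VE1 = PEV_mean`. Off-diagonal entries are those
#' of `Var(b_hat)` unchanged, since the correction is diagonal.
#'
#' @param system an [build_mme()] result whose only fixed effect is unit.
#' @return A `ve_store` with `correction = 1`.
#' @export
ve1 <- function(system) {
  stopifnot(inherits(system, "mme_system"))
  if (ncol(system$design$X2) > 0L) {
    stop("ve1 applies only when unit is the sole fixed effect; this ",
         "model has additional fixed effects - use ve2()", call. = FALSE)
  }
  Vb <- fixed_effect_covariance(system)
  corr <- diag(system$varcomp$sigma2_e / system$design$n_unit,
               length(system$design$n_unit))
  .ve_store(Vb - corr, 1L, system)
}

#' Corrected VE with additional fixed effects (VE2)
#'
#' With unit plus at least one other fixed effect in the model, the exact
#' recovery of the PEV block means needs, beyond the record-number
#' correction of [ve1()], terms that push the variance of the other
#' fixed-effect estimates and their covariance with the unit estimates
#' back onto the unit scale:
#' \deqn{VE_2 = Var(\hat b_1) - \sigma^2_e (X_1'X_1)^{-1}
#'   + T X_1'X_2 Var(\hat b_2) X_2'X_1 T
#'   + T X_1'X_2 Cov(\hat b_2, \hat b_1)
#'   + Cov(\hat b_1, \hat b_2) X_2'X_1 T}
#' with \eqn{T = (X_1'X_1)^{-1}}, \eqn{X_1} the unit columns and
#' \eqn{X_2} all remaining fixed-effect columns taken as one block. The
#' two covariance terms are transposes, so the result is symmetric by
#' construction.
#'
#' @param system an [build_mme()] result with unit plus >= 1 extra fixed
#'   effect.
#' @return A `ve_store` with `correction = 2`.
#' @export
ve2 <- function(system) {
  stopifnot(inherits(system, "mme_system"))
  X1 <- system$design$X1
  X2 <- system$design$X2
  if (ncol(X2) == 0L) {
    stop("ve2 needs at least one fixed effect beyond unit; for a ",
         "unit-only model use ve1()", call. = FALSE)
  }
  Vb <- fixed_effect_covariance(system)
  p1 <- ncol(X1)
  i1 <- seq_len(p1)
  i2 <- (p1 + 1L):ncol(system$design$X)
  V1 <- Vb[i1, i1, drop = FALSE]
  V2 <- Vb[i2, i2, drop = FALSE]
  C12 <- Vb[i1, i2, drop = FALSE]          # Cov(b1_hat, b2_hat)
  Tm <- diag(1 / system$design$n_unit, p1)  # (X1'X1)^{-1}
  A <- Tm %*% crossprod(X1, X2)
  VE <- V1 - system$varcomp$sigma2_e * Tm +
    A %*% V2 %*% t(A) + A %*% t(C12) + C12 %*% t(A)
  .ve_store(VE, 2L, system)
}
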