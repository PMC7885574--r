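#' Variance components for the mixed model
#'
#' The mixed model equations need the additive genetic variance
#' `sigma2_u`, the residual variance `sigma2_e`, and their ratio
#' `lambda = sigma2_e / sigma2_u` (the BLUP shrinkage parameter). Either
#' supply the two variances directly, or supply a heritability `h2`, in
#' which case the phenotypic variance is normalized to 1 so that
#' `sigma2_u = h2` and `sigma2_e = 1 - h2`. Variance components are
#' treated as known; no estimation is performed.
#'
#' @param sigma2_u additive genetic variance (> 0).
#' @param sigma2_e residual variance (> 0).
#' @param h2 narrow-sense heritability in (0, 1); alternative to the two
#'   variances.
#' @return An object of class `variance_components` with fields
#'   `sigma2_u`, `sigma2_e`, `lambda`.
#' @examples
#' variance_components(h2 = 0.5)        # lambda = 1
#' variance_components(sigma2_u = 2, sigma2_e = 1)
#' @export
variance_components <- function(sigma2_u = NULL, sigma2_e = NULL, h2 = NULL) {
  if (!is.null(h2)) {
    if (!is.null(sigma2_u) || !is.null(sigma2_e)) {
      stop("give either h2 or (sigma2_u, sigma2_e), not both", call. = FALSE)
    }
    if (!is.numeric(h2) || length(h2) != 1L || h2 <= 0 || h2 >= 1) {
      stop("h2 must be a single number in (0, 1)", call. = FALSE)
    }
    sigma2_u <- h2
    sigma2_e <- 1 - h2
  }
  if (is.null(sigma2_u) || is.null(sigma2_e) ||
      sigma2_u <= 0 || sigma2_e <= 0) {
    stop("sigma2_u and sigma2_e must both be positive", call. = FALSE)
  }
  structure(list(sigma2_u = sigma2_u, sigma2_e = sigma2_e,
                 lambda = sigma2_e / sigma2_u),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("sigma2_u = %g, sigma2_e = %g, lambda = %g\n",
              x$sigma2_u, x$sigma2_e, x$lambda))
  invisible(x)
}

#' Validate a phenotype table
#'
#' One record per individual, each carrying a unit (contemporary group)
#' label, optional categorical fixed effects such as sex, and a phenotype
#' value. Connectedness is only defined between at least two units.
#'
#' @param df data frame with at least the id, unit and phenotype columns.
#' @param id_col,unit_col,pheno_col column names (defaults `"id"`,
#'   `"unit"`, `"phenotype"`).
#' @return The validated data frame, class `phenotype_table`, with
#'   attributes recording the column roles.
#' @export
phenotype_table <- function(df, id_col = "id", unit_col = "unit",
                            pheno_col = "phenotype") {
  for (cl in c(id_col, unit_col, pheno_col)) {
    if (!cl %in% names(df)) {
      stop("phenotype table lacks column '", cl, "'", call. = FALSE)
    }
  }
  df[[id_col]] <- as.character(df[[id_col]])
  df[[unit_col]] <- as.character(df[[unit_col]])
  if (anyDuplicated(df[[id_col]])) {
    stop("repeated records per individual are not supported; found ",
         "duplicate id(s): ",
         paste(unique(df[[id_col]][duplicated(df[[id_col]])]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(df[[unit_col]]) || any(df[[unit_col]] == "")) {
    stop("every record needs a non-missing unit label", call. = FALSE)
  }
  if (length(unique(df[[unit_col]])) < 2L) {
    stop("connectedness needs at least 2 distinct units", call. = FALSE)
  }
  structure(df, id_col = id_col, unit_col = unit_col, pheno_col = pheno_col,
            class = c("phenotype_table", "data.frame"))
}

#' Incidence matrices for the mixed model
#'
#' Builds the fixed-effect incidence matrix `X` and the random-effect
#' incidence matrix `Z` for the model `y = Xb + Zu + e`. The unit effect
#' is always fitted, first, with full one-hot coding and no intercept, so
#' every unit-effect variance is directly available; each additional
#' categorical effect is reference-coded (first level dropped) to keep `X`
#' full rank. `Z` has one 1 per record, mapping records onto the
#' individuals of **K** in the order of `ids`; individuals in **K**
#' without records get all-zero columns so their breeding values are still
#' predicted.
#'
#' @param pheno a [phenotype_table()].
#' @param fixed_effects character vector of extra fixed-effect column
#'   names (beyond unit), e.g. `"sex"`; may be empty.
#' @param ids individual ids in **K** order; defaults to the phenotyped
#'   ids in record order.
#' @return An object of class `design_matrices`: list with `X`, `X1`
#'   (unit block), `X2` (other effects, possibly 0 columns), `Z`, `unit`
#'   (factor over records), `units` (levels), `n_unit` (records per
#'   unit), `ids`, and `unit_index` (unit -> positions of its phenotyped
#'   individuals in `ids` order).
#' @export
build_design <- function(pheno, fixed_effects = character(), ids = NULL) {
  stopifnot(inherits(pheno, "phenotype_table"))
  id_col <- attr(pheno, "id_col")
  unit_col <- attr(pheno, "unit_col")
  unknown <- setdiff(fixed_effects, names(pheno))
  if (length(unknown)) {
    stop("fixed effect column(s) not in phenotype table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (unit_col %in% fixed_effects) {
    fixed_effects <- setdiff(fixed_effects, unit_col)
  }
  if (is.null(ids)) ids <- pheno[[id_col]]
  ids <- as.character(ids)
  miss <- setdiff(pheno[[id_col]], ids)
  if (length(miss)) {
    stop(length(miss), " phenotyped individual(s) absent from the ",
         "relationship matrix, e.g.: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  n <- nrow(pheno)
  unit <- factor(pheno[[unit_col]])
  if (any(table(unit) == 0L)) stop("empty unit level", call. = FALSE)

  X1 <- stats::model.matrix(~ 0 + unit)
  colnames(X1) <- paste0("unit:", levels(unit))
  X2 <- matrix(0, n, 0)
  for (fe in fixed_effects) {
    f <- factor(pheno[[fe]])
    if (anyNA(f)) stop("missing values in fixed effect '", fe, "'", call. = FALSE)
    if (nlevels(f) < 2L) {
      stop("fixed effect '", fe, "' has a single level", call. = FALSE)
    }
    Xf <- stats::model.matrix(~ f)[, -1L, drop = FALSE]
    colnames(Xf) <- paste0(fe, ":", levels(f)[-1L])
    X2 <- cbind(X2, Xf)
  }
  X <- cbind(X1, X2)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("fixed effects are confounded (X rank deficient); aliased ",
         "column(s): ", paste(aliased, collapse = ", "), call. = FALSE)
  }

  Z <- matrix(0, n, length(ids), dimnames = list(NULL, ids))
  Z[cbind(seq_len(n), match(pheno[[id_col]], ids))] <- 1

  unit_index <- lapply(split(pheno[[id_col]], unit), match, table = ids)
  structure(list(X = X, X1 = X1, X2 = X2, Z = Z, unit = unit,
                 units = levels(unit), n_unit = as.integer(table(unit)),
                 ids = ids, unit_index = unit_index),
            class = "design_matrices")
}

#' Assemble and invert Henderson's mixed model equations
#'
#' Builds the coefficient matrix
#' `C = [[X'X, X'Z], [Z'X, Z'Z + Kinv * lambda]]` of the mixed model
#' equations and its full inverse, partitioned into the blocks `C11`
#' (fixed effects), `C12`, and `C22` (breeding values) that all
#' connectedness statistics are read from. The inverse is formed
#' explicitly via a Cholesky factorization — appropriate for the problem
#' sizes this package targets (up to a few thousand equations; a warning
#' is given above 10,000).
#'
#' @param design a [build_design()] result.
#' @param Kinv inverse relationship matrix (see
#'   [regularize_and_invert()]), dimension matching `ncol(design$Z)`.
#' @param varcomp a [variance_components()].
#' @return Object of class `mme_system`: list with `design`, `varcomp`,
#'   `C`, `Cinv`, blocks `C11`, `C12`, `C22`, and the fixed/random
#'   dimensions `p`, `q`.
#' @export
build_mme <- function(design, Kinv, varcomp) {
  stopifnot(inherits(design, "design_matrices"),
            inherits(varcomp, "variance_components"))
  Kinv <- as.matrix(Kinv)
  q <- ncol(design$Z)
  if (nrow(Kinv) != q || ncol(Kinv) != q) {
    stop("Kinv dimension (", nrow(Kinv), ") does not match the number of ",
         "individuals in Z (", q, ")", call. = FALSE)
  }
  X <- design$X
  Z <- design$Z
  p <- ncol(X)
  if (p + q > 10000L) {
    warning("MME has ", p + q, " equations; dense inversion may be slow",
            call. = FALSE)
  }
  C <- rbind(
    cbind(crossprod(X), crossprod(X, Z)),
    cbind(crossprod(Z, X), crossprod(Z) + Kinv * varcomp$lambda)
  )
  C <- (C + t(C)) / 2
  Cinv <- tryCatch(chol2inv(chol(C)), error = function(e) {
    stop("MME coefficient matrix is singular (block Z'Z + Kinv*lambda or ",
         "X'X not positive definite): ", conditionMessage(e), call. = FALSE)
  })
  fi <- seq_len(p)
  ri <- p + seq_len(q)
  structure(list(design = design, varcomp = varcomp, Kinv = Kinv,
                 C = C, Cinv = Cinv,
                 C11 = Cinv[fi, fi, drop = FALSE],
                 C12 = Cinv[fi, ri, drop = FALSE],
                 C22 = Cinv[ri, ri, drop = FALSE],
                 p = p, q = q),
            class = "mme_system")
}

#' @export
print.mme_system <- function(x, ...) {
  cat(sprintf(paste0("mixed model equations: %d fixed effect(s), ",
                     "%d individuals, lambda = %g\n"),
              x$p, x$q, x$varcomp$lambda))
  invisible(x)
}

#' Prediction error (co)variance of breeding values
#'
#' The prediction error variance matrix
#' `PEV(u) = Var(u_hat - u) = C22 * sigma2_e`, the posterior
#' (co)variance of the breeding values given the data. Its diagonal holds
#' the PEV of each individual and its off-diagonals the prediction error
#' covariances (PEC). `method = "absorption"` instead evaluates the
#' equivalent absorbed form `(Z'MZ + Kinv*lambda)^{-1} * sigma2_e`, with
#' `M = I - X (X'X)^- X'` the fixed-effect absorption (projection)
#' matrix; the two routes agree to numerical precision and the second is
#' exposed for verification.
#'
#' @param system an [build_mme()] result.
#' @param method `"blocks"` (read `C22` off the inverted MME, default) or
#'   `"absorption"`.
#' @return Object of class `pev_store`: list with the `PEV` matrix
#'   (individual ids as dimnames), `unit_index`, `units`, `n_unit`,
#'   and `varcomp`.
#' @export
pev <- function(system, method = c("blocks", "absorption")) {
  stopifnot(inherits(system, "mme_system"))
  method <- match.arg(method)
  s2e <- system$varcomp$sigma2_e
  P <- switch(method,
    blocks = system$C22 * s2e,
    absorption = {
      X <- system$design$X
      Z <- system$design$Z
      M <- diag(nrow(X)) - X %*% .pinv(crossprod(X)) %*% t(X)
      W <- crossprod(Z, M %*% Z) + system$Kinv * system$varcomp$lambda
      chol2inv(chol((W + t(W)) / 2)) * s2e
    }
  )
  dimnames(P) <- list(system$design$ids, system$design$ids)
  structure(list(PEV = (P + t(P)) / 2,
                 unit_index = system$design$unit_index,
                 units = system$design$units,
                 n_unit = system$design$n_unit,
                 varcomp = system$varcomp),
            class = "pev_store")
}

## Moore-Penrose pseudo-inverse of a symmetric matrix via eigendecomposition.
.pinv <- function(S, tol = 1e-10) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values))
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

#' @export
print.pev_store <- function(x, ...) {
  cat(sprintf("PEV matrix over %d individuals, %d units (%s)\n",
              nrow(x$PEV), length(x$units),
              paste(x$units, collapse = ", ")))
  invisible(x)
}

#' Variance-covariance matrix of fixed-effect estimates
#'
#' `Var(b_hat) = C11 * sigma2_e`, the sampling covariance of the
#' estimated fixed effects. `method = "absorbed"` evaluates the
#' equivalent absorbed expression
#' `[X'X - X'Z (Z'Z + Kinv*lambda)^{-1} Z'X]^{-1} * sigma2_e`
#' independently of the full MME inverse, for verification.
#'
#' @param system an [build_mme()] result.
#' @param method `"blocks"` (default) or `"absorbed"`.
#' @return Symmetric matrix over the fixed-effect columns of `X`.
#' @export
fixed_effect_covariance <- function(system, method = c("blocks", "absorbed")) {
  stopifnot(inherits(system, "mme_system"))
  method <- match.arg(method)
  s2e <- system$varcomp$sigma2_e
  V <- switch(method,
    blocks = system$C11 * s2e,
    absorbed = {
      X <- system$design$X
      Z <- system$design$Z
      ri <- system$p + seq_len(system$q)
      Winv <- chol2inv(chol(system$C[ri, ri]))   # (Z'Z + Kinv*lambda)^{-1}
      S <- crossprod(X) - crossprod(X, Z) %*% Winv %*% crossprod(Z, X)
      chol2inv(chol((S + t(S)) / 2)) * s2e
    }
  )
  dimnames(V) <- list(colnames(system$design$X), colnames(system$design$X))
  (V + t(V)) / 2
}
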