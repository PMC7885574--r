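#' Relationship matrix container
#'
#' Wraps a symmetric individuals-by-individuals genetic covariance
#' structure **K** — either a pedigree-based numerator relationship matrix
#' **A** or a marker-based genomic relationship matrix **G** — together
#' with individual labels and a source tag.
#'
#' @param K symmetric numeric matrix with row/column names (individual
#'   ids). Symmetry is enforced to within `1e-10` absolute.
#' @param source `"pedigree"` or `"genomic"`.
#' @return An object of class `relationship_matrix` (a named matrix with
#'   attribute `source`).
#' @export
relationship_matrix <- function(K, source = c("pedigree", "genomic")) {
  source <- match.arg(source)
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("K must be square", call. = FALSE)
  if (is.null(rownames(K))) {
    rownames(K) <- colnames(K) <- as.character(seq_len(nrow(K)))
  }
  if (max(abs(K - t(K))) > 1e-10) {
    stop("K is not symmetric (max asymmetry > 1e-10)", call. = FALSE)
  }
  K <- (K + t(K)) / 2
  structure(K, source = source,
            class = c("relationship_matrix", "matrix", "array"))
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("%s relationship matrix, %d individuals\n",
              attr(x, "source"), nrow(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE], ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Genomic relationship matrix from marker genotypes
#'
#' Computes VanRaden's first genomic relationship matrix
#' `G = W W' / (2 * sum(p * (1 - p)))`, where `W` is the genotype matrix
#' column-centred by twice the allele frequency `p`. Frequencies are taken
#' from the data (`freq_mode = "observed"`) or supplied per marker.
#' Monomorphic markers carry no relationship information and are dropped
#' with a warning; if every marker is monomorphic the denominator is zero
#' and an error is raised.
#'
#' @param markers integer matrix, individuals x markers, entries in
#'   \{0, 1, 2\} (allele counts), with individual ids as row names.
#' @param freq_mode `"observed"` (default) or `"supplied"`.
#' @param freq numeric vector of per-marker allele frequencies, required
#'   when `freq_mode = "supplied"`.
#' @return A [relationship_matrix()] with `source = "genomic"`.
#' @export
build_G <- function(markers, freq_mode = c("observed", "supplied"), freq = NULL) {
  freq_mode <- match.arg(freq_mode)
  M <- as.matrix(markers)
  storage.mode(M) <- "double"
  if (anyNA(M) || !all(M %in% c(0, 1, 2))) {
    stop("genotypes must be complete and coded 0/1/2; impute or drop ",
         "missing entries first", call. = FALSE)
  }
  if (is.null(rownames(M))) rownames(M) <- as.character(seq_len(nrow(M)))
  p <- switch(freq_mode,
    observed = colMeans(M) / 2,
    supplied = {
      if (is.null(freq) || length(freq) != ncol(M)) {
        stop("freq_mode = 'supplied' needs one frequency per marker",
             call. = FALSE)
      }
      as.numeric(freq)
    }
  )
  poly <- p > 0 & p < 1
  if (!any(poly)) {
    stop("all markers are monomorphic: genomic relationship undefined",
         call. = FALSE)
  }
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic marker(s) dropped from G",
            call. = FALSE)
    M <- M[, poly, drop = FALSE]
    p <- p[poly]
  }
  W <- sweep(M, 2L, 2 * p, `-`)
  G <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(rownames(M), rownames(M))
  relationship_matrix(G, source = "genomic")
}

#' Invert a relationship matrix, regularizing if needed
#'
#' Inverts **K** through a Cholesky factorization. A well-conditioned
#' matrix is inverted exactly; if the factorization fails (singular or
#' indefinite **K**, e.g. a genomic matrix with duplicated individuals) a
#' ridge `epsilon * I` is added once, with a warning, before retrying.
#' The ridge actually applied is recorded in the `"epsilon"` attribute of
#' the result (0 when no regularization was needed).
#'
#' @param K a [relationship_matrix()] or symmetric matrix.
#' @param epsilon ridge added to the diagonal on factorization failure
#'   (default `1e-8`).
#' @return The inverse matrix, with attribute `"epsilon"`.
#' @export
regularize_and_invert <- function(K, epsilon = 1e-8) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K) || max(abs(K - t(K))) > 1e-10) {
    stop("K must be symmetric", call. = FALSE)
  }
  stopifnot(epsilon > 0)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  eps_used <- 0
  if (is.null(ch)) {
    warning("K is singular or not positive definite; adding ridge ",
            format(epsilon), " * I before inversion", call. = FALSE)
    ch <- chol(K + diag(epsilon, nrow(K)))
    eps_used <- epsilon
  }
  Kinv <- chol2inv(ch)
  dimnames(Kinv) <- dimnames(K)
  attr(Kinv, "epsilon") <- eps_used
  Kinv
}
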