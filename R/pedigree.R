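#' Create and validate a pedigree table
#'
#' A pedigree table records, for every individual, its sire and dam.
#' Unknown parents are stored as `NA` internally; in files they are coded
#' `"0"` following the usual livestock convention. The pedigree must be
#' acyclic and every named parent must itself appear as an individual.
#'
#' @param df data frame with columns `id`, `sire`, `dam` (coerced to
#'   character). The value `"0"`, `""` or `NA` marks an unknown parent.
#' @return An object of class `pedigree_table`: a data frame with character
#'   columns `id`, `sire`, `dam` (unknown parent = `NA`), in the input
#'   record order, with an attribute `"order"` giving a topological
#'   ordering (parents before offspring) as row indices.
#' @examples
#' ped <- pedigree_table(data.frame(id = c("1", "2", "3"),
#'                                  sire = c("0", "0", "1"),
#'                                  dam  = c("0", "0", "2")))
#' build_A(ped)
#' @export
pedigree_table <- function(df) {
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df))) {
    stop("pedigree must have columns 'id', 'sire', 'dam'", call. = FALSE)
  }
  ped <- data.frame(
    id   = as.character(df$id),
    sire = .na_parent(df$sire),
    dam  = .na_parent(df$dam),
    stringsAsFactors = FALSE
  )
  extras <- setdiff(names(df), need)
  if (length(extras)) ped <- cbind(ped, df[extras])
  if (anyNA(ped$id) || any(ped$id == "")) {
    stop("missing individual id in pedigree", call. = FALSE)
  }
  dup <- ped$id[duplicated(ped$id)]
  if (length(dup)) {
    stop("duplicate individual id(s) in pedigree: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  parents <- stats::na.omit(unique(c(ped$sire, ped$dam)))
  missing_par <- setdiff(parents, ped$id)
  if (length(missing_par)) {
    stop("parent id(s) not listed as individuals: ",
         paste(missing_par, collapse = ", "), call. = FALSE)
  }
  attr(ped, "order") <- .toposort_pedigree(ped)
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

.na_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "0" | x == ""] <- NA_character_
  x
}

## Kahn's algorithm over parent -> offspring edges; errors on any cycle
## (which also covers an individual being its own ancestor).
.toposort_pedigree <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (j in idx) {
    for (p in c(si[j], di[j])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], j)
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    j <- queue[1L]
    queue <- queue[-1L]
    out <- c(out, j)
    for (k in children[[j]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) < n) {
    stop("pedigree contains a cycle involving id(s): ",
         paste(ped$id[setdiff(idx, out)], collapse = ", "), call. = FALSE)
  }
  out
}

#' Numerator relationship matrix from a pedigree
#'
#' Builds the additive (numerator) relationship matrix **A** by the tabular
#' method: individuals are processed parents-first and each new row is the
#' half-sum of its parents' rows, with diagonal `1 + F` where `F` is half
#' the relationship between the parents (the inbreeding coefficient).
#' Entries of **A** equal twice the kinship coefficient, so the result does
#' not depend on the order in which pedigree records are supplied.
#'
#' @param pedigree a [pedigree_table()] (or data frame coercible to one).
#' @return A [relationship_matrix()] with `source = "pedigree"`, rows and
#'   columns in the pedigree's record order.
#' @export
build_A <- function(pedigree) {
  ped <- if (inherits(pedigree, "pedigree_table")) pedigree else pedigree_table(pedigree)
  n <- nrow(ped)
  ord <- attr(ped, "order")
  ids <- ped$id[ord]
  pos <- seq_len(n)
  names(pos) <- ids
  si <- unname(pos[ped$sire[ord]])
  di <- unname(pos[ped$dam[ord]])

  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (j in seq_len(n)) {
    s <- si[j]
    d <- di[j]
    if (j > 1L) {
      prev <- seq_len(j - 1L)
      as <- if (!is.na(s)) A[prev, s] else 0
      ad <- if (!is.na(d)) A[prev, d] else 0
      v <- 0.5 * (as + ad)
      A[prev, j] <- v
      A[j, prev] <- v
    }
    A[j, j] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A <- A[ped$id, ped$id, drop = FALSE]
  relationship_matrix(A, source = "pedigree")
}
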