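#' Read and write pedigree files
#'
#' Pedigree CSV dialect: comma-separated with a header row and columns
#' `id,sire,dam`; `0` marks an unknown parent.
#'
#' @param path file path.
#' @return [read_pedigree()] returns a [pedigree_table()].
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  pedigree_table(df)
}

#' @rdname read_pedigree
#' @param pedigree a [pedigree_table()].
#' @export
write_pedigree <- function(pedigree, path) {
  out <- data.frame(id = pedigree$id,
                    sire = ifelse(is.na(pedigree$sire), "0", pedigree$sire),
                    dam = ifelse(is.na(pedigree$dam), "0", pedigree$dam))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write genotype files
#'
#' Genotype file dialect: whitespace-delimited; first column the
#' individual id, remaining columns allele counts 0/1/2; an optional
#' header row carries marker ids. Any entry outside \{0,1,2\} is a parse
#' error reported with its file line.
#'
#' @param path file path.
#' @param header whether the first row holds marker ids (default `TRUE`).
#' @return [read_genotypes()] returns an integer matrix, individuals x
#'   markers, with id row names.
#' @export
read_genotypes <- function(path, header = TRUE) {
  if (!file.exists(path)) stop("genotype file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = header, colClasses = "character",
                          check.names = FALSE)
  ids <- df[[1L]]
  M <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df)))
  )
  M <- matrix(M, nrow = nrow(df),
              dimnames = list(ids, colnames(df)[-1L]))
  bad <- which(matrix(is.na(M) | !(M %in% c(0, 1, 2)), nrow(M)),
               arr.ind = TRUE)
  if (nrow(bad)) {
    line <- bad[1L, "row"] + if (header) 1L else 0L
    stop("invalid genotype (not 0/1/2) at ", path, ":", line,
         ", marker column ", bad[1L, "col"], call. = FALSE)
  }
  storage.mode(M) <- "integer"
  M
}

#' @rdname read_genotypes
#' @param genotypes individuals x markers 0/1/2 matrix with id row names.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(id = rownames(genotypes), genotypes,
                   check.names = FALSE)
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = " ")
  invisible(path)
}

#' Read and write phenotype files
#'
#' Phenotype CSV dialect: comma-separated with a header; one record per
#' individual with its unit label, optional categorical fixed-effect
#' columns, and the phenotype value.
#'
#' @param path file path.
#' @param id_col,unit_col,pheno_col column names (defaults `"id"`,
#'   `"unit"`, `"phenotype"`).
#' @return [read_phenotypes()] returns a [phenotype_table()].
#' @export
read_phenotypes <- function(path, id_col = "id", unit_col = "unit",
                            pheno_col = "phenotype") {
  if (!file.exists(path)) stop("phenotype file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  phenotype_table(df, id_col = id_col, unit_col = unit_col,
                  pheno_col = pheno_col)
}

#' @rdname read_phenotypes
#' @param pheno a [phenotype_table()].
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(as.data.frame(pheno), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a user contrast file
#'
#' CSV with columns `id,coefficient`; coefficients must sum to zero.
#'
#' @param path file path.
#' @param ids individual ids of the relationship matrix, defining the
#'   order and length of the returned vector (ids absent from the file
#'   get coefficient 0).
#' @return Named numeric contrast vector.
#' @export
read_contrast <- function(path, ids) {
  df <- utils::read.csv(path, colClasses = c("character", "numeric"))
  names(df) <- tolower(names(df))
  if (!all(c("id", "coefficient") %in% names(df))) {
    stop("contrast file needs columns 'id,coefficient'", call. = FALSE)
  }
  unknown <- setdiff(df$id, ids)
  if (length(unknown)) {
    stop("contrast references unknown individual(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  x <- stats::setNames(numeric(length(ids)), ids)
  x[df$id] <- df$coefficient
  if (abs(sum(x)) > 1e-12) {
    stop("contrast coefficients must sum to zero", call. = FALSE)
  }
  x
}

.PEV_METRICS <- c("PEVD", "CD", "r")
.VE_METRICS <- c("VED", "CDVED", "CR")

#' Configuration of a connectedness run
#'
#' Bundles all choices of one analysis: the kinship source, the metric,
#' its summary (PEV-family metrics) or correction level (VE-family
#' metrics), the variance input, fixed effects and file paths.
#' Inconsistent combinations — a correction with a PEV-family metric or
#' a summary with a VE-family metric — are rejected here, at parse time.
#'
#' @param kinship `"pedigree"` or `"genomic"`.
#' @param metric one of `PEVD, CD, r` (PEV-based) or `VED, CDVED, CR`
#'   (VE-based).
#' @param summary `"GrpAve"` (default), `"IdAve"` or `"Contrast"`; only
#'   for PEV-based metrics.
#' @param correction 0, 1 or 2; only for VE-based metrics.
#' @param h2 heritability with phenotypic variance normalized to 1
#'   (`sigma2_u = h2`, `sigma2_e = 1 - h2`).
#' @param lambda variance ratio `sigma2_e / sigma2_u`; overrides `h2`,
#'   taking `sigma2_u = 1` and `sigma2_e = lambda` (sufficient for
#'   PEVD/VED; CD-family values then treat the genetic variance as 1).
#' @param fixed_effects extra fixed-effect column names beyond unit.
#' @param pheno,ped,geno,contrast input file paths (`ped` or `geno`
#'   according to `kinship`; `contrast` only with
#'   `summary = "Contrast"` when a user contrast is wanted).
#' @param id_col,unit_col,pheno_col phenotype column roles.
#' @param out output path prefix; `NULL` suppresses file output.
#' @param epsilon ridge for relationship-matrix inversion.
#' @return A list of class `run_config`.
#' @export
run_config <- function(kinship = c("pedigree", "genomic"), metric,
                       summary = NULL, correction = NULL,
                       h2 = NULL, lambda = NULL,
                       fixed_effects = character(),
                       pheno, ped = NULL, geno = NULL, contrast = NULL,
                       id_col = "id", unit_col = "unit",
                       pheno_col = "phenotype",
                       out = NULL, epsilon = 1e-8) {
  kinship <- match.arg(kinship)
  metric <- match.arg(metric, c(.PEV_METRICS, .VE_METRICS))
  if (metric %in% .PEV_METRICS) {
    if (!is.null(correction)) {
      stop("correction applies only to VE-based metrics (VED, CDVED, CR)",
           call. = FALSE)
    }
    summary <- if (is.null(summary)) "GrpAve" else
      match.arg(summary, c("GrpAve", "IdAve", "Contrast"))
  } else {
    if (!is.null(summary)) {
      stop("summary applies only to PEV-based metrics (PEVD, CD, r)",
           call. = FALSE)
    }
    if (is.null(correction) || !correction %in% 0:2) {
      stop("VE-based metrics need correction 0, 1 or 2", call. = FALSE)
    }
  }
  if (is.null(h2) && is.null(lambda)) {
    stop("supply h2 or lambda", call. = FALSE)
  }
  varcomp <- if (!is.null(lambda)) {
    variance_components(sigma2_u = 1, sigma2_e = lambda)
  } else {
    variance_components(h2 = h2)
  }
  if (kinship == "pedigree" && is.null(ped)) {
    stop("kinship = 'pedigree' needs a pedigree file", call. = FALSE)
  }
  if (kinship == "genomic" && is.null(geno)) {
    stop("kinship = 'genomic' needs a genotype file", call. = FALSE)
  }
  structure(list(kinship = kinship, metric = metric, summary = summary,
                 correction = if (is.null(correction)) NA_integer_ else
                   as.integer(correction),
                 varcomp = varcomp, fixed_effects = fixed_effects,
                 pheno = pheno, ped = ped, geno = geno,
                 contrast = contrast, id_col = id_col,
                 unit_col = unit_col, pheno_col = pheno_col,
                 out = out, epsilon = epsilon),
            class = "run_config")
}

#' Read and cross-check the input files of a run
#'
#' @param config a [run_config()].
#' @return List with `K` (relationship matrix), `pheno`
#'   ([phenotype_table()]).
#' @export
read_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pheno <- read_phenotypes(config$pheno, config$id_col, config$unit_col,
                           config$pheno_col)
  K <- if (config$kinship == "pedigree") {
    build_A(read_pedigree(config$ped))
  } else {
    build_G(read_genotypes(config$geno))
  }
  miss <- setdiff(pheno[[config$id_col]], rownames(K))
  if (length(miss)) {
    stop(length(miss), " of ", nrow(pheno), " phenotyped individuals ",
         "missing from the ", config$kinship, " source, e.g.: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  list(K = K, pheno = pheno)
}

#' Run a connectedness analysis end to end
#'
#' Reads the inputs, builds the relationship matrix and the mixed model
#' equations, computes the requested statistic and (when `out` is set)
#' writes the units x units matrix as CSV with a trailing `overall` line,
#' plus a `.log` file recording the defaults in effect (inversion ridge,
#' degeneracy tolerance, block-mean convention).
#'
#' @param config a [run_config()].
#' @param all compute every statistic valid for the fitted model instead
#'   of the single configured one (PEV metrics x 3 summaries, VE metrics
#'   x valid corrections).
#' @return A [unit_pair_result()] (invisibly, a named list of them when
#'   `all = TRUE`).
#' @export
run_connectedness <- function(config, all = FALSE) {
  stopifnot(inherits(config, "run_config"))
  inputs <- read_inputs(config)
  K <- inputs$K
  Kinv <- regularize_and_invert(K, config$epsilon)
  design <- build_design(inputs$pheno, config$fixed_effects,
                         ids = rownames(K))
  system <- build_mme(design, Kinv, config$varcomp)
  ps <- pev(system)
  unit_only <- ncol(design$X2) == 0L

  compute_one <- function(metric, summary, correction) {
    if (metric %in% .PEV_METRICS) {
      if (summary == "Contrast" && !is.null(config$contrast)) {
        x <- read_contrast(config$contrast, rownames(K))
        val <- switch(metric,
                      PEVD = pevd_contrast(ps, x),
                      CD = cd_contrast(ps, K, x),
                      r = r_contrast(ps, x))
        return(val)
      }
      switch(metric,
             PEVD = switch(summary, GrpAve = pevd_grpave(ps),
                           IdAve = pevd_idave(ps),
                           Contrast = .contrast_matrix(ps, K, "PEVD")),
             CD = switch(summary, GrpAve = cd_grpave(ps, K),
                         IdAve = cd_idave(ps, K),
                         Contrast = .contrast_matrix(ps, K, "CD")),
             r = switch(summary, GrpAve = r_grpave(ps),
                        IdAve = r_idave(ps),
                        Contrast = .contrast_matrix(ps, K, "r")))
    } else {
      ve <- switch(as.character(correction),
                   "0" = ve0(system), "1" = ve1(system), "2" = ve2(system))
      switch(metric, VED = ved(ve), CDVED = cdved(ve, K), CR = cr(ve))
    }
  }

  if (all) {
    valid_corr <- c(0L, if (unit_only) 1L else 2L)
    combos <- rbind(
      expand.grid(metric = .PEV_METRICS,
                  summary = c("GrpAve", "IdAve", "Contrast"),
                  correction = NA_integer_, stringsAsFactors = FALSE),
      expand.grid(metric = .VE_METRICS, summary = NA_character_,
                  correction = valid_corr, stringsAsFactors = FALSE)
    )
    results <- list()
    for (i in seq_len(nrow(combos))) {
      m <- combos$metric[i]
      s <- combos$summary[i]
      cc <- combos$correction[i]
      tag <- if (m %in% .PEV_METRICS) paste(m, s, sep = "_") else
        paste0(m, cc)
      results[[tag]] <- compute_one(m, s, cc)
      if (!is.null(config$out)) .write_result(results[[tag]], config, tag)
    }
    if (!is.null(config$out)) .write_log(config, K)
    return(invisible(results))
  }

  res <- compute_one(config$metric, config$summary, config$correction)
  if (!is.null(config$out)) {
    tag <- if (config$metric %in% .PEV_METRICS) {
      paste(config$metric, config$summary, sep = "_")
    } else {
      paste0(config$metric, config$correction)
    }
    .write_result(res, config, tag)
    .write_log(config, K)
  }
  res
}

## contrast summary over all unit pairs: evaluates the contrast form on
## each auto-generated unit-pair contrast
.contrast_matrix <- function(ps, K, metric) {
  units <- ps$units
  k <- length(units)
  out <- matrix(if (metric == "PEVD") 0 else 1, k, k,
                dimnames = list(units, units))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a < b) {
        x <- unit_contrast(ps, units[a], units[b])
        v <- switch(metric,
                    PEVD = pevd_contrast(ps, x),
                    CD = cd_contrast(ps, K, x),
                    r = r_contrast(ps, x))
        out[a, b] <- out[b, a] <- v
      }
    }
  }
  unit_pair_result(metric, "Contrast", matrix = out)
}

.write_result <- function(res, config, tag) {
  path <- paste0(config$out, "_", tag, ".csv")
  if (inherits(res, "unit_pair_result")) {
    df <- data.frame(unit = rownames(res$matrix), res$matrix,
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
    cat(sprintf("overall,%.10g\n", res$overall), file = path, append = TRUE)
  } else {
    cat(sprintf("contrast_%s,%.10g\n", tag, res), file = path)
  }
  invisible(path)
}

.write_log <- function(config, K) {
  path <- paste0(config$out, ".log")
  lines <- c(
    sprintf("kinship: %s (%d individuals)", config$kinship, nrow(K)),
    sprintf("sigma2_u: %g  sigma2_e: %g  lambda: %g",
            config$varcomp$sigma2_u, config$varcomp$sigma2_e,
            config$varcomp$lambda),
    sprintf("fixed effects: unit%s",
            if (length(config$fixed_effects))
              paste0(" + ", paste(config$fixed_effects, collapse = " + "))
            else " (only)"),
    sprintf("inversion ridge epsilon: %g (applied only on factorization failure)",
            config$epsilon),
    sprintf("degenerate-denominator tolerance: %g", .DEGEN_TOL),
    "block means: diagonal-inclusive (group-average and contrast summaries coincide)"
  )
  writeLines(lines, path)
  invisible(path)
}
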