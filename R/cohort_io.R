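## Cohort input: expression matrix, per-individual metadata, probe->gene
## mapping and gene effect-size tables. TSV or CSV with a header row; the
## separator is auto-detected from the header line.

detectSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

readTable <- function(path, what) {
  if (!file.exists(path)) stop("missing ", what, " file: ", path,
                               call. = FALSE)
  read.delim(path, sep = detectSep(path), stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read an age-annotated expression cohort
#'
#' Loads a probe x individual expression matrix, per-individual metadata
#' (chronological age in years and sex) and a probe-to-gene mapping into a
#' \linkS4class{CohortExpression}. Individuals are ordered as in the
#' metadata file. Individuals present in the metadata but missing from the
#' expression matrix are dropped with a warning (cohort subsetting);
#' individuals present in the expression matrix but missing from the
#' metadata raise an error.
#'
#' @param exprPath TSV/CSV, first column probe ids, remaining columns one per
#'   individual.
#' @param metaPath TSV/CSV with columns \code{individual_id}, \code{age},
#'   \code{sex}.
#' @param mappingPath TSV/CSV with columns \code{probe_id}, \code{gene_id},
#'   one row per probe-gene pair.
#' @return a \linkS4class{CohortExpression}.
#' @export
readCohort <- function(exprPath, metaPath, mappingPath) {
  ex <- readTable(exprPath, "expression")
  meta <- readTable(metaPath, "metadata")
  map <- readTable(mappingPath, "probe mapping")

  probes <- as.character(ex[[1]])
  vals <- ex[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]) & nzchar(vals[[j]]))
    if (length(bad) || anyNA(vals[[j]]))
      stop(sprintf(
        "non-numeric expression value at probe '%s', individual '%s'",
        probes[c(bad, which(is.na(vals[[j]])))[1]], colnames(vals)[j]),
        call. = FALSE)
    vals[[j]] <- v
  }
  vals <- as.matrix(vals)
  rownames(vals) <- probes

  for (cl in c("individual_id", "age", "sex"))
    if (!cl %in% colnames(meta))
      stop("metadata lacks column '", cl, "'", call. = FALSE)
  ids <- as.character(meta$individual_id)
  ageNum <- suppressWarnings(as.numeric(meta$age))
  if (anyNA(ageNum))
    stop("missing or non-numeric age for individual(s): ",
         paste(ids[is.na(ageNum)], collapse = ", "), call. = FALSE)

  orphans <- setdiff(colnames(vals), ids)
  if (length(orphans))
    stop("individual(s) present in expression but absent from metadata: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  extra <- setdiff(ids, colnames(vals))
  if (length(extra)) {
    warning("dropping individual(s) without expression data: ",
            paste(extra, collapse = ", "), call. = FALSE)
    keep <- !ids %in% extra
    ids <- ids[keep]; ageNum <- ageNum[keep]; meta <- meta[keep, , drop = FALSE]
  }
  vals <- vals[, ids, drop = FALSE]

  for (cl in c("probe_id", "gene_id"))
    if (!cl %in% colnames(map))
      stop("probe mapping lacks column '", cl, "'", call. = FALSE)
  pg <- split(as.character(map$gene_id), as.character(map$probe_id))

  CohortExpression(vals, probeGenes = pg, age = ageNum,
                   sex = as.character(meta$sex))
}

#' Write a cohort as the three standard TSV files
#'
#' Inverse of \code{\link{readCohort}}: writes \code{expression.tsv},
#' \code{metadata.tsv} and \code{probe_map.tsv} under \code{dir}.
#'
#' @param expr a \linkS4class{CohortExpression}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(expr, dir) {
  stopifnot(is(expr, "CohortExpression"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vals <- exprValues(expr)
  write.table(data.frame(probe_id = rownames(vals), vals,
                         check.names = FALSE),
              file.path(dir, "expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(individual_id = individualIds(expr),
                         age = unname(ages(expr)), sex = unname(sexes(expr))),
              file.path(dir, "metadata.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  pg <- probeGenes(expr)
  write.table(data.frame(probe_id = rep(names(pg), lengths(pg)),
                         gene_id = unlist(pg, use.names = FALSE)),
              file.path(dir, "probe_map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Read a gene effect-size table
#'
#' @param path TSV/CSV with columns \code{gene_id} and \code{effect_size}.
#' @return named numeric vector, gene -> signed effect size.
#' @export
readEffectSizes <- function(path) {
  df <- readTable(path, "effect size")
  for (cl in c("gene_id", "effect_size"))
    if (!cl %in% colnames(df))
      stop("effect-size table lacks column '", cl, "'", call. = FALSE)
  b <- suppressWarnings(as.numeric(df$effect_size))
  if (anyNA(b) || any(!is.finite(b)))
    stop("effect sizes must be finite numbers", call. = FALSE)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene id in effect-size table: ",
         df$gene_id[duplicated(df$gene_id)][1], call. = FALSE)
  setNames(b, as.character(df$gene_id))
}

#' @rdname readEffectSizes
#' @param effects named numeric vector of effect sizes.
#' @param path output file path.
#' @export
writeEffectSizes <- function(effects, path) {
  write.table(data.frame(gene_id = names(effects),
                         effect_size = unname(effects)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
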