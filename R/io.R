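#' Write a spot dataset as MatrixMarket + TSV triplet
#'
#' 10x-style layout: \code{matrix.mtx} (sparse counts), \code{genes.tsv}
#' (no header: gene_id, marker_set, panel_member, background_probe) and
#' \code{spots.tsv} (no header: spot_id, sample_id, row, col, true_class).
#' Grid coordinates are 0-based in the files; physical centre positions are
#' row/col times the 100 um centre spacing.
#'
#' @param spots a \code{spot_dataset}.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_spot_dataset <- function(spots, dir) {
  stopifnot(inherits(spots, "spot_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::Matrix(spots$counts, sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  gm <- spots$gene_meta
  utils::write.table(
    data.frame(gm$gene_id, ifelse(is.na(gm$marker_set), "none", gm$marker_set),
               as.integer(gm$panel_member), as.integer(gm$background_probe)),
    file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  sm <- spots$spot_meta
  utils::write.table(
    data.frame(sm$spot_id, sm$sample_id, sm$row - 1L, sm$col - 1L,
               sm$true_class),
    file.path(dir, "spots.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a spot dataset
#'
#' Accepts either the MatrixMarket triplet written by
#' \code{\link{write_spot_dataset}} (\code{matrix.mtx}, \code{genes.tsv},
#' \code{spots.tsv}) or a dense-CSV pair (\code{counts.csv} with gene ids in
#' the first column and \code{spots.csv} with header
#' spot_id,sample_id,row,col,true_class).  Counts are validated to be
#' non-negative integers; violations are rejected with the file and
#' entry named.
#'
#' @param dir directory holding one of the two dialects.
#' @return a \code{spot_dataset}.
#' @export
read_spot_dataset <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (file.exists(mtx)) {
    m <- tryCatch(as.matrix(Matrix::readMM(mtx)), error = function(e)
      stop_fmt("malformed MatrixMarket file %s: %s", mtx, conditionMessage(e)))
    genes <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                               stringsAsFactors = FALSE)
    spots <- utils::read.table(file.path(dir, "spots.tsv"), sep = "\t",
                               stringsAsFactors = FALSE)
    if (nrow(genes) != nrow(m))
      stop_fmt("%s: %d genes but matrix has %d rows",
               file.path(dir, "genes.tsv"), nrow(genes), nrow(m))
    if (nrow(spots) != ncol(m))
      stop_fmt("%s: %d spots but matrix has %d columns",
               file.path(dir, "spots.tsv"), nrow(spots), ncol(m))
    validate_counts_file(m, mtx)
    gene_meta <- data.frame(gene_id = genes[[1]],
                            marker_set = ifelse(genes[[2]] == "none",
                                                NA_character_, genes[[2]]),
                            panel_member = genes[[3]] == 1,
                            background_probe = genes[[4]] == 1,
                            composite = FALSE, stringsAsFactors = FALSE)
    spot_meta <- data.frame(spot_id = spots[[1]], sample_id = spots[[2]],
                            row = spots[[3]] + 1L, col = spots[[4]] + 1L,
                            true_class = spots[[5]], stringsAsFactors = FALSE)
    dimnames(m) <- list(gene_meta$gene_id, spot_meta$spot_id)
    return(new_spot_dataset(m, spot_meta, gene_meta))
  }
  ccsv <- file.path(dir, "counts.csv")
  if (!file.exists(ccsv))
    stop_fmt("%s contains neither matrix.mtx nor counts.csv", dir)
  tab <- utils::read.csv(ccsv, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  validate_counts_file(m, ccsv)
  spot_meta <- utils::read.csv(file.path(dir, "spots.csv"),
                               stringsAsFactors = FALSE)
  gene_meta <- data.frame(gene_id = rownames(m), marker_set = NA_character_,
                          panel_member = TRUE, background_probe = FALSE,
                          composite = FALSE, stringsAsFactors = FALSE)
  gpath <- file.path(dir, "genes.csv")
  if (file.exists(gpath)) gene_meta <- utils::read.csv(gpath,
                                                       stringsAsFactors = FALSE)
  new_spot_dataset(m, spot_meta, gene_meta)
}

validate_counts_file <- function(m, path) {
  bad <- which(!is.finite(m) | m < 0 | m != floor(m))
  if (length(bad)) {
    i <- bad[1L]
    r <- (i - 1L) %% nrow(m) + 1L; cc <- (i - 1L) %/% nrow(m) + 1L
    stop_fmt("%s: non-integer count %s at row %d, column %d",
             path, format(m[i]), r, cc)
  }
  invisible(m)
}

#' Write / read a bulk cohort as CSV pair
#'
#' \code{counts.csv} (genes x subjects, gene ids in the first column) and
#' \code{covariates.csv} (subject_id, group, fibrosis_stage, NAS).
#'
#' @param cohort a \code{bulk_cohort}.
#' @param dir output directory.
#' @return the directory (write) or a \code{bulk_cohort} (read).
#' @export
write_bulk_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "bulk_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(gene_id = rownames(cohort$counts),
                              cohort$counts, check.names = FALSE),
                   file.path(dir, "counts.csv"), row.names = FALSE)
  utils::write.csv(cohort$subject_meta, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_bulk_cohort
#' @export
read_bulk_cohort <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "counts.csv"), check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  validate_counts_file(m, file.path(dir, "counts.csv"))
  meta <- utils::read.csv(file.path(dir, "covariates.csv"),
                          stringsAsFactors = FALSE)
  out <- list(counts = m, subject_meta = meta)
  class(out) <- "bulk_cohort"
  out
}
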