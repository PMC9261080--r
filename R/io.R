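# TSV readers/writers for every artifact the pipeline exchanges on disk.
# All tables are tab-separated with a header; square matrices are dense TSV
# with node ids as header row and first column; missing dosages are "NA".

write_tsv <- function(df, path, rownames = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = rownames, col.names = TRUE)

read_tsv <- function(path, ...)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)

#' Write / read a cohort table
#' @param cohort a \code{cohort_table}.
#' @param path TSV file path.
#' @return \code{read_cohort_tsv} returns a \code{cohort_table}.
#' @export
write_cohort_tsv <- function(cohort, path) {
  write_tsv(as.data.frame(cohort), path)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  df <- read_tsv(path)
  df$group <- factor(df$group, levels = unique(df$group))
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write / read a set of ROI time series
#'
#' One nodes x volumes TSV per subject plus a manifest
#' (\code{manifest.tsv}: subject_id, file, n_nodes, n_volumes) and a shared
#' block-design file (\code{blocks.tsv}: block_index, condition,
#' start_volume, n_volumes; volume indices 0-based, intervals half-open).
#'
#' @param ts_list named list of \code{\link{roi_timeseries}}.
#' @param dir output directory (created if needed).
#' @return \code{read_timeseries_dir} returns the named list back.
#' @export
write_timeseries_dir <- function(ts_list, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(subject_id = character(0), file = character(0),
                         n_nodes = integer(0), n_volumes = integer(0))
  for (ts in ts_list) {
    f <- paste0(ts$subject_id, "_timeseries.tsv")
    df <- as.data.frame(ts$data)
    names(df) <- paste0("V", seq_len(ncol(df)))
    write_tsv(cbind(node_id = ts$node_ids, df), file.path(dir, f))
    manifest <- rbind(manifest, data.frame(
      subject_id = ts$subject_id, file = f,
      n_nodes = nrow(ts$data), n_volumes = ncol(ts$data)))
  }
  b <- ts_list[[1]]$blocks
  write_tsv(data.frame(block_index = seq_len(nrow(b)) - 1L,
                       condition = b$condition, start_volume = b$start,
                       n_volumes = b$length),
            file.path(dir, "blocks.tsv"))
  write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' @rdname write_timeseries_dir
#' @export
read_timeseries_dir <- function(dir) {
  manifest <- read_tsv(file.path(dir, "manifest.tsv"))
  bl <- read_tsv(file.path(dir, "blocks.tsv"))
  blocks <- data.frame(condition = as.character(bl$condition),
                       start = bl$start_volume, length = bl$n_volumes)
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    df <- read_tsv(file.path(dir, manifest$file[i]))
    m <- as.matrix(df[, -1, drop = FALSE])
    dimnames(m) <- NULL
    roi_timeseries(manifest$subject_id[i], m, df$node_id, blocks)
  })
  names(out) <- manifest$subject_id
  out
}

#' Write / read a connectivity matrix
#' @param m a \code{connectome}.
#' @param path TSV path; node ids become the header row and first column.
#' @param subject_id subject id to attach when reading.
#' @param scale,corrected metadata to attach when reading.
#' @return \code{read_connectome_tsv} returns a \code{connectome}.
#' @export
write_connectome_tsv <- function(m, path) {
  stopifnot(inherits(m, "connectome"))
  df <- as.data.frame(m$weights)
  names(df) <- m$node_ids
  write_tsv(cbind(node_id = m$node_ids, df), path)
  invisible(path)
}

#' @rdname write_connectome_tsv
#' @export
read_connectome_tsv <- function(path, subject_id = NA_character_,
                                scale = "z", corrected = FALSE) {
  df <- read_tsv(path, check.names = FALSE)
  W <- as.matrix(df[, -1, drop = FALSE])
  rownames(W) <- df$node_id
  structure(list(subject_id = subject_id, weights = W,
                 node_ids = df$node_id, scale = scale, corrected = corrected),
            class = "connectome")
}

#' Write metric curves and regional clustering tables
#'
#' Per subject, a curve TSV (density, C, L, C_null, L_null, gamma, lambda,
#' sigma) and a regional TSV (node_id x density of clustering values).
#'
#' @param curve a \code{\link{metric_curves}} object.
#' @param curve_path,regional_path output TSV paths (regional optional).
#' @return invisibly, \code{curve_path}.
#' @export
write_curves_tsv <- function(curve, curve_path, regional_path = NULL) {
  stopifnot(inherits(curve, "metric_curve"))
  write_tsv(curve$curve, curve_path)
  if (!is.null(regional_path)) {
    reg <- as.data.frame(curve$regional)
    names(reg) <- sprintf("d%.2f", curve$curve$density)
    node_id <- rownames(curve$regional)
    if (is.null(node_id)) node_id <- paste0("N", seq_len(nrow(reg)))
    write_tsv(cbind(node_id = node_id, reg), regional_path)
  }
  invisible(curve_path)
}

#' Write / read genotype data as TSV triplet
#'
#' Dosages (rows = subjects, columns = SNP ids, missing as NA), SNP
#' metadata (snp_id, chrom, pos, effect_allele, other_allele) and GWAS
#' weights (snp_id, effect_allele, OR, p).
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param weights GWAS weights data.frame (optional).
#' @param dir output directory.
#' @return \code{read_genetics_dir} returns
#'   \code{list(genotypes, weights)}.
#' @export
write_genetics_dir <- function(geno, weights = NULL, dir) {
  stopifnot(inherits(geno, "genotype_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dos <- as.data.frame(geno$dosages)
  write_tsv(cbind(subject_id = geno$subjects, dos),
            file.path(dir, "dosages.tsv"))
  write_tsv(geno$snps, file.path(dir, "snps.tsv"))
  if (!is.null(weights)) write_tsv(weights, file.path(dir, "weights.tsv"))
  invisible(dir)
}

#' @rdname write_genetics_dir
#' @export
read_genetics_dir <- function(dir) {
  dos <- read_tsv(file.path(dir, "dosages.tsv"), check.names = FALSE)
  snps <- read_tsv(file.path(dir, "snps.tsv"))
  g <- genotype_matrix(dos$subject_id, snps,
                       as.matrix(dos[, -1, drop = FALSE]))
  wfile <- file.path(dir, "weights.tsv")
  list(genotypes = g,
       weights = if (file.exists(wfile)) read_tsv(wfile) else NULL)
}
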