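#' Read and write the pipeline's plain-text data formats
#'
#' Haplotypes travel as TSV (rows = lines, columns = SNP ids, cells =
#' founder code 1..8 or NA), the SNP map as TSV (snp_id, chrom, pos_bp),
#' phenotypes as long CSV (line_id, trait, environment, value). Scenes are
#' written as an image PNG, a mask PNG and a JSON sidecar holding
#' truth_vf, spread and seed.
#'
#' @param haplo,snp_map,pheno objects as produced by the synthetic-data
#'   module.
#' @param path file path.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_haplotypes <- function(haplo, path) {
  df <- data.frame(line_id = rownames(haplo), haplo, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_haplotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$line_id
  m
}

#' @rdname pipeline_io
#' @export
write_snp_map <- function(snp_map, path) {
  utils::write.table(snp_map[, c("snp_id", "chrom", "pos_bp")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_snp_map <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname pipeline_io
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(pheno[, c("line_id", "trait", "environment", "value")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_phenotypes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a canopy scene to disk
#'
#' @param scene a \code{canopy_scene}.
#' @param dir output directory (created if needed).
#' @param id file stem; writes \code{<id>.png}, \code{<id>_mask.png},
#'   \code{<id>.json}.
#' @return the three paths, invisibly.
#' @export
write_scene <- function(scene, dir, id) {
  stopifnot(inherits(scene, "canopy_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_img <- file.path(dir, paste0(id, ".png"))
  p_mask <- file.path(dir, paste0(id, "_mask.png"))
  p_json <- file.path(dir, paste0(id, ".json"))
  png::writePNG(scene$image / 255, p_img)
  png::writePNG(scene$truth_mask + 0, p_mask)
  jsonlite::write_json(list(truth_vf = scene$truth_vf,
                            coverage_target = scene$coverage_target,
                            spread = scene$spread, seed = scene$seed),
                       p_json, auto_unbox = TRUE, digits = NA)
  invisible(c(image = p_img, mask = p_mask, meta = p_json))
}

#' Read an RGB raster from PNG as an 8-bit array
#'
#' @param path PNG file.
#' @return H x W x 3 integer array with values 0..255.
#' @export
read_raster_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3L] > 3L) x <- x[, , 1:3, drop = FALSE]
  a <- round(x * 255)
  storage.mode(a) <- "integer"
  a
}
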