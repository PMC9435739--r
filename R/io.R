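# Fixture serialization. Internal coordinates are 0-based half-open;
# conversion to GTF's 1-based inclusive convention happens here only
# (GRanges are 1-based inclusive, BED export shifts back automatically).

.genes_to_granges <- function(genes) {
  rows <- list()
  for (g in genes) {
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = g$chrom, start = g$start + 1, end = g$end, strand = g$strand,
      type = "gene", gene_id = g$gene_id, gene_biotype = g$biotype,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = g$chrom, start = g$exons[, 1L] + 1, end = g$exons[, 2L],
      strand = g$strand, type = "exon", gene_id = g$gene_id,
      gene_biotype = g$biotype, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$source <- "introntime"
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$gene_biotype <- df$gene_biotype
  gr
}

#' Write a gene set as GTF
#'
#' Emits one `gene` and per-exon `exon` features with `gene_id` and
#' `gene_biotype` attributes (1-based, inclusive coordinates).
#'
#' @param genes A `gene_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  rtracklayer::export(.genes_to_granges(genes), path, format = "gtf")
  invisible(path)
}

#' Write a gene set as BED12
#'
#' Exon block structure per gene, 0-based half-open coordinates.
#'
#' @param genes A `gene_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(genes, path) {
  grl <- methods::as(lapply(genes, function(g) {
    GenomicRanges::GRanges(
      seqnames = g$chrom,
      ranges = IRanges::IRanges(start = g$exons[, 1L] + 1, end = g$exons[, 2L]),
      strand = g$strand)
  }), "GRangesList")
  names(grl) <- vapply(genes, function(g) g$gene_id, character(1))
  # seqinfo merge warnings from combining single-chromosome elements are benign
  bed12 <- suppressWarnings(rtracklayer::asBED(grl))
  rtracklayer::export(bed12, path, format = "bed")
  invisible(path)
}

#' Read a GTF annotation back into a gene set
#'
#' Reconstructs [gene_model] objects from `exon` features grouped by
#' `gene_id` (introns re-derived as inter-exon gaps).
#'
#' @param path GTF file path.
#' @return A `gene_set`.
#' @export
read_gtf_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[S4Vectors::mcols(gr)$type == "exon"]
  ids <- S4Vectors::mcols(ex)$gene_id
  models <- lapply(unique(ids), function(id) {
    sub <- ex[ids == id]
    exons <- cbind(GenomicRanges::start(sub) - 1, GenomicRanges::end(sub))
    exons <- exons[order(exons[, 1L]), , drop = FALSE]
    gene_model(
      gene_id = id,
      chrom = as.character(GenomicRanges::seqnames(sub))[1L],
      strand = as.character(GenomicRanges::strand(sub))[1L],
      start = min(exons[, 1L]), end = max(exons[, 2L]),
      biotype = S4Vectors::mcols(sub)$gene_biotype[1L],
      exons = exons)
  })
  names(models) <- vapply(models, function(g) g$gene_id, character(1))
  structure(models, class = "gene_set")
}

#' Write a wide profile/count table as TSV
#' @param x Wide data frame (`gene_id`, `region`, time columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a wide profile/count TSV
#' @param path File path.
#' @return Wide data frame with numeric time columns.
#' @export
read_profiles_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a complete synthetic fixture to a directory
#'
#' Emits `genes.gtf` (1-based inclusive), `genes.bed` (BED12, 0-based
#' half-open), `counts.tsv`, `truth.tsv` and a `manifest.yaml` recording the
#' generating configuration and seed. Refuses to overwrite an existing
#' manifest unless `force = TRUE`.
#'
#' @param genes,truth,config Output of [make_genome()].
#' @param counts Count table from [simulate_counts()].
#' @param out_dir Output directory (created if missing).
#' @param force Overwrite an existing fixture.
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(genes, counts, truth, config, out_dir,
                          force = FALSE) {
  manifest_path <- file.path(out_dir, "manifest.yaml")
  if (file.exists(manifest_path) && !force)
    stop2("fixture_exists",
          "manifest already present in %s; use force = TRUE", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_gtf(genes, file.path(out_dir, "genes.gtf"))
  write_bed(genes, file.path(out_dir, "genes.bed"))
  write_profiles_tsv(counts, file.path(out_dir, "counts.tsv"))
  utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- unclass(config)
  cfg$depth_factors <- as.numeric(attr(counts, "depth_factors"))
  yaml::write_yaml(cfg, manifest_path)
  invisible(out_dir)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @return List with `genes`, `counts`, `truth`, `config`.
#' @export
read_fixture <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  cfg <- lapply(cfg, function(x) if (is.list(x)) unlist(x) else x)
  config <- do.call(sim_config, cfg)
  list(genes = read_gtf_genes(file.path(dir, "genes.gtf")),
       counts = read_profiles_tsv(file.path(dir, "counts.tsv")),
       truth = utils::read.delim(file.path(dir, "truth.tsv"),
                                 stringsAsFactors = FALSE),
       config = config)
}
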