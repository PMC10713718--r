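#' Read a BED3+ file of genomic intervals
#'
#' Reads BED (0-based half-open) with any number of trailing columns; the
#' first six are named `chrom,start,end,name,score,strand`, further columns
#' keep `X7, X8, ...` (so narrowPeak files read fine). `track`/`browser`/`#`
#' lines are skipped. Records are returned sorted by `(chrom, start)`.
#'
#' @param path Path to a BED file.
#' @return Tibble of intervals (see [as_intervals()]).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("BED parse error at line %d: fewer than 3 fields",
                  idx[which(nf < 3)[1]]))
  }
  ncol_use <- min(nf)
  mat <- t(vapply(fields, function(f) f[seq_len(ncol_use)], character(ncol_use)))
  bed_names <- c("chrom", "start", "end", "name", "score", "strand")
  colnames(mat) <- c(bed_names[seq_len(min(ncol_use, 6))],
                     if (ncol_use > 6) paste0("X", 7:ncol_use))
  out <- as_tibble(mat)
  start <- suppressWarnings(as.numeric(out$start))
  end <- suppressWarnings(as.numeric(out$end))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    abort(sprintf("BED parse error at line %d: non-numeric start/end", idx[bad[1]]))
  }
  out$start <- as.integer(start)
  out$end <- as.integer(end)
  if ("score" %in% names(out)) {
    out$score <- suppressWarnings(as.numeric(out$score))
  }
  bad <- which(!(out$start >= 0 & out$start < out$end))
  if (length(bad) > 0) {
    abort(sprintf("BED validation error at line %d: requires 0 <= start < end",
                  idx[bad[1]]))
  }
  as_intervals(out)
}

#' Write intervals to a BED file
#'
#' Emits `chrom,start,end` plus `name`, `score`, `strand` when present
#' (earlier optional columns are filled with `.`/`0` placeholders as the BED
#' dialect requires).
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- list(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  has <- intersect(c("name", "score", "strand"), names(x))
  if (length(has) > 0) {
    name <- if ("name" %in% names(x)) as.character(x$name) else rep(".", nrow(x))
    cols <- c(cols, list(name))
    if (any(c("score", "strand") %in% has)) {
      score <- if ("score" %in% names(x)) as.character(x$score) else rep("0", nrow(x))
      cols <- c(cols, list(score))
      if ("strand" %in% has) cols <- c(cols, list(as.character(x$strand)))
    }
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a bedGraph coverage file
#'
#' Segments must be non-overlapping within a chromosome (the bedGraph
#' contract); overlap is an error.
#'
#' @param path Path to a bedGraph file.
#' @return Tibble with `chrom, start, end, value`, sorted.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                       col_types = "ciid", comment = "#", progress = FALSE)
  validate_intervals(x)
  x <- arrange(x, .data$chrom, .data$start)
  same <- x$chrom == dplyr::lag(x$chrom)
  if (any(same & x$start < dplyr::lag(x$end), na.rm = TRUE)) {
    abort("bedGraph format error: overlapping segments within a chromosome")
  }
  x
}

#' Write a bedGraph coverage file
#' @param x Tibble with `chrom, start, end, value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  validate_intervals(x)
  readr::write_tsv(x[, c("chrom", "start", "end", "value")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Uses `gene` feature rows (falling back to the span of `transcript` rows per
#' gene when no `gene` rows exist). GTF 1-based closed coordinates are
#' converted to 0-based half-open; the TSS is `start` for `+` genes and
#' `end - 1` for `-` genes (the biological start of transcription).
#'
#' @param path Path to a GTF file.
#' @return Tibble with `gene_id, chrom, start, end, strand, tss`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    sel <- gr[S4Vectors::mcols(gr)$type == "gene"]
    if (length(sel) == 0) sel <- gr[S4Vectors::mcols(gr)$type == "transcript"]
  } else {
    sel <- gr
  }
  if (length(sel) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(),
                  strand = character(), tss = integer()))
  }
  strand <- as.character(GenomicRanges::strand(sel))
  if (any(!strand %in% c("+", "-"))) {
    abort("GTF validation error: gene with unknown strand")
  }
  out <- tibble(
    gene_id = as.character(S4Vectors::mcols(sel)$gene_id),
    chrom = as.character(GenomicRanges::seqnames(sel)),
    start = GenomicRanges::start(sel) - 1L,
    end = GenomicRanges::end(sel),
    strand = strand
  )
  out <- distinct(out, .data$gene_id, .keep_all = TRUE)
  add_tss(arrange(out, .data$chrom, .data$start))
}

#' Strand-aware TSS column for a gene table
#' @param genes Tibble with `start, end, strand`.
#' @return `genes` with a `tss` column (0-based position).
#' @export
add_tss <- function(genes) {
  if (any(!genes$strand %in% c("+", "-"))) {
    abort("gene validation error: strand must be '+' or '-'")
  }
  mutate(genes, tss = if_else(.data$strand == "+", .data$start, .data$end - 1L))
}

#' Write gene models to a GTF file
#'
#' Emits one `gene` feature per row, converting back to GTF 1-based closed
#' coordinates; round-trips with [read_gtf()].
#'
#' @param genes Gene tibble (`gene_id, chrom, start, end, strand`).
#' @param path Output path.
#' @param source Source field string.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path, source = "t3chrom") {
  if (any(!genes$strand %in% c("+", "-"))) {
    abort("gene validation error: strand must be '+' or '-'")
  }
  lines <- sprintf(
    '%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
    genes$chrom, source, genes$start + 1L, genes$end, genes$strand,
    genes$gene_id)
  writeLines(lines, path)
  invisible(path)
}
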