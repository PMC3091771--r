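#' Read transcript annotations from a GTF file
#'
#' Parses `exon`, `CDS` and (when present) `transcript` features into the
#' long-format transcript table used by [merge_transcripts()]. GTF
#' coordinates are 1-based closed; they are converted to the package-wide
#' 0-based half-open convention on read.
#'
#' @param path Path to a GTF file.
#' @return A tibble with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `feature`, `start`, `end` (0-based half-open).
#' @export
read_gtf <- function(path) {
  cols <- readr::read_tsv(
    path,
    col_names = c("chrom", "source", "feature", "start", "end",
                  "score", "strand", "frame", "attributes"),
    col_types = "ccciicccc",
    comment = "#",
    progress = FALSE
  )
  cols <- dplyr::filter(cols, .data$feature %in% c("exon", "CDS", "transcript"))
  attr_field <- function(attrs, key) {
    m <- stringr::str_match(attrs, paste0(key, ' "([^"]*)"'))[, 2]
    m
  }
  tibble::tibble(
    gene_id = attr_field(cols$attributes, "gene_id"),
    transcript_id = attr_field(cols$attributes, "transcript_id"),
    chrom = cols$chrom,
    strand = cols$strand,
    feature = cols$feature,
    start = cols$start - 1L,
    end = cols$end
  )
}

#' Read transcript annotations from a BED12 file
#'
#' Block fields become exons; the thickStart/thickEnd span intersected with
#' the blocks becomes the CDS. The BED `name` field is used as the
#' transcript id; `gene_id` is taken from `name` up to the first period
#' unless a `gene_from_name` function is supplied.
#'
#' @param path Path to a BED12 file.
#' @param gene_from_name Function mapping the name field to a gene id.
#' @return A transcript table as in [read_gtf()].
#' @export
read_bed12 <- function(path, gene_from_name = function(x) sub("\\..*$", "", x)) {
  b <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand",
                  "thick_start", "thick_end", "rgb", "block_count",
                  "block_sizes", "block_starts"),
    col_types = "ciicncii_icc",
    progress = FALSE
  )
  rows <- purrr::pmap(b, function(chrom, start, end, name, score, strand,
                                   thick_start, thick_end, block_count,
                                   block_sizes, block_starts) {
    sizes <- as.integer(strsplit(block_sizes, ",")[[1]])
    offs <- as.integer(strsplit(block_starts, ",")[[1]])
    ex_start <- start + offs
    ex_end <- ex_start + sizes
    out <- tibble::tibble(
      transcript_id = name, chrom = chrom, strand = strand,
      feature = c("transcript", rep("exon", length(sizes))),
      start = c(start, ex_start), end = c(end, ex_end)
    )
    if (thick_end > thick_start) {
      cs <- pmax(ex_start, thick_start)
      ce <- pmin(ex_end, thick_end)
      keep <- ce > cs
      if (any(keep)) {
        out <- dplyr::bind_rows(out, tibble::tibble(
          transcript_id = name, chrom = chrom, strand = strand,
          feature = "CDS", start = cs[keep], end = ce[keep]
        ))
      }
    }
    out
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, gene_id = gene_from_name(.data$transcript_id),
                .before = "transcript_id")
}

#' Read a BED track (3-6 columns)
#'
#' @param path Path to a BED file.
#' @return Tibble with `chrom`, `start`, `end` and, when present in the
#'   file, `name`, `score`, `strand`. Coordinates stay 0-based half-open.
#' @export
read_bed <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  ncol <- length(strsplit(first, "\t")[[1]])
  names_all <- c("chrom", "start", "end", "name", "score", "strand")
  types_all <- c("c", "i", "i", "c", "n", "c")
  readr::read_tsv(path, col_names = names_all[seq_len(ncol)],
                  col_types = paste(types_all[seq_len(ncol)], collapse = ""),
                  progress = FALSE)
}

#' Read a conserved-element track (BED5/BED6 with conservation score)
#'
#' @param path Path to a BED file whose score column holds the element's
#'   conservation score (e.g. a phastCons LOD score).
#' @return Tibble with `chrom`, `start`, `end`, `name`, `score`.
#' @export
read_elements <- function(path) {
  b <- read_bed(path)
  if (!"score" %in% names(b)) {
    stop("conserved-element track needs a score column (BED5/BED6)", call. = FALSE)
  }
  b
}

#' Read a RepeatMasker annotation table
#'
#' Accepts either a RepeatMasker `.out` file (3 header lines, whitespace
#' separated) or a BED file with the repeat name in column 4. Repeat
#' categories are derived with [repeat_category()].
#'
#' @param path Path to the annotation file.
#' @param format `"auto"` (default), `"rmout"` or `"bed"`.
#' @return Tibble with `chrom`, `start`, `end`, `name`, `category`, `is_L1M`.
#' @export
read_repeats <- function(path, format = c("auto", "rmout", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    head <- readr::read_lines(path, n_max = 1)
    format <- if (grepl("^\\s*SW|^\\s*score", head)) "rmout" else "bed"
  }
  if (format == "rmout") {
    lines <- readr::read_lines(path, skip = 3)
    lines <- lines[nzchar(trimws(lines))]
    f <- strsplit(trimws(lines), "\\s+")
    rep_tbl <- tibble::tibble(
      chrom = purrr::map_chr(f, 5),
      start = as.integer(purrr::map_chr(f, 6)) - 1L,  # .out is 1-based
      end = as.integer(purrr::map_chr(f, 7)),
      name = purrr::map_chr(f, 10),
      rm_class = purrr::map_chr(f, 11)
    )
  } else {
    b <- read_bed(path)
    rep_tbl <- tibble::tibble(chrom = b$chrom, start = b$start, end = b$end,
                              name = b$name, rm_class = NA_character_)
  }
  dplyr::mutate(rep_tbl,
    category = repeat_category(.data$name, .data$rm_class),
    is_L1M = startsWith(.data$name, "L1M"),
    rm_class = NULL
  )
}

#' Read a two-column gene-group file
#'
#' @param path TSV with columns gene id and group label (e.g. `maternal`,
#'   `paternal`, `autosomal`). A header line is detected and skipped.
#' @return Tibble with `gene_id`, `group`.
#' @export
read_gene_groups <- function(path) {
  g <- readr::read_tsv(path, col_names = c("gene_id", "group"),
                       col_types = "cc", progress = FALSE)
  if (nrow(g) > 0 && tolower(g$gene_id[1]) %in% c("gene_id", "gene", "id")) {
    g <- g[-1, ]
  }
  g
}

#' Load a genome FASTA
#'
#' @param path Path to an (uncompressed or gzip) FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Write an interval table as BED6
#'
#' @param df Tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path Output path.
#' @export
write_bed6 <- function(df, path) {
  check_intervals(df)
  out <- tibble::tibble(
    chrom = df$chrom, start = df$start, end = df$end,
    name = if ("name" %in% names(df)) df$name else
      if ("gene_id" %in% names(df)) df$gene_id else ".",
    score = if ("score" %in% names(df)) df$score else 0,
    strand = if ("strand" %in% names(df)) df$strand else "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a transcript table as GTF
#'
#' @param transcripts Transcript table as returned by [read_gtf()].
#' @param path Output path.
#' @export
write_gtf <- function(transcripts, path) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   transcripts$gene_id, transcripts$transcript_id)
  out <- tibble::tibble(
    chrom = transcripts$chrom, source = "imprintcons",
    feature = transcripts$feature,
    start = transcripts$start + 1L, end = transcripts$end,
    score = ".", strand = transcripts$strand, frame = ".", attributes = attrs
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE, escape = "none")
  invisible(path)
}
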