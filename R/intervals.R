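# Internal interval arithmetic. All user-facing tables use 0-based
# half-open [start, end) coordinates (BED convention); GenomicRanges is
# 1-based closed, so conversion happens only inside these helpers.

as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

granges_tbl <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

check_intervals <- function(df, what = "interval table") {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(what, " lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(df$end < df$start)) {
    stop(what, " contains intervals with end < start", call. = FALSE)
  }
  invisible(df)
}

# Union of possibly overlapping intervals -> disjoint sorted intervals.
iv_reduce <- function(df) {
  if (nrow(df) == 0) return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  granges_tbl(GenomicRanges::reduce(as_granges0(df)))
}

# a minus b, preserving no metadata.
iv_setdiff <- function(a, b) {
  if (nrow(a) == 0) return(a[, c("chrom", "start", "end")])
  if (nrow(b) == 0) return(iv_reduce(a))
  granges_tbl(GenomicRanges::setdiff(as_granges0(a), as_granges0(b)))
}

# Overlap hit pairs with overlap widths (>= 1 bp only).
iv_hits <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(tibble::tibble(q = integer(), s = integer(), width = integer()))
  }
  gq <- as_granges0(query)
  gs <- as_granges0(subject)
  # disjoint seqlevels (e.g. an element chromosome with no annotation)
  # are a legitimate no-hit case, not worth a warning
  h <- suppressWarnings(GenomicRanges::findOverlaps(gq, gs, minoverlap = 1L))
  qh <- S4Vectors::queryHits(h)
  sh <- S4Vectors::subjectHits(h)
  tibble::tibble(
    q = qh,
    s = sh,
    width = pmin(query$end[qh], subject$end[sh]) -
      pmax(query$start[qh], subject$start[sh])
  )
}

iv_overlap_any <- function(query, subject) {
  out <- rep(FALSE, nrow(query))
  h <- iv_hits(query, subject)
  out[unique(h$q)] <- TRUE
  out
}

# Per query row: number of query bases covered by the union of subject.
iv_covered_width <- function(query, subject) {
  if (nrow(query) == 0) return(integer(0))
  if (nrow(subject) == 0) return(rep(0L, nrow(query)))
  gq <- as_granges0(query)
  gs <- GenomicRanges::reduce(as_granges0(subject))
  h <- suppressWarnings(GenomicRanges::findOverlaps(gq, gs))
  ov <- GenomicRanges::pintersect(gq[S4Vectors::queryHits(h)], gs[S4Vectors::subjectHits(h)])
  w <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(h), sum)
  out <- rep(0L, nrow(query))
  out[as.integer(names(w))] <- as.integer(w)
  out
}

iv_total_width <- function(df) {
  if (nrow(df) == 0) return(0L)
  r <- iv_reduce(df)
  sum(r$end - r$start)
}
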