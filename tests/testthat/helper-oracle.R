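# Brute-force per-base oracles, kept deliberately independent of the
# package's interval arithmetic: every base of a small chromosome is
# labelled by scanning, and element-level quantities are recomputed by
# counting labelled bases.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random small single-chromosome fixture: non-overlapping gene spans with
# exons/CDS, plus unconstrained elements and feature intervals.
random_fixture <- function(seed, chrom_len = NULL, max_genes = 10) {
  set.seed(seed)
  chrom_len <- chrom_len %||% sample(2000:10000, 1)
  n_genes <- sample(1:max_genes, 1)
  # lay genes greedily left to right
  tx <- list(); spans <- list()
  cursor <- sample(0:200, 1)
  for (i in seq_len(n_genes)) {
    gap <- sample(0:400, 1)
    start <- cursor + gap
    n_ex <- sample(1:4, 1)
    ex_len <- sample(20:150, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1) sample(30:300, n_ex - 1, replace = TRUE) else integer(0)
    lens <- integer(2 * n_ex - 1)
    lens[seq(1, by = 2, length.out = n_ex)] <- ex_len
    if (n_ex > 1) lens[seq(2, by = 2, length.out = n_ex - 1)] <- in_len
    if (start + sum(lens) + 100 > chrom_len) break
    starts <- start + cumsum(c(0L, lens[-length(lens)]))
    ends <- starts + lens
    is_exon <- seq_along(lens) %% 2 == 1
    span <- c(start, start + sum(lens))
    cds <- c(span[1] + ex_len[1] %/% 3, span[2] - ex_len[n_ex] %/% 3)
    ex_s <- starts[is_exon]; ex_e <- ends[is_exon]
    cds_s <- pmax(ex_s, cds[1]); cds_e <- pmin(ex_e, cds[2])
    keep <- cds_e > cds_s
    gid <- sprintf("g%02d", i)
    strand <- sample(c("+", "-"), 1)
    tx[[i]] <- tibble::tibble(
      gene_id = gid, transcript_id = paste0(gid, ".t"), chrom = "chrT",
      strand = strand,
      feature = c("transcript", rep("exon", n_ex), rep("CDS", sum(keep))),
      start = c(span[1], ex_s, cds_s[keep]),
      end = c(span[2], ex_e, cds_e[keep])
    )
    spans[[i]] <- span
    cursor <- span[2]
  }
  transcripts <- dplyr::bind_rows(tx)
  n_el <- sample(5:30, 1)
  el_len <- sample(20:120, n_el, replace = TRUE)
  el_s <- vapply(el_len, function(l) sample(0:(chrom_len - l), 1), integer(1))
  elements <- tibble::tibble(chrom = "chrT", start = el_s, end = el_s + el_len,
                             name = sprintf("e%03d", seq_len(n_el)),
                             score = round(stats::runif(n_el, 10, 500), 1))
  rand_track <- function(n_max, len_range) {
    n <- sample(0:n_max, 1)
    if (n == 0) return(tibble::tibble(chrom = character(), start = integer(),
                                      end = integer()))
    len <- sample(len_range[1]:len_range[2], n, replace = TRUE)
    s <- vapply(len, function(l) sample(0:(chrom_len - l), 1), integer(1))
    tibble::tibble(chrom = "chrT", start = s, end = s + len)
  }
  list(transcripts = transcripts, elements = elements,
       chrom_len = chrom_len,
       cpg_islands = rand_track(4, c(50, 400)),
       feature_track = rand_track(6, c(10, 200)))
}

# Per-base region labels from a scan: "exon"/"cds"/"intron" per gene, and
# per-base nearest-gene assignment of intergenic bases.
oracle_base_labels <- function(transcripts, chrom_len) {
  label <- rep("intergenic", chrom_len)     # index = base + 1
  gene_at <- rep(NA_character_, chrom_len)
  exon_at <- rep(FALSE, chrom_len)
  cds_at <- rep(FALSE, chrom_len)
  genes <- unique(transcripts$gene_id)
  spans <- lapply(genes, function(g) {
    sub <- transcripts[transcripts$gene_id == g, ]
    c(min(sub$start), max(sub$end))
  })
  for (i in seq_along(genes)) {
    g <- genes[i]
    sub <- transcripts[transcripts$gene_id == g, ]
    sp <- spans[[i]]
    label[(sp[1] + 1):sp[2]] <- "genic"
    gene_at[(sp[1] + 1):sp[2]] <- g
    ex <- sub[sub$feature == "exon", ]
    for (r in seq_len(nrow(ex))) exon_at[(ex$start[r] + 1):ex$end[r]] <- TRUE
    cd <- sub[sub$feature == "CDS", ]
    for (r in seq_len(nrow(cd))) cds_at[(cd$start[r] + 1):cd$end[r]] <- TRUE
  }
  # intergenic assignment: midpoint halving, scanned gap by gap
  bounds <- do.call(rbind, spans)
  ord <- order(bounds[, 1])
  bounds <- bounds[ord, , drop = FALSE]
  genes_sorted <- genes[ord]
  gaps_a <- c(0, bounds[, 2])
  gaps_b <- c(bounds[, 1], chrom_len)
  left_gene <- c(NA_character_, genes_sorted)
  right_gene <- c(genes_sorted, NA_character_)
  for (r in seq_along(gaps_a)) {
    a <- gaps_a[r]; b <- gaps_b[r]
    if (b <= a) next
    bases <- a:(b - 1)
    owner <- if (is.na(left_gene[r])) rep(right_gene[r], length(bases))
      else if (is.na(right_gene[r])) rep(left_gene[r], length(bases))
      else ifelse(bases < (a + b) %/% 2, left_gene[r], right_gene[r])
    gene_at[bases + 1] <- owner
  }
  list(label = label, gene_at = gene_at, exon_at = exon_at, cds_at = cds_at)
}

# Element-level classification recomputed by counting labelled bases.
oracle_classify <- function(elements, labels) {
  n <- nrow(elements)
  klass <- character(n); gene <- character(n)
  for (i in seq_len(n)) {
    bases <- (elements$start[i] + 1):elements$end[i]
    genic <- labels$label[bases] == "genic"
    if (any(genic)) {
      counts <- table(labels$gene_at[bases][genic])
      best <- max(counts)
      cand <- names(counts)[counts == best]
      g <- sort(cand)[1]   # gene ids sort in coordinate order in fixtures
      gbases <- bases[genic & labels$gene_at[bases] == g]
      gene[i] <- g
      klass[i] <- if (any(labels$cds_at[gbases])) "coding"
        else if (any(labels$exon_at[gbases])) "UTR" else "intronic"
    } else {
      counts <- table(labels$gene_at[bases])
      gene[i] <- if (length(counts) == 0) NA_character_
        else names(counts)[which.max(counts)]
      klass[i] <- "intergenic"
    }
  }
  tibble::tibble(element_class = klass, gene_id = gene)
}

# Per-base overlap oracle (>= 1 shared base).
oracle_overlap <- function(elements, track, chrom_len) {
  mask <- rep(FALSE, chrom_len)
  for (r in seq_len(nrow(track))) {
    if (track$end[r] > track$start[r]) mask[(track$start[r] + 1):track$end[r]] <- TRUE
  }
  vapply(seq_len(nrow(elements)), function(i) {
    any(mask[(elements$start[i] + 1):elements$end[i]])
  }, logical(1))
}

# Per-gene intron coverage by intronic elements, recomputed per base.
oracle_intron_coverage <- function(elements, el_class, el_gene, labels,
                                   chrom_len) {
  el_mask_of <- function(g) {
    mask <- rep(FALSE, chrom_len)
    idx <- which(el_class == "intronic" & !is.na(el_gene) & el_gene == g)
    for (i in idx) mask[(elements$start[i] + 1):elements$end[i]] <- TRUE
    mask
  }
  genes <- unique(labels$gene_at[!is.na(labels$gene_at) &
                                   labels$label == "genic"])
  out <- list()
  for (g in genes) {
    intron_mask <- labels$label == "genic" & !labels$exon_at &
      !is.na(labels$gene_at) & labels$gene_at == g
    n_intron <- sum(intron_mask)
    if (n_intron == 0) next
    covered <- sum(intron_mask & el_mask_of(g))
    out[[g]] <- tibble::tibble(gene_id = g, region_bp = n_intron,
                               covered_bp = covered,
                               coverage = covered / n_intron)
  }
  dplyr::bind_rows(out)
}

# Signed exon distance recomputed from per-base labels: exon intervals of
# the host gene are recovered from label runs, then the stated convention
# is applied to them.
oracle_exon_distance <- function(start, end, host, labels) {
  exmask <- labels$exon_at & !is.na(labels$gene_at) & labels$gene_at == host
  r <- rle(exmask)
  stops <- cumsum(r$lengths)
  ex_end <- stops[r$values]                 # half-open ends
  ex_start <- (stops - r$lengths)[r$values] # 0-based starts
  ov <- pmin(end, ex_end) - pmax(start, ex_start)
  if (all(ov <= 0)) {
    gap <- ifelse(ex_end <= start, start - ex_end, ex_start - end)
    return(min(gap[gap >= 0]))
  }
  hit <- which(ov > 0)
  inside <- hit[start >= ex_start[hit] & end <= ex_end[hit]]
  if (length(inside) > 0) {
    return(-min(pmin(start - ex_start[inside], ex_end[inside] - end)))
  }
  pen <- c(
    ifelse(start < ex_start[hit], pmin(end, ex_end[hit]) - ex_start[hit], Inf),
    ifelse(end > ex_end[hit], ex_end[hit] - pmax(start, ex_start[hit]), Inf)
  )
  -min(pen[is.finite(pen) & pen > 0])
}
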