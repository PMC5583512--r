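#' Binned ChIP-seq coverage track (RPKPM)
#'
#' Per-bin coverage normalized as reads per kilobase per million mapped reads.
#'
#' @param values Per-bin values (>= 0).
#' @param bin_size Bin size in bp (default 1 kb).
#' @param genome A [genome_spec()].
#' @param total_reads Total mapped reads behind the track.
#' @param label Sample label.
#' @return An object of class `chip_track`.
#' @export
chip_track <- function(values, bin_size, genome, total_reads = NA_real_,
                       label = "track") {
  stopifnot(inherits(genome, "genome_spec"))
  n <- n_bins(genome, bin_size)
  if (length(values) != n)
    stop("track has ", length(values), " bins; genome needs ", n)
  if (any(values < 0, na.rm = TRUE)) stop("track values must be >= 0")
  structure(list(values = as.numeric(values), bin_size = bin_size,
                 genome = genome, total_reads = total_reads, label = label),
            class = "chip_track")
}

#' @export
print.chip_track <- function(x, ...) {
  cat(sprintf("<chip_track> %s: %d bins of %g kb (%s reads)\n", x$label,
              length(x$values), x$bin_size / 1000,
              format(x$total_reads, big.mark = ",")))
  invisible(x)
}

# true length (bp) of each bin, accounting for the short last bin
bin_lengths_bp <- function(genome, bin_size) {
  n <- n_bins(genome, bin_size)
  len <- rep(bin_size, n)
  len[n] <- genome$length_bp - (n - 1) * bin_size
  len
}

#' Build an RPKPM coverage track from read positions
#'
#' Reads are assigned to bins by their 5' position; each bin's value is
#' `count / (bin length in kb) / (total reads / 1e6)`. The final partial bin
#' is normalized by its true length.
#'
#' @param read_positions Read 5'-end positions in bp.
#' @param genome A [genome_spec()].
#' @param bin_size Bin size in bp (default 1 kb).
#' @param label Sample label.
#' @return A [chip_track()].
#' @export
rpkpm_track <- function(read_positions, genome, bin_size = 1000,
                        label = "track") {
  stopifnot(inherits(genome, "genome_spec"))
  total <- length(read_positions)
  if (total < 1L) stop("need at least one read")
  if (any(read_positions < 0 | read_positions >= genome$length_bp))
    stop("read position outside the genome")
  n <- n_bins(genome, bin_size)
  counts <- tabulate(floor(read_positions / bin_size) + 1L, nbins = n)
  vals <- counts / (bin_lengths_bp(genome, bin_size) / 1000) / (total / 1e6)
  chip_track(vals, bin_size, genome, total_reads = total, label = label)
}

#' Tagged / untagged enrichment-ratio track
#'
#' `ratio(bin) = (tagged + pseudocount) / (untagged + pseudocount)`; values
#' near 1 indicate no enrichment.
#'
#' @param tagged,untagged Two [chip_track()]s on the same bin grid.
#' @param pseudocount Stabilizing pseudocount added to both (default 0.5).
#' @return A [chip_track()] of ratios.
#' @export
enrichment_ratio <- function(tagged, untagged, pseudocount = 0.5) {
  stopifnot(inherits(tagged, "chip_track"), inherits(untagged, "chip_track"))
  if (tagged$bin_size != untagged$bin_size ||
      length(tagged$values) != length(untagged$values))
    stop("tagged and untagged tracks are on different bin grids")
  chip_track((tagged$values + pseudocount) / (untagged$values + pseudocount),
             tagged$bin_size, tagged$genome,
             label = paste0(tagged$label, "/", untagged$label))
}

#' Per-gene occupancy from a coverage track
#'
#' `occupancy(gene) = (length-weighted mean track value over the gene's bins)
#' x (gene length in kb)`. For an RNA polymerase track this is the RPKPM x
#' gene-length abundance measure. Genes flagged `unreliable` (e.g. rRNA
#' clusters, where short reads cannot be mapped uniquely) can be masked.
#'
#' @param track A [chip_track()].
#' @param genes A gene table (see [read_genes_bed()]).
#' @param mask_unreliable Drop genes whose `unreliable` column is `TRUE`.
#' @return The gene table with an `occupancy` column appended (and
#'   `orientation` relative to SMC translocation, via
#'   [classify_orientation()]).
#' @export
gene_occupancy <- function(track, genes, mask_unreliable = TRUE) {
  stopifnot(inherits(track, "chip_track"))
  if (mask_unreliable && !is.null(genes$unreliable))
    genes <- genes[!genes$unreliable, , drop = FALSE]
  L <- track$genome$length_bp
  if (any(genes$start < 0 | genes$end > L | genes$start >= genes$end))
    stop("gene outside the genome (or start >= end)")
  bs <- track$bin_size
  occ <- vapply(seq_len(nrow(genes)), function(g) {
    s <- genes$start[g]; e <- genes$end[g]
    bins <- seq(floor(s / bs), floor((e - 1) / bs))
    lo <- pmax(bins * bs, s)
    hi <- pmin((bins + 1) * bs, e)
    wmean <- sum(track$values[bins + 1] * (hi - lo)) / (e - s)
    wmean * (e - s) / 1000
  }, numeric(1))
  genes$occupancy <- occ
  genes$orientation <- classify_orientation(genes, track$genome)
  genes
}

#' Classify gene orientation relative to SMC translocation
#'
#' SMC loaded at *parS* translocates toward *ter* on each arm. A gene whose
#' transcription points back toward *parS* on its arm meets SMC head-on;
#' otherwise it is co-directional. On the right arm (ascending from *ori*),
#' `+`-strand genes are co-directional; on the left arm, `-`-strand genes
#' are.
#'
#' @param genes A gene table with `start`, `end`, `strand`.
#' @param genome A [genome_spec()].
#' @return Character vector, `"co_directional"` or `"head_on"`.
#' @export
classify_orientation <- function(genes, genome) {
  stopifnot(inherits(genome, "genome_spec"))
  a1 <- ori_offset(genes$start, genome)$arm
  a2 <- ori_offset(genes$end - 1, genome)$arm
  if (any(a1 != a2))
    stop("gene spanning ori or ter (ambiguous arm): ",
         paste(genes$id[a1 != a2], collapse = ", "))
  ifelse((a1 == "right") == (genes$strand == "+"), "co_directional", "head_on")
}

#' Transcription orientation bias
#'
#' Ratio of summed expression weight on co-directional genes to head-on genes
#' (relative to SMC translocation away from *parS*), with a per-arm breakdown
#' and a count-based companion ratio.
#'
#' @param genes A gene table with `strand` and `weight`.
#' @param genome A [genome_spec()].
#' @return List with `bias_weight`, `bias_count`, `per_arm` (data.frame), and
#'   `infinite` flag (no head-on gene).
#' @export
orientation_bias <- function(genes, genome) {
  if (nrow(genes) == 0L) stop("empty gene table")
  orient <- classify_orientation(genes, genome)
  arm <- ori_offset(genes$start, genome)$arm
  w <- if (is.null(genes$weight)) rep(1, nrow(genes)) else genes$weight
  sum_w <- function(sel) sum(w[sel])
  co <- orient == "co_directional"
  per_arm <- do.call(rbind, lapply(c("left", "right"), function(a) {
    data.frame(arm = a, co_weight = sum_w(co & arm == a),
               head_on_weight = sum_w(!co & arm == a),
               co_count = sum(co & arm == a),
               head_on_count = sum(!co & arm == a))
  }))
  inf <- !any(!co)
  list(bias_weight = if (inf) Inf else sum_w(co) / sum_w(!co),
       bias_count = if (inf) Inf else sum(co) / sum(!co),
       per_arm = per_arm, infinite = inf)
}

#' Aggregate a ChIP track onto profile offsets
#'
#' For each offset `d` the track is averaged over the window
#' `[anchor + d*1000 - span/2, anchor + d*1000 + span/2)` on the right arm and
#' the mirrored window on the left arm, and the two arm values are averaged.
#' This pairs a 1-kb ChIP track with a 10-kb Hi-C score profile.
#'
#' @param track A [chip_track()].
#' @param offsets_kb Offsets in kb.
#' @param anchor Anchor position in bp (default *ori*).
#' @param span_bp Averaging window per arm (default 10 kb).
#' @return Numeric vector of aggregated track values, one per offset.
#' @export
track_at_offsets <- function(track, offsets_kb, anchor = track$genome$ori_bp,
                             span_bp = 10000) {
  stopifnot(inherits(track, "chip_track"))
  L <- track$genome$length_bp
  n <- length(track$values)
  bs <- track$bin_size
  win_mean <- function(center) {
    lo <- center - span_bp / 2
    bins <- (floor(lo / bs) + seq_len(ceiling(span_bp / bs)) - 1) %% n + 1
    mean(track$values[bins])
  }
  vapply(offsets_kb, function(d) {
    (win_mean((anchor + d * 1000) %% L) + win_mean((anchor - d * 1000) %% L)) / 2
  }, numeric(1))
}

# ---- I/O --------------------------------------------------------------------

#' Write a track as bedGraph (0-based half-open)
#'
#' @param track A [chip_track()].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  g <- track$genome
  n <- length(track$values)
  starts <- (seq_len(n) - 1) * track$bin_size
  ends <- pmin(starts + track$bin_size, g$length_bp)
  gr <- GenomicRanges::GRanges(g$name,
                               IRanges::IRanges(start = starts + 1, end = ends),
                               score = track$values)
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}

#' Read a bedGraph track on a fixed bin grid
#'
#' @param path Path to a bedGraph file.
#' @param genome A [genome_spec()].
#' @param bin_size Bin size in bp the file is expected to tile.
#' @param label Sample label.
#' @return A [chip_track()].
#' @export
read_bedgraph <- function(path, genome, bin_size = 1000, label = basename(path)) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  n <- n_bins(genome, bin_size)
  vals <- numeric(n)
  idx <- floor((GenomicRanges::start(gr) - 1) / bin_size) + 1
  if (any(idx < 1 | idx > n)) stop("bedGraph interval outside the genome")
  vals[idx] <- GenomicRanges::mcols(gr)$score
  chip_track(vals, bin_size, genome, label = label)
}

#' Read a BED6 gene table
#'
#' Columns: chrom, start, end, name, score (expression weight), strand.
#'
#' @param path Path to a BED6 file.
#' @return Data.frame with `id`, `start`, `end`, `strand`, `weight`.
#' @export
read_genes_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(id = GenomicRanges::mcols(gr)$name,
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             weight = GenomicRanges::mcols(gr)$score,
             stringsAsFactors = FALSE)
}

#' Write a gene table as BED6
#'
#' @param genes A gene table (`id`, `start`, `end`, `strand`, `weight`).
#' @param path Output path.
#' @param chrom Chromosome name.
#' @export
write_genes_bed <- function(genes, path, chrom = "chr") {
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = genes$start + 1, end = genes$end),
    strand = genes$strand)
  GenomicRanges::mcols(gr)$name <- genes$id
  GenomicRanges::mcols(gr)$score <- genes$weight
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Read read positions from a one-position-per-line file or BED3
#'
#' @param path Text file: either one 0-based position per line or BED3 (the
#'   start column is used).
#' @return Numeric vector of positions.
#' @export
read_positions <- function(path) {
  tab <- utils::read.table(path, sep = "\t", comment.char = "#")
  if (ncol(tab) >= 3) as.numeric(tab[[2]]) else as.numeric(tab[[1]])
}
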