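#' Binned Hi-C contact matrix
#'
#' A square symmetric matrix of contacts between fixed-size genomic bins on a
#' circular chromosome, carrying its bin size, processing stage (`raw` counts,
#' `balanced` frequencies, `log` scores, or model `probability`), the set of
#' masked (excluded) bins, an optional rotation (see [ori_center()]), and the
#' genome it refers to.
#'
#' @param mat n x n numeric matrix.
#' @param bin_size Bin size in bp.
#' @param stage One of `"raw"`, `"balanced"`, `"log"`, `"probability"`.
#' @param genome A [genome_spec()]; `n` must equal `ceiling(length_bp/bin_size)`.
#' @param mask Integer indices of masked matrix rows/columns.
#' @param rotation Rotation offset in bins: matrix row `i` holds the genomic
#'   bin starting at `((i - 1 + rotation) %% n) * bin_size`.
#' @param extra Named list of stage-specific metadata (kept on the object).
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(mat, bin_size, stage, genome, mask = integer(0),
                           rotation = 0L, extra = list()) {
  stopifnot(inherits(genome, "genome_spec"), is.matrix(mat),
            nrow(mat) == ncol(mat))
  n <- n_bins(genome, bin_size)
  if (nrow(mat) != n)
    stop("matrix is ", nrow(mat), " x ", nrow(mat), " but the genome needs ",
         n, " bins of ", bin_size, " bp")
  stage <- match.arg(stage, c("raw", "balanced", "log", "probability"))
  structure(
    c(list(mat = mat, bin_size = bin_size, stage = stage, genome = genome,
           mask = as.integer(mask), rotation = as.integer(rotation)),
      extra),
    class = "contact_matrix"
  )
}

#' Number of bins covering a genome at a bin size
#' @param genome A [genome_spec()].
#' @param bin_size Bin size in bp.
#' @export
n_bins <- function(genome, bin_size) as.integer(ceiling(genome$length_bp / bin_size))

#' @export
print.contact_matrix <- function(x, ...) {
  n <- nrow(x$mat)
  cat(sprintf("<contact_matrix> %d x %d bins of %g kb, stage '%s'\n",
              n, n, x$bin_size / 1000, x$stage))
  cat(sprintf("  genome %s; %d masked bin(s); rotation %d bin(s)\n",
              x$genome$name, length(x$mask), x$rotation))
  if (x$stage == "raw")
    cat(sprintf("  total valid pairs: %s\n",
                format(matrix_mass(x), big.mark = ",")))
  invisible(x)
}

#' @export
plot.contact_matrix <- function(x, main = NULL, ...) {
  v <- x$mat
  n <- nrow(v)
  starts <- bin_starts(x) / 1000
  if (is.null(main)) main <- sprintf("%s (%s)", x$genome$name, x$stage)
  graphics::image(seq_len(n), seq_len(n), v[, n:1, drop = FALSE],
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "bin", ylab = "bin", main = main, useRaster = TRUE, ...)
  invisible(x)
}

# genomic start (bp) of each matrix row
bin_starts <- function(m) {
  n <- nrow(m$mat)
  (((seq_len(n) - 1L + m$rotation) %% n)) * m$bin_size
}

# matrix row holding genomic position pos
bin_of <- function(m, pos) {
  n <- nrow(m$mat)
  b0 <- floor(pos / m$bin_size)        # 0-based genomic bin
  as.integer(((b0 - m$rotation) %% n) + 1L)
}

# total mass over upper triangle including the diagonal (unmasked bins)
matrix_mass <- function(m) {
  v <- m$mat
  if (length(m$mask)) v[m$mask, ] <- v[, m$mask] <- NA
  v[lower.tri(v)] <- NA
  sum(v, na.rm = TRUE)
}

#' Bin valid Hi-C read pairs into a raw contact matrix
#'
#' Each valid pair increments `(i, j)` and `(j, i)` once each for `i != j` and
#' the diagonal `(i, i)` once, so off-diagonal mass is double-counted
#' symmetrically and the sum over the upper triangle plus diagonal equals the
#' number of contributing valid pairs. The final bin may be shorter when the
#' genome length is not a bin-size multiple.
#'
#' @param pairs A read-pair data.frame (see [read_pairs()]).
#' @param genome A [genome_spec()].
#' @param bin_size Bin size in bp (default 10 kb).
#' @param classes Optional classification vector (from [classify_pairs()]);
#'   defaults to the pairs' `label` column, else all pairs count as valid.
#' @param dedup Drop exact duplicate (pos1, strand1, pos2, strand2) records
#'   first. Off by default.
#' @return A raw-stage [contact_matrix()].
#' @export
bin_pairs <- function(pairs, genome, bin_size = 10000, classes = NULL,
                      dedup = FALSE) {
  stopifnot(inherits(genome, "genome_spec"), bin_size > 0)
  if (dedup)
    pairs <- pairs[!duplicated(pairs[c("pos1", "strand1", "pos2", "strand2")]), ]
  if (is.null(classes)) classes <- pairs$label
  if (!is.null(classes)) pairs <- pairs[classes == "valid", , drop = FALSE]
  n <- n_bins(genome, bin_size)
  i <- floor(pairs$pos1 / bin_size) + 1
  j <- floor(pairs$pos2 / bin_size) + 1
  if (nrow(pairs) && (max(i, j) > n || min(i, j) < 1))
    stop("read position outside the genome")
  lin <- c((j - 1) * n + i, ((i - 1) * n + j)[i != j])
  counts <- matrix(tabulate(lin, nbins = n * n), n, n)
  contact_matrix(counts, bin_size, "raw", genome)
}

#' Balance a raw contact matrix by iterative correction
#'
#' Masks uninformative bins (zero coverage plus the lowest-coverage quantile),
#' then applies symmetric iterative row/column scaling until the coefficient
#' of variation of unmasked row sums falls below `tol`, and finally rescales
#' globally so total mass is preserved. Masked rows and columns are set to
#' `NA`. Non-convergence within `max_iter` raises a warning and is flagged on
#' the result (`converged` field).
#'
#' @param m A raw-stage (or re-run balanced-stage) [contact_matrix()].
#' @param tol Convergence tolerance on the row-sum coefficient of variation.
#' @param max_iter Maximum iterations.
#' @param min_coverage_quantile Bins with coverage at or below this quantile
#'   of the positive coverages are masked (default bottom 1%).
#' @return A balanced-stage [contact_matrix()] with fields `converged` and
#'   `iterations`.
#' @export
iterative_correction <- function(m, tol = 1e-6, max_iter = 500,
                                 min_coverage_quantile = 0.01) {
  stopifnot(inherits(m, "contact_matrix"))
  if (m$stage == "log") stop("cannot balance a log-stage matrix")
  v <- m$mat
  n <- nrow(v)
  cov <- rowSums(v, na.rm = TRUE)     # previously masked rows are all-NA
  mask <- cov == 0
  poscov <- cov[!mask]
  if (length(poscov) && min_coverage_quantile > 0)
    mask <- mask | cov <= stats::quantile(poscov, min_coverage_quantile)
  keep <- which(!mask)
  if (length(keep) == 0L) stop("all bins masked; nothing to balance")
  W <- v[keep, keep, drop = FALSE]
  mass0 <- {
    u <- W
    u[lower.tri(u)] <- 0
    sum(u)
  }
  cv <- function(s) stats::sd(s) / mean(s)
  it <- 0L
  repeat {
    s <- rowSums(W)
    if (any(s == 0)) stop("zero row sum on an unmasked bin during balancing")
    if (cv(s) < tol || it >= max_iter) break
    b <- s / mean(s)
    W <- W / outer(b, b)
    it <- it + 1L
  }
  converged <- cv(rowSums(W)) < tol
  if (!converged)
    warning("iterative correction did not reach tol = ", tol, " within ",
            max_iter, " iterations")
  u <- W; u[lower.tri(u)] <- 0
  W <- W * (mass0 / sum(u))
  out <- matrix(NA_real_, n, n)
  out[keep, keep] <- W
  contact_matrix(out, m$bin_size, "balanced", m$genome,
                 mask = which(mask), rotation = m$rotation,
                 extra = list(converged = converged, iterations = it))
}

#' Log-transform a balanced contact matrix
#'
#' Balanced contacts are converted to relative frequencies (dividing by the
#' total mass over the upper triangle plus diagonal) and mapped to
#' `ln(frequency + pseudocount)`, the scale on which contact maps and
#' interaction-score profiles are drawn. Masked bins stay `NA`.
#'
#' @param m A balanced-stage [contact_matrix()].
#' @param pseudocount Positive float; default half of the smallest positive
#'   relative frequency.
#' @return A log-stage [contact_matrix()] (field `pseudocount` records the
#'   value used).
#' @export
log_map <- function(m, pseudocount = NULL) {
  stopifnot(inherits(m, "contact_matrix"))
  if (!m$stage %in% c("balanced", "probability"))
    stop("log_map expects a balanced (or probability) stage matrix")
  f <- m$mat / matrix_mass(m)
  if (is.null(pseudocount)) {
    pos <- f[is.finite(f) & f > 0]
    if (length(pos) == 0L) stop("matrix has no positive entries")
    pseudocount <- min(pos) / 2
  }
  if (pseudocount <= 0) stop("pseudocount must be positive")
  contact_matrix(log(f + pseudocount), m$bin_size, "log", m$genome,
                 mask = m$mask, rotation = m$rotation,
                 extra = list(pseudocount = pseudocount))
}

#' Rotate bins so that a landmark is the central bin
#'
#' Circular rotation of bin indices placing the bin containing `anchor`
#' (default *ori*) at the central row/column, the orientation used to display
#' arm-alignment maps. Contact values are unchanged; only bin bookkeeping
#' moves.
#'
#' @param m A [contact_matrix()].
#' @param genome A [genome_spec()] (defaults to the matrix's own).
#' @param anchor Genomic position to center on (default `ori_bp`).
#' @return The rotated [contact_matrix()].
#' @export
ori_center <- function(m, genome = m$genome, anchor = genome$ori_bp) {
  stopifnot(inherits(m, "contact_matrix"))
  n <- nrow(m$mat)
  center <- floor(n / 2) + 1L
  b_anchor <- floor(anchor / m$bin_size)            # 0-based genomic bin
  rotation_new <- as.integer((b_anchor - (center - 1L)) %% n)
  set_rotation(m, rotation_new)
}

# re-rotate a contact matrix to an absolute rotation offset
set_rotation <- function(m, rotation_new) {
  n <- nrow(m$mat)
  shift <- (rotation_new - m$rotation) %% n
  perm <- ((seq_len(n) - 1L + shift) %% n) + 1L      # new row i <- old row perm[i]
  out <- m
  out$mat <- m$mat[perm, perm, drop = FALSE]
  if (length(m$mask)) out$mask <- as.integer(sort(match(m$mask, perm)))
  out$rotation <- as.integer(rotation_new %% n)
  out
}

#' One-call Hi-C pipeline: classify, bin, balance, log-transform
#'
#' @param pairs A read-pair data.frame.
#' @param genome A [genome_spec()].
#' @param bin_size Bin size in bp.
#' @param frag Optional [fragment_map()]; when given, pairs are (re)classified
#'   with [classify_pairs()] before binning.
#' @param ... Passed to [iterative_correction()].
#' @return A log-stage [contact_matrix()].
#' @export
hic_matrix <- function(pairs, genome, bin_size = 10000, frag = NULL, ...) {
  classes <- if (!is.null(frag)) classify_pairs(pairs, frag) else NULL
  log_map(iterative_correction(bin_pairs(pairs, genome, bin_size, classes), ...))
}

#' Write a contact matrix as dense TSV
#'
#' A `#` header line records stage, bin size, genome name/length, rotation and
#' mask; the first row and column carry bin start coordinates (bp).
#'
#' @param m A [contact_matrix()].
#' @param path Output path (a `.gz` suffix triggers gzip compression).
#' @export
write_contact_matrix <- function(m, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# smcalign_matrix stage=%s bin_size=%g length_bp=%.0f name=%s rotation=%d mask=%s",
    m$stage, m$bin_size, m$genome$length_bp, m$genome$name, m$rotation,
    if (length(m$mask)) paste(m$mask, collapse = ",") else "-"), con)
  starts <- bin_starts(m)
  writeLines(paste(c("bin_start", format(starts, scientific = FALSE, trim = TRUE)),
                   collapse = "\t"), con)
  body <- cbind(format(starts, scientific = FALSE, trim = TRUE),
                matrix(sprintf("%.10e", m$mat), nrow(m$mat)))
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a contact matrix written by [write_contact_matrix()]
#'
#' @param path Path to the matrix TSV.
#' @param genome Optional [genome_spec()]; reconstructed from the header when
#'   omitted (with default landmark positions).
#' @return A [contact_matrix()].
#' @export
read_contact_matrix <- function(path, genome = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  hdr <- readLines(con, n = 1L)
  if (!grepl("^# smcalign_matrix ", hdr))
    stop("not a smcalign matrix file: ", path)
  kv <- strsplit(strsplit(sub("^# smcalign_matrix ", "", hdr), " ")[[1]], "=")
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  tab <- utils::read.table(con, sep = "\t", header = TRUE, check.names = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(mat) <- NULL
  if (is.null(genome))
    genome <- genome_spec(meta[["name"]], as.numeric(meta[["length_bp"]]),
                          ori_bp = 0)
  mask <- if (meta[["mask"]] == "-") integer(0)
  else as.integer(strsplit(meta[["mask"]], ",")[[1]])
  contact_matrix(mat, as.numeric(meta[["bin_size"]]), meta[["stage"]], genome,
                 mask = mask, rotation = as.integer(meta[["rotation"]]))
}
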