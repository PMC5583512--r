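#' Describe a circular bacterial chromosome
#'
#' A `genome_spec` records the geometry needed for arm-alignment analysis of a
#' single circular chromosome: its length and the positions of the replication
#' origin (*ori*), the centromere-like *parS* site, and the terminus (*ter*).
#' All coordinates are 0-based base pairs in `[0, length_bp)`; kilobases are
#' used only when reporting.
#'
#' @param name Chromosome name (used in file headers).
#' @param length_bp Chromosome length in bp (> 0).
#' @param ori_bp Position of the replication origin.
#' @param parS_bp Position of the parS site.
#' @param ter_bp Position of the terminus. Defaults to the antipode of `ori_bp`.
#' @return An object of class `genome_spec`.
#' @seealso [caulobacter_genome()] for the default preset.
#' @export
genome_spec <- function(name, length_bp, ori_bp = 0L, parS_bp = ori_bp,
                        ter_bp = NULL) {
  length_bp <- as.numeric(length_bp)
  if (length(length_bp) != 1L || !is.finite(length_bp) || length_bp <= 0)
    stop("length_bp must be a single positive number")
  if (is.null(ter_bp)) ter_bp <- floor(length_bp / 2)
  pos <- c(ori_bp = ori_bp, parS_bp = parS_bp, ter_bp = ter_bp)
  pos <- vapply(pos, as.numeric, numeric(1))
  if (any(pos < 0 | pos >= length_bp))
    stop("ori_bp, parS_bp and ter_bp must lie in [0, length_bp)")
  structure(
    list(name = as.character(name), length_bp = length_bp,
         ori_bp = pos[["ori_bp"]], parS_bp = pos[["parS_bp"]],
         ter_bp = pos[["ter_bp"]]),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> %s: %s bp (circular)\n", x$name,
              format(x$length_bp, big.mark = ",")))
  cat(sprintf("  ori %s bp | parS %s bp | ter %s bp\n",
              format(x$ori_bp, big.mark = ","),
              format(x$parS_bp, big.mark = ","),
              format(x$ter_bp, big.mark = ",")))
  invisible(x)
}

#' Caulobacter crescentus NA1000 chromosome preset
#'
#' Geometry of the 4,042,929-bp NA1000 chromosome with *ori* at coordinate 0.
#' The parS site sits ~8 kb from *ori* on the left arm (i.e. just below the
#' origin when the circle is linearized at *ori*) and *ter* is taken at the
#' antipode of *ori*.
#'
#' @return A [genome_spec()].
#' @export
caulobacter_genome <- function() {
  len <- 4042929
  genome_spec("NA1000", len, ori_bp = 0, parS_bp = len - 8000,
              ter_bp = floor(len / 2))
}

#' Read a single circular chromosome from a FASTA file
#'
#' Reads exactly one record and returns the sequence together with a
#' `genome_spec` of matching length. Multi-record files are rejected: the
#' analysis is defined for one circular chromosome.
#'
#' @param path Path to a FASTA file with one sequence.
#' @param ori_bp,parS_bp,ter_bp Landmark coordinates for the returned spec;
#'   defaults place `ori` at 0, `parS` 8 kb below it, `ter` at the antipode.
#' @return A list with elements `sequence` (uppercase character scalar) and
#'   `genome` (a [genome_spec()]).
#' @export
read_genome_fasta <- function(path, ori_bp = 0, parS_bp = NULL, ter_bp = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequence records in ", path)
  if (length(seqs) > 1L)
    stop("expected a single circular chromosome, found ", length(seqs),
         " records in ", path)
  len <- Biostrings::width(seqs)[1]
  if (is.null(parS_bp)) parS_bp <- (ori_bp - 8000) %% len
  list(
    sequence = toupper(as.character(seqs[[1]])),
    genome = genome_spec(sub("\\s.*$", "", names(seqs)[1]), len,
                         ori_bp = ori_bp, parS_bp = parS_bp, ter_bp = ter_bp)
  )
}

#' Shortest arc distance between two positions on the circle
#'
#' @param x,y Positions in bp, each in `[0, length_bp)`; vectors recycle.
#' @param genome A [genome_spec()].
#' @return Distance in bp, at most `length_bp / 2`.
#' @export
arc_distance <- function(x, y, genome) {
  stopifnot(inherits(genome, "genome_spec"))
  L <- genome$length_bp
  if (any(x < 0 | x >= L) || any(y < 0 | y >= L))
    stop("positions must lie in [0, length_bp)")
  d <- abs(x - y)
  pmin(d, L - d)
}

#' Signed ori offset and arm assignment
#'
#' Positions ascending from *ori* toward *ter* form the right arm (positive
#' offsets); positions descending from *ori* (equivalently, from `length_bp`)
#' toward *ter* form the left arm (negative offsets). *ter* splits the circle;
#' a position exactly at *ter* is reported on the right arm.
#'
#' @param x Positions in bp (vectorized).
#' @param genome A [genome_spec()].
#' @return A data.frame with columns `pos_bp`, `offset_kb` (signed), `arm`
#'   (`"left"` or `"right"`).
#' @export
ori_offset <- function(x, genome) {
  stopifnot(inherits(genome, "genome_spec"))
  L <- genome$length_bp
  if (any(x < 0 | x >= L)) stop("positions must lie in [0, length_bp)")
  d_right <- (x - genome$ori_bp) %% L
  d_left <- (genome$ori_bp - x) %% L
  arm_len_right <- (genome$ter_bp - genome$ori_bp) %% L
  right <- d_right <= arm_len_right
  data.frame(
    pos_bp = x,
    offset_kb = ifelse(right, d_right, -d_left) / 1000,
    arm = ifelse(right, "right", "left"),
    stringsAsFactors = FALSE
  )
}

# ---- inversions -------------------------------------------------------------

#' Specify a chromosomal inversion
#'
#' The segment `[start_bp, end_bp)` (linearized coordinates, not spanning the
#' origin) is reversed in place.
#'
#' @param label Name of the inversion strain.
#' @param start_bp,end_bp 0-based half-open segment bounds, `start < end`.
#' @param genome_length Optional chromosome length used to validate bounds.
#' @return An object of class `inversion_spec`.
#' @export
inversion_spec <- function(label, start_bp, end_bp, genome_length = NULL) {
  if (is.na(start_bp) || is.na(end_bp))
    stop("inversion endpoints must be specified (see caulobacter_inversions()",
         " for presets with an unknown endpoint)")
  if (!(start_bp >= 0 && start_bp < end_bp))
    stop("require 0 <= start_bp < end_bp")
  if (!is.null(genome_length) && end_bp > genome_length)
    stop("inversion extends beyond the genome")
  structure(list(label = as.character(label), start_bp = start_bp,
                 end_bp = end_bp),
            class = "inversion_spec")
}

#' Named inversion presets for the NA1000 chromosome
#'
#' Endpoints (kb): 1 = 4,038; 2 = 4,030; 4 = 3,788; 5 = 3,611. The coordinate
#' of endpoint 3 is not published; the `flip34` entry is therefore `NA` and
#' [inversion_spec()] refuses to instantiate it.
#'
#' @return A named list of `inversion_spec` objects (and one `NA` placeholder).
#' @export
caulobacter_inversions <- function() {
  list(
    flip15 = inversion_spec("Flip 1-5", 3611e3, 4038e3),
    flip25 = inversion_spec("Flip 2-5", 3611e3, 4030e3),
    flip24 = inversion_spec("Flip 2-4", 3788e3, 4030e3),
    flip45 = inversion_spec("Flip 4-5", 3611e3, 3788e3),
    flip34 = NA  # endpoint 3 coordinate unpublished
  )
}

#' Remap positions through an inversion
#'
#' Positions inside `[start, end)` are reflected to `start + end - 1 - x`
#' (the offset from `start` becomes the offset back from `end`); positions
#' outside are unchanged. The map is an involution and a bijection on
#' `[0, length)`.
#'
#' @param x Positions in bp (vectorized).
#' @param inv An [inversion_spec()].
#' @param genome_length Chromosome length in bp (for validation).
#' @return Remapped positions.
#' @export
apply_inversion <- function(x, inv, genome_length) {
  stopifnot(inherits(inv, "inversion_spec"))
  if (inv$end_bp > genome_length) stop("inversion extends beyond the genome")
  if (any(x < 0 | x >= genome_length))
    stop("positions must lie in [0, length)")
  inside <- x >= inv$start_bp & x < inv$end_bp
  x[inside] <- inv$start_bp + inv$end_bp - 1 - x[inside]
  x
}

#' Remap a gene table through an inversion
#'
#' Genes fully inside the inverted segment have their interval reflected and
#' their strand flipped; genes fully outside are unchanged; genes straddling
#' an inversion endpoint are an error.
#'
#' @param genes A gene table (see [read_genes_bed()]): columns `id`, `start`,
#'   `end`, `strand`, `weight`.
#' @param inv An [inversion_spec()].
#' @param genome_length Chromosome length in bp.
#' @return The remapped gene table, ordered by `start`.
#' @export
invert_genes <- function(genes, inv, genome_length) {
  stopifnot(inherits(inv, "inversion_spec"))
  inside <- genes$start >= inv$start_bp & genes$end <= inv$end_bp
  outside <- genes$end <= inv$start_bp | genes$start >= inv$end_bp
  if (any(!inside & !outside))
    stop("gene(s) straddle an inversion endpoint: ",
         paste(genes$id[!inside & !outside], collapse = ", "))
  a <- inv$start_bp; b <- inv$end_bp
  new_start <- genes$start; new_end <- genes$end
  new_start[inside] <- a + (b - genes$end[inside])
  new_end[inside] <- a + (b - genes$start[inside])
  genes$start <- new_start
  genes$end <- new_end
  genes$strand[inside] <- ifelse(genes$strand[inside] == "+", "-", "+")
  genes[order(genes$start), , drop = FALSE]
}

#' Reverse-complement an inverted segment of a genome sequence
#'
#' @param sequence Character scalar, the full chromosome sequence.
#' @param inv An [inversion_spec()].
#' @return The sequence with `[start, end)` reverse-complemented.
#' @export
invert_sequence <- function(sequence, inv, genome = NULL) {
  stopifnot(inherits(inv, "inversion_spec"))
  n <- nchar(sequence)
  if (inv$end_bp > n) stop("inversion extends beyond the sequence")
  seg <- substr(sequence, inv$start_bp + 1, inv$end_bp)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg)))
  paste0(substr(sequence, 1, inv$start_bp), rc,
         substr(sequence, inv$end_bp + 1, n))
}
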