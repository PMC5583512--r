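#' Read mapped Hi-C read pairs
#'
#' Tab-separated text: `read_id  pos1  strand1  pos2  strand2` with optional
#' sixth `label` column (`valid` / `self_ligation` / `non_ligation`, ground
#' truth when simulated). Lines starting with `#` are comments. Positions are
#' 0-based bp on a single circular chromosome.
#'
#' @param path Path to a pairs file.
#' @return A data.frame of read pairs.
#' @export
read_pairs <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L)
    return(data.frame(read_id = character(), pos1 = numeric(),
                      strand1 = character(), pos2 = numeric(),
                      strand2 = character(), stringsAsFactors = FALSE))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 5L)
  if (length(bad))
    stop("malformed pairs record at line ", keep[bad[1]], " of ", path,
         ": expected at least 5 tab-separated fields")
  get <- function(i) vapply(fields, `[[`, "", i)
  pairs <- data.frame(
    read_id = get(1),
    pos1 = as.numeric(get(2)), strand1 = get(3),
    pos2 = as.numeric(get(4)), strand2 = get(5),
    stringsAsFactors = FALSE
  )
  if (all(nf >= 6L)) pairs$label <- get(6)
  badstrand <- which(!(pairs$strand1 %in% c("+", "-")) |
                       !(pairs$strand2 %in% c("+", "-")))
  if (length(badstrand))
    stop("malformed strand field at line ", keep[badstrand[1]], " of ", path)
  badpos <- which(is.na(pairs$pos1) | is.na(pairs$pos2))
  if (length(badpos))
    stop("malformed position field at line ", keep[badpos[1]], " of ", path)
  pairs
}

#' Write read pairs to the tab-separated pairs format
#'
#' @param pairs A read-pair data.frame (see [read_pairs()]).
#' @param path Output path.
#' @param header Optional named character vector written as `# key: value`.
#' @export
write_pairs <- function(pairs, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(sprintf("# %s: %s", names(header), header), con)
  cols <- c("read_id", "pos1", "strand1", "pos2", "strand2")
  if (!is.null(pairs$label)) cols <- c(cols, "label")
  out <- pairs[, cols, drop = FALSE]
  out$pos1 <- format(out$pos1, scientific = FALSE, trim = TRUE)
  out$pos2 <- format(out$pos2, scientific = FALSE, trim = TRUE)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Classify read pairs as valid, self-ligation, or non-ligation products
#'
#' Both mates on the same restriction fragment and pointing toward each other
#' (inward) are unligated fragments (`non_ligation`); the same fragment with
#' mates pointing away from each other (outward) indicates a self-circularized
#' fragment (`self_ligation`); mates on different fragments are `valid` Hi-C
#' products. Orientation is judged from positions and strands within the
#' (possibly wrap-around) fragment. Same-fragment pairs with equal strands do
#' not fit either ligation-artifact geometry and are kept as `valid`.
#'
#' @param pairs A read-pair data.frame (see [read_pairs()]).
#' @param frag A [fragment_map()].
#' @return Character vector of classes, one per pair.
#' @export
classify_pairs <- function(pairs, frag) {
  stopifnot(inherits(frag, "fragment_map"))
  s1 <- pairs$strand1; s2 <- pairs$strand2
  bad <- which(!(s1 %in% c("+", "-")) | !(s2 %in% c("+", "-")))
  if (length(bad)) stop("malformed strand in pair ", bad[1])
  f1 <- assign_fragment(pairs$pos1, frag)
  f2 <- assign_fragment(pairs$pos2, frag)
  cls <- rep("valid", nrow(pairs))
  same <- f1 == f2
  if (any(same)) {
    start_of <- function(f) if (length(frag$cuts)) frag$cuts[f] else 0
    off1 <- (pairs$pos1[same] - start_of(f1[same])) %% frag$length_bp
    off2 <- (pairs$pos2[same] - start_of(f2[same])) %% frag$length_bp
    a1 <- s1[same]; a2 <- s2[same]
    inward <- (off1 < off2 & a1 == "+" & a2 == "-") |
      (off2 < off1 & a2 == "+" & a1 == "-")
    outward <- (off1 < off2 & a1 == "-" & a2 == "+") |
      (off2 < off1 & a2 == "-" & a1 == "+")
    cls[same][inward] <- "non_ligation"
    cls[same][outward] <- "self_ligation"
  }
  cls
}
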