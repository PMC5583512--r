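#' Interaction-score profile along genomic offsets
#'
#' Scores (ln-scale contact values) as a function of genomic offset from an
#' anchor (usually *ori* or *parS*). Offsets near the anchor or near its
#' antipode are dominated by intra-arm contacts on a circular chromosome and
#' are flagged `excluded`.
#'
#' @param offsets_kb Offsets in kb (ascending; signed for vertical-line
#'   profiles).
#' @param score Scores at each offset (ln scale).
#' @param excluded Logical mask of offsets to ignore in downstream estimates.
#' @param anchor_bp Anchor position (bp).
#' @param kind Profile kind label (e.g. `"secondary_diagonal"`).
#' @return An object of class `score_profile`.
#' @export
score_profile <- function(offsets_kb, score, excluded = rep(FALSE, length(score)),
                          anchor_bp = NA_real_, kind = "profile") {
  stopifnot(length(offsets_kb) == length(score),
            length(excluded) == length(score))
  o <- order(offsets_kb)
  structure(list(offsets_kb = offsets_kb[o], score = score[o],
                 excluded = excluded[o] | !is.finite(score[o]),
                 anchor_bp = anchor_bp, kind = kind),
            class = "score_profile")
}

#' @export
print.score_profile <- function(x, ...) {
  cat(sprintf("<score_profile> %s: %d offsets (%g..%g kb), %d excluded\n",
              x$kind, length(x$offsets_kb), min(x$offsets_kb),
              max(x$offsets_kb), sum(x$excluded)))
  invisible(x)
}

#' @export
plot.score_profile <- function(x, ...) {
  graphics::plot(x$offsets_kb[!x$excluded], x$score[!x$excluded], type = "l",
                 xlab = "offset from anchor (kb)", ylab = "interaction score (ln)",
                 main = x$kind, ...)
  invisible(x)
}

exclusion_flags <- function(offsets_kb, half_len_kb, exclusion_kb) {
  abs(offsets_kb) < exclusion_kb | half_len_kb - abs(offsets_kb) < exclusion_kb
}

#' Inter-arm interaction scores along the secondary diagonal
#'
#' For an anchor bin `b` the secondary diagonal pairs loci equidistant from
#' the anchor on opposite arms: `score(d) = m[b - k, b + k]` (circular bin
#' arithmetic, `d = k * bin_size`). Elevated scores indicate arm-to-arm
#' juxtaposition. Offsets within `exclusion_kb` of the anchor or of its
#' antipode are flagged excluded: there the "inter-arm" diagonal approaches
#' the intra-arm main diagonal.
#'
#' @param m A log-stage [contact_matrix()].
#' @param genome A [genome_spec()] (defaults to the matrix's own).
#' @param anchor Anchor position in bp (default *ori*).
#' @param exclusion_kb Exclusion radius near anchor and antipode (default 30).
#' @return A [score_profile()].
#' @export
secondary_diagonal <- function(m, genome = m$genome, anchor = genome$ori_bp,
                               exclusion_kb = 30) {
  stopifnot(inherits(m, "contact_matrix"))
  if (m$stage != "log") stop("secondary_diagonal expects a log-stage matrix")
  n <- nrow(m$mat)
  b <- bin_of(m, anchor)
  k <- 0:(n %/% 2)
  rows <- ((b - 1 - k) %% n) + 1
  cols <- ((b - 1 + k) %% n) + 1
  d <- k * m$bin_size / 1000
  half <- genome$length_bp / 2000
  score_profile(d, m$mat[cbind(rows, cols)],
                excluded = exclusion_flags(d, half, exclusion_kb),
                anchor_bp = anchor, kind = "secondary_diagonal")
}

#' Interaction scores of one anchor bin with every bin (vertical line)
#'
#' Extracts row `b` of the matrix (the contacts of the anchor bin with every
#' other bin), indexed by signed offset from the anchor: negative offsets are
#' the left arm, positive the right.
#'
#' @inheritParams secondary_diagonal
#' @return A [score_profile()] with signed offsets.
#' @export
vertical_line <- function(m, genome = m$genome, anchor = genome$ori_bp,
                          exclusion_kb = 0) {
  stopifnot(inherits(m, "contact_matrix"))
  if (m$stage != "log") stop("vertical_line expects a log-stage matrix")
  n <- nrow(m$mat)
  b <- bin_of(m, anchor)
  L <- genome$length_bp
  starts <- bin_starts(m)
  raw <- (starts - floor(anchor / m$bin_size) * m$bin_size) %% L
  off <- ifelse(raw > L / 2, raw - L, raw) / 1000
  half <- L / 2000
  score_profile(off, m$mat[b, ],
                excluded = exclusion_flags(off, half, exclusion_kb),
                anchor_bp = anchor, kind = "vertical_line")
}

#' Per-arm inter-arm alignment profile
#'
#' For each offset `d` from the anchor along one arm, the score is the maximum
#' log contact between the bin at that offset and any bin on the opposite arm.
#' Unlike [secondary_diagonal()], which assumes loci pair at equal offsets,
#' this profile follows the alignment ridge even when the two arms zip up at
#' different speeds, so each arm's alignment extent can be measured
#' separately.
#'
#' @inheritParams secondary_diagonal
#' @param arm Which arm to profile, `"left"` or `"right"`.
#' @return A [score_profile()].
#' @export
arm_profile <- function(m, genome = m$genome, arm = c("left", "right"),
                        anchor = genome$ori_bp, exclusion_kb = 30) {
  stopifnot(inherits(m, "contact_matrix"))
  if (m$stage != "log") stop("arm_profile expects a log-stage matrix")
  arm <- match.arg(arm)
  n <- nrow(m$mat)
  b <- bin_of(m, anchor)
  k <- 1:(n %/% 2)
  sgn <- if (arm == "left") -1 else 1
  rows <- ((b - 1 + sgn * k) %% n) + 1
  cols <- ((b - 1 - sgn * k) %% n) + 1
  sub <- m$mat[rows, cols, drop = FALSE]
  sc <- apply(sub, 1, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  d <- k * m$bin_size / 1000
  half <- genome$length_bp / 2000
  score_profile(d, sc, excluded = exclusion_flags(d, half, exclusion_kb),
                anchor_bp = anchor, kind = paste0("arm_", arm))
}

#' Estimate the extent of chromosomal arm alignment from a score profile
#'
#' Background is the median score over a distal window where no alignment
#' signal is expected; the peak is the maximum of the moving-median-smoothed
#' profile. The extent is the largest offset up to which the smoothed profile
#' stays at or above `background + fraction * (peak - background)` (first
#' down-crossing rule). All three knobs are exposed.
#'
#' @param p A [score_profile()] (unsigned offsets).
#' @param background_window Distal window (kb) for the background median,
#'   default `c(1200, 1800)`.
#' @param fraction Threshold fraction between background and peak, default 0.5
#'   (half-max).
#' @param smooth_bins Moving-median width in profile bins (odd; default 3).
#' @return An `extent_estimate`: list with `extent_kb`, `background`, `peak`,
#'   `threshold`, `flag` (`"ok"` or `"no_signal"`), `method`.
#' @export
alignment_extent <- function(p, background_window = c(1200, 1800),
                             fraction = 0.5, smooth_bins = 3) {
  stopifnot(inherits(p, "score_profile"))
  keep <- !p$excluded
  off <- p$offsets_kb[keep]
  sc <- p$score[keep]
  if (length(off) < smooth_bins) stop("too few unmasked offsets")
  sm <- stats::runmed(sc, smooth_bins, endrule = "median")
  inbg <- off >= background_window[1] & off <= background_window[2]
  if (!any(inbg) || all(inbg))
    stop("profile needs unmasked offsets inside and outside the background window")
  background <- stats::median(sm[inbg])
  peak <- max(sm)
  method <- sprintf("halfmax(fraction=%g, smooth=%d, bg=[%g,%g]kb)",
                    fraction, smooth_bins, background_window[1],
                    background_window[2])
  mk <- function(extent, thr, flag)
    structure(list(extent_kb = extent, background = background, peak = peak,
                   threshold = thr, flag = flag, method = method),
              class = "extent_estimate")
  if (peak <= background) return(mk(0, background, "no_signal"))
  threshold <- background + fraction * (peak - background)
  below <- which(sm < threshold)
  if (length(below) == 0L) return(mk(off[length(off)], threshold, "ok"))
  if (below[1] == 1L) return(mk(0, threshold, "no_signal"))
  mk(off[below[1] - 1L], threshold, "ok")
}

#' @export
print.extent_estimate <- function(x, ...) {
  cat(sprintf("<extent_estimate> %g kb [%s]\n", x$extent_kb, x$flag))
  cat(sprintf("  background %.3f | threshold %.3f | peak %.3f (%s)\n",
              x$background, x$threshold, x$peak, x$method))
  invisible(x)
}

#' Fit an arm-alignment rate from time-resolved extents
#'
#' Ordinary least-squares fit of alignment extent (kb) against time (min)
#' over the points falling inside `window` (inclusive).
#'
#' @param extents A data.frame with columns `t` (min) and `extent_kb`.
#' @param window Time window in minutes, default `c(10, 25)`.
#' @return A `rate_fit`: `slope_kb_per_min`, `intercept_kb`, `window`,
#'   `residual_rmse`, `n`.
#' @export
alignment_rate <- function(extents, window = c(10, 25)) {
  stopifnot(is.data.frame(extents), all(c("t", "extent_kb") %in% names(extents)))
  sel <- extents$t >= window[1] & extents$t <= window[2]
  if (sum(sel) < 2L) stop("need at least 2 time points inside the window")
  fit <- stats::lm(extent_kb ~ t, data = extents[sel, , drop = FALSE])
  structure(list(slope_kb_per_min = unname(stats::coef(fit)[2]),
                 intercept_kb = unname(stats::coef(fit)[1]),
                 window = window,
                 residual_rmse = sqrt(mean(stats::residuals(fit)^2)),
                 n = sum(sel)),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> %.2f kb/min over t in [%g, %g] min (n = %d, rmse %.1f kb)\n",
              x$slope_kb_per_min, x$window[1], x$window[2], x$n,
              x$residual_rmse))
  invisible(x)
}

# least-absolute-deviations line fit, deterministic (Nelder-Mead from OLS)
lad_fit <- function(x, y) {
  ols <- stats::coef(stats::lm(y ~ x))
  obj <- function(p) sum(abs(y - p[1] - p[2] * x))
  fit <- stats::optim(ols, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 10000))
  c(intercept = unname(fit$par[1]), slope = unname(fit$par[2]))
}

#' Quantify asymmetry of the inter-arm interaction ridge
#'
#' For each left-arm offset in `left_range`, records the right-arm offset with
#' the maximal inter-arm score, then fits a robust (least absolute deviations)
#' line through the (left, right) offset pairs. A symmetric alignment band
#' gives slope 1 (0 degrees deviation from the diagonal); one-arm stalling
#' flattens the ridge. The vertical-streak flag is set when, among
#' near-maximal inter-arm scores, the interquartile spread of left offsets is
#' less than a quarter of that of right offsets (a narrow left region
#' contacting a long right segment).
#'
#' @inheritParams secondary_diagonal
#' @param left_range,right_range Offset ranges (kb) scanned on each arm.
#' @param top_quantile Score quantile defining "near-maximal" cells for the
#'   streak diagnostic (default 0.90).
#' @return A `ridge_fit`: `slope`, `intercept`, `deviation_deg`, `streak`,
#'   `iqr_left_kb`, `iqr_right_kb`, and the `(dL, dR)` ridge table.
#' @export
ridge_asymmetry <- function(m, genome = m$genome, anchor = genome$ori_bp,
                            left_range = c(40, 400), right_range = c(40, 500),
                            top_quantile = 0.90) {
  stopifnot(inherits(m, "contact_matrix"))
  if (m$stage != "log") stop("ridge_asymmetry expects a log-stage matrix")
  n <- nrow(m$mat)
  bs_kb <- m$bin_size / 1000
  b <- bin_of(m, anchor)
  krange <- function(r) {
    lo <- ceiling(r[1] / bs_kb); hi <- floor(r[2] / bs_kb)
    if (hi < lo) stop("empty offset range")
    lo:hi
  }
  kL <- krange(left_range)
  kR <- krange(right_range)
  rows <- ((b - 1 - kL) %% n) + 1
  cols <- ((b - 1 + kR) %% n) + 1
  sub <- m$mat[rows, cols, drop = FALSE]
  dL <- kL * bs_kb
  dR <- kR * bs_kb
  arg <- apply(sub, 1, function(r) if (all(is.na(r))) NA_integer_ else which.max(r))
  ok <- !is.na(arg)
  ridge <- data.frame(dL = dL[ok], dR = dR[arg[ok]])
  co <- lad_fit(ridge$dL, ridge$dR)
  ang <- atan(co[["slope"]]) * 180 / pi
  deviation <- abs(45 - ang) %% 90
  thr <- stats::quantile(sub, top_quantile, na.rm = TRUE)
  sel <- which(sub >= thr, arr.ind = TRUE)
  iqrL <- stats::IQR(dL[sel[, 1]])
  iqrR <- stats::IQR(dR[sel[, 2]])
  structure(list(slope = co[["slope"]], intercept = co[["intercept"]],
                 deviation_deg = deviation,
                 streak = is.finite(iqrR) && iqrR > 0 && iqrL < iqrR / 4,
                 iqr_left_kb = iqrL, iqr_right_kb = iqrR, ridge = ridge),
            class = "ridge_fit")
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat(sprintf("<ridge_fit> slope %.2f, deviation %.1f deg from diagonal; streak %s\n",
              x$slope, x$deviation_deg, if (x$streak) "ON" else "off"))
  cat(sprintf("  near-maximal IQR: left %.0f kb, right %.0f kb\n",
              x$iqr_left_kb, x$iqr_right_kb))
  invisible(x)
}

#' Paired t test between two interaction-score profiles
#'
#' Tests whether the per-offset differences `a - b` over the jointly unmasked
#' offsets differ from zero (Student's paired t).
#'
#' @param a,b Two [score_profile()]s on identical offset grids.
#' @param alternative `"two.sided"`, `"less"`, or `"greater"` (for `a - b`).
#' @return A `stat_result`: `estimate` (mean difference), `statistic` (t),
#'   `p_value`, `df`, `n`, `sidedness`.
#' @export
profile_paired_t <- function(a, b, alternative = c("two.sided", "less", "greater")) {
  stopifnot(inherits(a, "score_profile"), inherits(b, "score_profile"))
  alternative <- match.arg(alternative)
  if (length(a$offsets_kb) != length(b$offsets_kb) ||
      any(a$offsets_kb != b$offsets_kb))
    stop("mismatched offsets between profiles")
  keep <- !a$excluded & !b$excluded
  if (sum(keep) < 2L) stop("need at least 2 jointly unmasked offsets")
  d <- a$score[keep] - b$score[keep]
  if (stats::sd(d) == 0) stop("degenerate differences: zero variance")
  ht <- stats::t.test(a$score[keep], b$score[keep], paired = TRUE,
                      alternative = alternative)
  structure(list(estimate = unname(ht$estimate), statistic = unname(ht$statistic),
                 p_value = ht$p.value, df = unname(ht$parameter),
                 n = sum(keep), sidedness = alternative),
            class = "stat_result")
}

#' Pearson correlation between two matched tracks
#'
#' Sample Pearson r with a two-sided p value from the t transform, for two
#' equal-length numeric vectors paired on matched genomic offsets.
#'
#' @param x,y Numeric vectors of equal length (>= 3), finite.
#' @return A `stat_result` with `estimate` = r.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ht <- stats::cor.test(x, y, method = "pearson")
  structure(list(estimate = unname(ht$estimate), statistic = unname(ht$statistic),
                 p_value = ht$p.value, df = unname(ht$parameter),
                 n = length(x), sidedness = "two.sided"),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> estimate %.4f, statistic %.3f, p = %.3g (n = %d, %s)\n",
              x$estimate, x$statistic, x$p_value, x$n, x$sidedness))
  invisible(x)
}

#' Write a score profile as TSV
#'
#' Two columns (`offset_kb`, `score`); excluded offsets are listed in the `#`
#' header so files round-trip.
#'
#' @param p A [score_profile()].
#' @param path Output path.
#' @export
write_profile <- function(p, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# smcalign_profile kind=%s anchor_bp=%.0f excluded=%s",
                     p$kind, p$anchor_bp,
                     if (any(p$excluded))
                       paste(which(p$excluded), collapse = ",") else "-"), con)
  writeLines("offset_kb\tscore", con)
  writeLines(sprintf("%.10g\t%.10e", p$offsets_kb, p$score), con)
  invisible(path)
}

#' Read a score profile written by [write_profile()]
#' @param path Path to the profile TSV.
#' @return A [score_profile()].
#' @export
read_profile <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!grepl("^# smcalign_profile ", hdr)) stop("not a smcalign profile: ", path)
  kv <- strsplit(strsplit(sub("^# smcalign_profile ", "", hdr), " ")[[1]], "=")
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  tab <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  excl <- rep(FALSE, nrow(tab))
  if (meta[["excluded"]] != "-")
    excl[as.integer(strsplit(meta[["excluded"]], ",")[[1]])] <- TRUE
  score_profile(tab$offset_kb, tab$score, excluded = excl,
                anchor_bp = as.numeric(meta[["anchor_bp"]]),
                kind = meta[["kind"]])
}

#' Write a flat key-value report file
#' @param x Named list of scalars.
#' @param path Output path.
#' @export
write_report <- function(x, path) {
  vals <- vapply(x, function(v)
    if (is.numeric(v)) sprintf("%.9g", v) else as.character(v), "")
  writeLines(paste(names(x), vals, sep = "\t"), path)
  invisible(path)
}

#' Read a key-value report file written by [write_report()]
#' @param path Path to the report.
#' @return Named list (numeric where parseable).
#' @export
read_report <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  out <- lapply(tab$V2, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  })
  stats::setNames(out, tab$V1)
}
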