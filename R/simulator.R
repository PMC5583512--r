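#' Configuration for the SMC arm-alignment simulator
#'
#' The generative model: SMC complexes load at *parS* and tether the two
#' chromosomal arms while translocating toward *ter*, the left and right arm
#' being reeled at speeds `v_left` / `v_right` (kb/min). A tether loaded at
#' time 0 and observed at age `tau` sits at arm offsets
#' `(min(v_left * tau, cap), min(v_right * tau, cap))`; occupancy over
#' `(dL, dR)` is exponential attrition `exp(-max(dL, dR)/lambda)` with
#' processivity `lambda` along the leading arm, times a Gaussian kernel of
#' width `sigma` around that register path (a ray at slope `v_right/v_left`
#' plus a completion segment while the lagging arm catches up to the cap),
#' truncated at the per-arm fronts
#' `min(v * t, front_cap)`. Transcription barriers on an arm either unload a
#' fraction `beta` of complexes (occupancy beyond the barrier scaled by
#' `1 - beta`) or stall that arm (a fraction `beta` keeps its offset pinned at
#' the barrier while the other arm continues, adding the vertical-streak
#' ridge). Expected Hi-C contact probabilities combine power-law distance
#' decay `(s + s0)^(-alpha)`, a uniform floor `epsilon`, and `amplitude * O`
#' on inter-arm bin pairs.
#'
#' @param genome A [genome_spec()] (default [caulobacter_genome()]).
#' @param alpha Distance-decay exponent (default 1).
#' @param s0_kb Decay offset in kb (default 10).
#' @param epsilon Uniform background floor (default 1e-3).
#' @param amplitude Tether amplitude on the decay scale (default 0.08, chosen
#'   so the inter-arm band stands well clear of the floor out to the cap).
#' @param sigma_kb Co-progression kernel width in kb (default 30).
#' @param lambda_kb Processivity in kb (default 600).
#' @param front_cap_kb Maximum tether reach in kb; defaults to `lambda_kb`,
#'   making the processivity scale the alignment-extent ground truth.
#' @param v_left,v_right Per-arm translocation speeds in kb/min (defaults 19
#'   and 16).
#' @param t_min Time since loading began, minutes (`Inf` = steady state; at
#'   `t = 0` no tethers exist yet).
#' @param barriers `NULL` or a data.frame with columns `arm` (`"left"` /
#'   `"right"`), `offset_kb` (from *parS*), `beta` (0..1), `mode` (`"unload"`
#'   / `"stall"`).
#' @param n_pairs Number of read pairs to sample.
#' @param fractions Named class fractions summing to 1
#'   (`valid`, `self_ligation`, `non_ligation`).
#' @param chip_depth Expected total ChIP reads per sample.
#' @param load_amp,load_sigma_kb Height and width of the parS loading peak in
#'   the simulated SMC ChIP signal.
#' @param artifact `NULL` or a data.frame with `pos_bp`, `strength`:
#'   "hyper-ChIPable" artifact peaks at highly expressed genes, present in
#'   tagged and untagged samples alike.
#' @param artifact_ratio Tagged:untagged strength ratio of artifact peaks
#'   (1 = artifacts cancel exactly in the enrichment ratio).
#' @param seed Integer seed governing all stochastic draws (per-stage
#'   substreams are derived from it deterministically).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome = caulobacter_genome(), alpha = 1, s0_kb = 10,
                       epsilon = 1e-3, amplitude = 0.08, sigma_kb = 30,
                       lambda_kb = 600, front_cap_kb = lambda_kb,
                       v_left = 19, v_right = 16, t_min = Inf,
                       barriers = NULL, n_pairs = 1e6,
                       fractions = c(valid = 0.70, self_ligation = 0.15,
                                     non_ligation = 0.15),
                       chip_depth = 2e6, load_amp = 3, load_sigma_kb = 5,
                       artifact = NULL, artifact_ratio = 1,
                       seed = 1L) {
  stopifnot(inherits(genome, "genome_spec"), alpha > 0, lambda_kb > 0,
            v_left >= 0, v_right >= 0, epsilon >= 0, amplitude >= 0,
            sigma_kb > 0, n_pairs >= 1)
  fractions <- fractions[c("valid", "self_ligation", "non_ligation")]
  if (any(is.na(fractions)) || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must name valid, self_ligation, non_ligation and sum to 1")
  if (!is.null(barriers)) {
    stopifnot(all(c("arm", "offset_kb", "beta", "mode") %in% names(barriers)),
              all(barriers$arm %in% c("left", "right")),
              all(barriers$beta >= 0 & barriers$beta <= 1),
              all(barriers$mode %in% c("unload", "stall")))
    barriers <- barriers[order(barriers$offset_kb), , drop = FALSE]
  }
  structure(list(genome = genome, alpha = alpha, s0_kb = s0_kb,
                 epsilon = epsilon, amplitude = amplitude, sigma_kb = sigma_kb,
                 lambda_kb = lambda_kb, front_cap_kb = front_cap_kb,
                 v_left = v_left, v_right = v_right, t_min = t_min,
                 barriers = barriers, n_pairs = n_pairs, fractions = fractions,
                 chip_depth = chip_depth, load_amp = load_amp,
                 load_sigma_kb = load_sigma_kb, artifact = artifact,
                 artifact_ratio = artifact_ratio, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> lambda %g kb, amplitude %g, v %g/%g kb/min, t %s min\n",
              x$lambda_kb, x$amplitude, x$v_left, x$v_right,
              format(x$t_min)))
  cat(sprintf("  %d barrier(s); %s pairs; seed %d\n",
              if (is.null(x$barriers)) 0L else nrow(x$barriers),
              format(x$n_pairs, big.mark = ","), x$seed))
  invisible(x)
}

#' Scenario presets
#'
#' Named configurations mirroring the experimental panel logic: `wt`
#' (symmetric band), `dsmc` (no tethers), `flip25` (full stall barrier 70 kb
#' out on the left arm: vertical streak), `flip24` (partial stall closer in),
#' `flip45` (stall after a ~290-kb symmetric phase), `rif`
#' (transcription inhibited: the flip25 scenario with its barriers removed),
#' `flip15` (loading site relocated ~429 kb from *ori* by the large
#' inversion), `ectopic_parS` (extra loading site at +1,800 kb), and
#' `timecourse` (ParB replenishment kinetics; pair `times` with
#' [simulate_timecourse()]).
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
sim_preset <- function(name = c("wt", "dsmc", "flip25", "flip24", "flip45",
                                "rif", "flip15", "ectopic_parS", "timecourse"),
                       seed = 1L, ...) {
  name <- match.arg(name)
  g <- caulobacter_genome()
  stall <- function(offset_kb, beta)
    data.frame(arm = "left", offset_kb = offset_kb, beta = beta,
               mode = "stall")
  args <- switch(
    name,
    wt = list(),
    dsmc = list(amplitude = 0),
    flip25 = list(barriers = stall(70, 1)),
    flip24 = list(barriers = stall(80, 0.7)),
    flip45 = list(barriers = stall(290, 0.9)),
    # transcription inhibited: head-on barriers vanish and, with no
    # transcriptional friction, both arms translocate at the mean speed
    rif = list(v_left = 17.5, v_right = 17.5),
    flip15 = list(genome = genome_spec(g$name, g$length_bp, ori_bp = g$ori_bp,
                                       parS_bp = 3614070, ter_bp = g$ter_bp),
                  lambda_kb = 400, front_cap_kb = 400),
    ectopic_parS = list(genome = genome_spec(g$name, g$length_bp,
                                             ori_bp = g$ori_bp,
                                             parS_bp = 1800e3,
                                             ter_bp = g$ter_bp),
                        lambda_kb = 300, front_cap_kb = 300),
    timecourse = list(n_pairs = 5e5)
  )
  do.call(sim_config, utils::modifyList(args, c(list(seed = seed), list(...))))
}

# per-arm translocation front (kb): how far tethers reach at time t
sim_fronts <- function(config) {
  t <- config$t_min
  cap <- config$front_cap_kb
  c(left = min(config$v_left * t, cap), right = min(config$v_right * t, cap))
}

# squared distance from points (X, Y) to the segment a -> b
dist2_segment <- function(X, Y, a, b) {
  ux <- b[1] - a[1]; uy <- b[2] - a[2]
  len2 <- ux^2 + uy^2
  if (len2 == 0) return((X - a[1])^2 + (Y - a[2])^2)
  tt <- pmin(pmax(((X - a[1]) * ux + (Y - a[2]) * uy) / len2, 0), 1)
  (X - (a[1] + tt * ux))^2 + (Y - (a[2] + tt * uy))^2
}

# the tether register path {(min(vL*tau, cap), min(vR*tau, cap))}: a ray at
# slope vR/vL until the leading arm reaches the cap, then a completion
# segment while the lagging arm catches up
register_path <- function(config) {
  cap <- config$front_cap_kb
  vL <- config$v_left; vR <- config$v_right
  t <- config$t_min
  p <- function(tau) c(min(vL * tau, cap), min(vR * tau, cap))
  if (vL == 0 && vR == 0) return(list(c(0, 0), c(0, 0)))
  tau_knee <- cap / max(vL, vR)
  tau_end <- min(t, if (min(vL, vR) > 0) cap / min(vL, vR) else Inf)
  if (!is.finite(tau_end)) tau_end <- tau_knee   # one arm immobile
  list(p(0), p(min(tau_knee, tau_end)), p(tau_end))
}

# occupancy O(dL, dR) evaluated on the outer grid of two offset vectors (kb)
occupancy_grid <- function(config, dL, dR) {
  fr <- sim_fronts(config)
  DL <- matrix(dL, length(dL), length(dR))
  DR <- matrix(dR, length(dL), length(dR), byrow = TRUE)
  lam <- config$lambda_kb
  sig <- config$sigma_kb
  path <- register_path(config)
  d2 <- pmin(dist2_segment(DL, DR, path[[1]], path[[2]]),
             dist2_segment(DL, DR, path[[2]], path[[3]]))
  O <- exp(-pmax(DL, DR) / lam) * exp(-d2 / (2 * sig^2))
  ridge <- 0
  for (arm in c("left", "right")) {
    b <- config$barriers
    b <- b[b$arm == arm, , drop = FALSE]
    if (is.null(b) || nrow(b) == 0L) next
    Dthis <- if (arm == "left") DL else DR
    Dother <- if (arm == "left") DR else DL
    vt <- if (arm == "left") config$v_left else config$v_right
    vo <- if (arm == "left") config$v_right else config$v_left
    survive <- 1
    for (i in seq_len(nrow(b))) {
      g <- b$offset_kb[i]
      if (g > fr[[arm]]) break                      # front never reaches it
      if (b$mode[i] == "stall") {
        # fraction beta pins this arm at g while the other arm, which stood
        # at g * vo/vt when the stall happened, keeps translocating
        g_other <- if (vt > 0) g * vo / vt else 0
        ridge <- ridge + survive * b$beta[i] *
          exp(-pmax(g, Dother) / lam) *
          exp(-(Dthis - g)^2 / (2 * sig^2)) * (Dother >= g_other)
      }
      survive <- survive * (1 - b$beta[i])
      O <- O * ifelse(Dthis > g, 1 - b$beta[i], 1)
    }
  }
  O <- O + ridge
  O[DL > fr[["left"]] | DR > fr[["right"]]] <- 0
  if (config$t_min == 0) O[] <- 0
  O
}

#' Tether occupancy surface
#'
#' Evaluates the SMC tether occupancy `O(dL, dR)` of the model on a regular
#' offset grid, with per-arm marginals (each normalized to a unit maximum
#' when positive).
#'
#' @param config A [sim_config()].
#' @param grid_kb Grid step in kb (default 5).
#' @param max_kb Largest offset evaluated (default: half the genome).
#' @return An `occupancy_surface`: list with `dL`, `dR` (kb grids), `O`
#'   (matrix), `marginal_left`, `marginal_right`.
#' @export
sim_occupancy <- function(config, grid_kb = 5,
                          max_kb = config$genome$length_bp / 2000) {
  stopifnot(inherits(config, "sim_config"))
  d <- seq(0, max_kb, by = grid_kb)
  O <- occupancy_grid(config, d, d)
  norm1 <- function(x) if (max(x) > 0) x / max(x) else x
  structure(list(dL = d, dR = d, O = O,
                 marginal_left = norm1(rowSums(O)),
                 marginal_right = norm1(colSums(O))),
            class = "occupancy_surface")
}

#' @export
print.occupancy_surface <- function(x, ...) {
  cat(sprintf("<occupancy_surface> %d x %d grid, step %g kb, max O = %.3g\n",
              length(x$dL), length(x$dR), diff(x$dL[1:2]), max(x$O)))
  invisible(x)
}

# signed parS offsets of bin centers: list(right = kb or NA, left = kb or NA)
bin_parS_offsets <- function(config, bin_size) {
  g <- config$genome
  L <- g$length_bp
  n <- n_bins(g, bin_size)
  starts <- (seq_len(n) - 1) * bin_size
  lens <- bin_lengths_bp(g, bin_size)
  centers <- starts + lens / 2
  a <- (centers - g$parS_bp) %% L
  right <- a <= L / 2
  list(right = ifelse(right, a / 1000, NA_real_),
       left = ifelse(right, NA_real_, (L - a) / 1000),
       is_right = right, centers = centers)
}

#' Expected Hi-C contact probability matrix of the model
#'
#' `P(i, j)` combines power-law distance decay between bin centers, the
#' uniform floor, and the tether occupancy for inter-arm bin pairs, and is
#' normalized to sum 1 over the upper triangle including the diagonal.
#'
#' @param config A [sim_config()].
#' @param bin_size Bin size in bp (default 10 kb).
#' @return A probability-stage [contact_matrix()].
#' @export
expected_matrix <- function(config, bin_size = 10000) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$genome
  L <- g$length_bp
  off <- bin_parS_offsets(config, bin_size)
  centers <- off$centers
  D <- abs(outer(centers, centers, "-"))
  S <- pmin(D, L - D) / 1000
  P <- (S + config$s0_kb)^(-config$alpha) + config$epsilon
  if (config$amplitude > 0 && config$t_min > 0) {
    iR <- which(off$is_right)
    iL <- which(!off$is_right)
    if (length(iR) && length(iL)) {
      O <- occupancy_grid(config, off$left[iL], off$right[iR])
      P[iL, iR] <- P[iL, iR] + config$amplitude * O
      P[iR, iL] <- P[iR, iL] + config$amplitude * t(O)
    }
  }
  u <- P; u[lower.tri(u)] <- 0
  P <- P / sum(u)
  contact_matrix(P, bin_size, "probability", g)
}

# split n into class counts that sum to n, honoring the fractions
class_counts <- function(n, fractions) {
  k <- floor(n * fractions)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(n * fractions - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  k
}

#' Sample labeled read pairs from the model
#'
#' Valid pairs are drawn from the expected-matrix bin probabilities with
#' uniform positions within bins, resampled until the two mates fall on
#' different restriction fragments; self-ligation and non-ligation pairs are
#' placed on a single fragment (chosen proportional to length) with outward /
#' inward mate orientation. Ground-truth labels are attached and the draw is
#' fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param frag A [fragment_map()] for the same genome.
#' @param bin_size Bin size for the expected matrix (default 10 kb).
#' @return A read-pair data.frame with a `label` column.
#' @export
sample_pairs <- function(config, frag, bin_size = 10000) {
  stopifnot(inherits(config, "sim_config"), inherits(frag, "fragment_map"))
  g <- config$genome
  if (frag$length_bp != g$length_bp)
    stop("fragment map and genome lengths differ")
  set.seed(config$seed)
  n <- n_bins(g, bin_size)
  lens <- bin_lengths_bp(g, bin_size)
  counts <- class_counts(config$n_pairs, config$fractions)

  # --- valid pairs -----------------------------------------------------------
  P <- expected_matrix(config, bin_size)$mat
  ut <- which(upper.tri(P, diag = TRUE), arr.ind = TRUE)
  probs <- P[ut]
  nv <- counts[["valid"]]
  pos1 <- pos2 <- numeric(nv)
  todo <- seq_len(nv)
  cell <- sample.int(nrow(ut), nv, replace = TRUE, prob = probs)
  draw_pos <- function(bin, k) (bin - 1) * bin_size + floor(stats::runif(k) * lens[bin])
  for (iter in 1:100) {
    i <- ut[cell[todo], 1]; j <- ut[cell[todo], 2]
    pos1[todo] <- draw_pos(i, length(todo))
    pos2[todo] <- draw_pos(j, length(todo))
    same <- assign_fragment(pos1[todo], frag) == assign_fragment(pos2[todo], frag)
    if (iter %% 20 == 0 && any(same))  # bins engulfed by one fragment: new cell
      cell[todo[same]] <- sample.int(nrow(ut), sum(same), replace = TRUE,
                                     prob = probs)
    todo <- todo[same]
    if (length(todo) == 0L) break
  }
  if (length(todo))
    stop("could not place ", length(todo), " valid pair(s) on distinct fragments")
  valid <- data.frame(
    pos1 = pos1, strand1 = sample(c("+", "-"), nv, replace = TRUE),
    pos2 = pos2, strand2 = sample(c("+", "-"), nv, replace = TRUE),
    label = "valid", stringsAsFactors = FALSE)

  # --- same-fragment artifact classes ---------------------------------------
  flens <- fragment_lengths(frag)
  fstart <- if (length(frag$cuts)) frag$cuts else 0
  same_frag_pairs <- function(k, inward) {
    eligible <- which(flens >= 2)
    fi <- eligible[sample.int(length(eligible), k, replace = TRUE,
                              prob = flens[eligible])]
    o1 <- floor(stats::runif(k) * flens[fi])
    o2 <- floor(stats::runif(k) * (flens[fi] - 1))
    o2 <- ifelse(o2 >= o1, o2 + 1, o2)             # two distinct offsets
    lo <- pmin(o1, o2); hi <- pmax(o1, o2)
    data.frame(
      pos1 = (fstart[fi] + lo) %% frag$length_bp,
      strand1 = if (inward) "+" else "-",
      pos2 = (fstart[fi] + hi) %% frag$length_bp,
      strand2 = if (inward) "-" else "+",
      label = if (inward) "non_ligation" else "self_ligation",
      stringsAsFactors = FALSE)
  }
  out <- rbind(valid,
               same_frag_pairs(counts[["self_ligation"]], inward = FALSE),
               same_frag_pairs(counts[["non_ligation"]], inward = TRUE))
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  cbind(read_id = sprintf("sim_%07d", seq_len(nrow(out))), out,
        stringsAsFactors = FALSE)
}

#' Simulate a ParB-replenishment Hi-C time course
#'
#' One labeled read-pair set per time point, with tether occupancy truncated
#' at the per-arm fronts `v * t`; at `t = 0` no tethers exist.
#'
#' @param config A [sim_config()] (typically `sim_preset("timecourse")`).
#' @param times Sampling times in minutes.
#' @param frag A [fragment_map()]; defaults to [synthetic_fragments()] on the
#'   config's genome.
#' @return Named list of read-pair data.frames, one per time point.
#' @export
simulate_timecourse <- function(config, times = c(0, 5, 10, 15, 25, 30),
                                frag = NULL) {
  stopifnot(inherits(config, "sim_config"), all(times >= 0))
  if (is.null(frag)) frag <- synthetic_fragments(config$genome,
                                                 seed = config$seed)
  out <- lapply(seq_along(times), function(i) {
    cfg <- config
    cfg$t_min <- times[i]
    cfg$seed <- config$seed + 1009L * i
    sample_pairs(cfg, frag)
  })
  names(out) <- paste0("t", times)
  out
}

#' Simulate SMC ChIP-seq tracks (tagged and untagged samples)
#'
#' The tagged sample's expected signal is a flat baseline plus a Gaussian
#' loading peak at *parS*, the per-arm tether-occupancy marginals laid along
#' the chromosome, and any configured hyper-ChIPable artifact peaks; the
#' untagged control carries only baseline and artifacts (scaled by
#' `1 / artifact_ratio`). Read counts are Poisson at `chip_depth` and
#' reported as RPKPM tracks.
#'
#' @param config A [sim_config()].
#' @param bin_size Track bin size in bp (default 1 kb).
#' @return List with `tagged` and `untagged` [chip_track()]s.
#' @export
simulate_chip <- function(config, bin_size = 1000) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 77L)
  g <- config$genome
  n <- n_bins(g, bin_size)
  off <- bin_parS_offsets(config, bin_size)
  arm_off <- ifelse(off$is_right, off$right, off$left)
  grid <- seq(0, max(arm_off) + 10, by = 5)
  O <- occupancy_grid(config, grid, grid)
  margL <- rowSums(O); margR <- colSums(O)
  mx <- max(margL, margR, 1e-300)
  occ_sig <- ifelse(off$is_right,
                    stats::approx(grid, margR / mx, xout = arm_off, rule = 2)$y,
                    stats::approx(grid, margL / mx, xout = arm_off, rule = 2)$y)
  if (config$amplitude == 0 || config$t_min == 0) occ_sig <- 0 * occ_sig
  dparS <- arc_distance(off$centers %% g$length_bp,
                        rep(g$parS_bp, n), g) / 1000
  load_pk <- config$load_amp * exp(-dparS^2 / (2 * config$load_sigma_kb^2))
  if (config$amplitude == 0 || config$t_min == 0) load_pk <- 0 * load_pk
  art <- numeric(n)
  if (!is.null(config$artifact) && nrow(config$artifact))
    for (i in seq_len(nrow(config$artifact))) {
      d <- arc_distance(off$centers %% g$length_bp,
                        rep(config$artifact$pos_bp[i], n), g) / 1000
      art <- art + config$artifact$strength[i] * exp(-d^2 / 2)  # ~1-kb peaks
    }
  base <- 1
  rate_tag <- base + load_pk + occ_sig + art
  rate_untag <- base + art / config$artifact_ratio
  lens_kb <- bin_lengths_bp(g, bin_size) / 1000
  draw <- function(rate, label) {
    lam <- rate * lens_kb
    counts <- stats::rpois(n, config$chip_depth * lam / sum(lam))
    total <- sum(counts)
    chip_track(counts / lens_kb / (total / 1e6), bin_size, g,
               total_reads = total, label = label)
  }
  list(tagged = draw(rate_tag, "tagged"), untagged = draw(rate_untag, "untagged"))
}
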