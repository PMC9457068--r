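#' Call boundaries from an insulation track
#'
#' Boundaries are local minima of the insulation score whose topographic
#' prominence reaches `min_prominence`. The prominence of a minimum is the
#' smaller, over the two sides, of (highest intervening score - minimum score)
#' scanning out to the nearest deeper minimum (or the end of the defined
#' track). Plateau minima are reported at their leftmost bin. Each contiguous
#' defined segment of the track is scanned independently.
#'
#' @param track an `insulation_track`.
#' @param min_prominence minimum prominence in log2 score units.
#' @return a `boundary_set`: data.frame with `chrom`, `bin` (0-based bin of the
#'   minimum), `pos` (bp, bin * resolution), `strength` (prominence).
#' @export
call_boundaries <- function(track, min_prominence = 0.15) {
  score <- track$score
  assert_that(any(!is.na(score)), "all-missing insulation track")
  segs <- split(which(!is.na(score)),
                cumsum(c(1, diff(which(!is.na(score)))) != 1))
  rows <- list()
  for (seg in segs) {
    x <- score[seg]
    mins <- local_minima(x)
    for (i in mins) {
      p <- prominence_at(x, i)
      if (p >= min_prominence) {
        # a boundary depresses the two bins flanking its edge almost equally,
        # so the edge sits between the minimum and its lower-scoring neighbor;
        # reporting that edge is stable to +/-1-bin jitter of the argmin
        lo_right <- i < length(x) && (i == 1 || x[i + 1] <= x[i - 1])
        edge <- seg[i] - 1L + as.integer(lo_right)
        rows[[length(rows) + 1]] <- data.frame(
          chrom = track$chrom, bin = seg[i] - 1L,
          pos = edge * track$resolution, strength = p)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), bin = integer(), pos = numeric(),
               strength = numeric())
  out <- out[order(out$chrom, out$bin), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("boundary_set", "data.frame")
  attr(out, "resolution") <- track$resolution
  out
}

# indices of (plateau-aware) strict local minima; plateau reported at left edge
local_minima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  out <- integer()
  i <- 2
  while (i <= n - 1) {
    if (x[i] < x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1
      if (j <= n - 1 && x[j + 1] > x[i]) out <- c(out, i)
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# topographic prominence of the minimum at index i of x: per side, the barrier
# is (running max - x[i]) out to the nearest deeper point (or segment end)
prominence_at <- function(x, i) {
  scan <- function(idx) {
    if (length(idx) == 0) return(Inf)
    run_max <- -Inf
    for (j in idx) {
      if (x[j] < x[i]) return(run_max - x[i])
      run_max <- max(run_max, x[j])
    }
    run_max - x[i]
  }
  left <- scan(if (i > 1) (i - 1):1 else integer())
  right <- scan(if (i < length(x)) (i + 1):length(x) else integer())
  min(left, right)
}

#' Two-scale TAD/subTAD boundary calling
#'
#' TAD boundaries come from a coarse-window insulation track; subTAD
#' boundaries are fine-window boundaries that do not fall within one bin of a
#' TAD boundary (so the two levels never coincide). The input matrix is
#' balanced internally unless already flagged balanced.
#'
#' @param cm a `contact_matrix`.
#' @param coarse_window,fine_window insulation windows in bp
#'   (coarse > fine; defaults 100 kb and 50 kb).
#' @param min_prominence length-2 numeric, prominence thresholds for the TAD
#'   and subTAD level (log2 units). On deeply covered maps TAD minima are far
#'   more prominent than subTAD minima, so the TAD threshold doubles as the
#'   level separator: coarse-window minima below it are left to the subTAD
#'   level.
#' @return list of class `boundary_hierarchy` with `tad` and `subtad`
#'   boundary sets and both insulation tracks.
#' @export
call_hierarchy <- function(cm, coarse_window = 1e5, fine_window = 5e4,
                           min_prominence = c(tad = 2, subtad = 0.5)) {
  assert_that(coarse_window > fine_window, "coarse_window must exceed fine_window")
  if (!isTRUE(attr(cm, "balanced"))) cm <- balance(cm)
  tr_c <- insulation_track(cm, coarse_window)
  tr_f <- insulation_track(cm, fine_window)
  tad <- call_boundaries(tr_c, min_prominence[[1]])
  fine <- call_boundaries(tr_f, min_prominence[[2]])
  near_tad <- vapply(fine$bin, function(b) any(abs(tad$bin - b) <= 1), TRUE)
  subtad <- fine[!near_tad, , drop = FALSE]
  rownames(subtad) <- NULL
  class(subtad) <- class(fine)
  attr(subtad, "resolution") <- attr(fine, "resolution")
  structure(list(tad = tad, subtad = subtad,
                 coarse_track = tr_c, fine_track = tr_f),
            class = "boundary_hierarchy")
}

#' Match two position sets one-to-one within a tolerance
#'
#' Greedy nearest-neighbor matching: candidate pairs within `tol` are accepted
#' in order of increasing distance, ties broken toward the smaller coordinate
#' (then smaller partner coordinate), each position used at most once. On 1-d
#' point sets this attains maximum matching cardinality.
#'
#' @param x,y numeric position vectors.
#' @param tol maximum |x - y|.
#' @return 2-column integer matrix of matched (index into x, index into y).
#' @export
match_positions <- function(x, y, tol) {
  if (length(x) == 0 || length(y) == 0)
    return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  cand <- which(abs(outer(x, y, "-")) <= tol, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  d <- abs(x[cand[, 1]] - y[cand[, 2]])
  ord <- order(d, x[cand[, 1]], y[cand[, 2]])
  used_x <- logical(length(x)); used_y <- logical(length(y))
  keep <- matrix(integer(), ncol = 2)
  for (k in ord) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_x[i] && !used_y[j]) {
      used_x[i] <- TRUE; used_y[j] <- TRUE
      keep <- rbind(keep, c(i, j))
    }
  }
  colnames(keep) <- c("x", "y")
  keep
}

#' Classify boundaries across a control and two clones
#'
#' A control boundary matched (one-to-one, within `tol`) in both clones is
#' `constant`; matched in neither, `lost`; in exactly one, `discordant`. Clone
#' boundaries unmatched in the control that mutually match between the clones
#' are `gained` (one record per pair, at the clone-1 position); one-clone-only
#' novelties are `discordant`. The returned rows therefore partition the union
#' of matched boundary entities across the three samples.
#'
#' @param control,clone1,clone2 `boundary_set` objects (same level/resolution),
#'   or numeric vectors of bp positions.
#' @param tol matching tolerance in bp (default 10 kb).
#' @return a `boundary_class_table`: data.frame with `pos` (bp), `class`,
#'   `source`, and matched partner positions (NA where unmatched).
#' @export
classify_boundaries <- function(control, clone1, clone2, tol = 1e4) {
  pos_of <- function(b) if (is.data.frame(b)) as.numeric(b$pos) else as.numeric(b)
  res <- if (is.data.frame(control)) attr(control, "resolution") else NULL
  if (!is.null(res) && tol < res)
    warning("tolerance below matrix resolution; matching may be too strict")
  pc <- pos_of(control); p1 <- pos_of(clone1); p2 <- pos_of(clone2)
  m1 <- match_positions(pc, p1, tol)
  m2 <- match_positions(pc, p2, tol)
  in1 <- seq_along(pc) %in% m1[, 1]
  in2 <- seq_along(pc) %in% m2[, 1]
  cls <- ifelse(in1 & in2, "constant", ifelse(!in1 & !in2, "lost", "discordant"))
  match1 <- rep(NA_real_, length(pc)); match1[m1[, 1]] <- p1[m1[, 2]]
  match2 <- rep(NA_real_, length(pc)); match2[m2[, 1]] <- p2[m2[, 2]]
  ctrl_rows <- data.frame(pos = pc, class = cls, source = "control",
                          clone1_pos = match1, clone2_pos = match2)
  nov1 <- setdiff(seq_along(p1), m1[, 2])
  nov2 <- setdiff(seq_along(p2), m2[, 2])
  mg <- match_positions(p1[nov1], p2[nov2], tol)
  gained_rows <- data.frame(pos = p1[nov1][mg[, 1]],
                            class = rep("gained", nrow(mg)),
                            source = rep("clones", nrow(mg)),
                            clone1_pos = p1[nov1][mg[, 1]],
                            clone2_pos = p2[nov2][mg[, 2]])
  solo1 <- p1[nov1][setdiff(seq_along(nov1), mg[, 1])]
  solo2 <- p2[nov2][setdiff(seq_along(nov2), mg[, 2])]
  solo_rows <- data.frame(
    pos = c(solo1, solo2),
    class = rep("discordant", length(solo1) + length(solo2)),
    source = c(rep("clone1", length(solo1)), rep("clone2", length(solo2))),
    clone1_pos = c(solo1, rep(NA_real_, length(solo2))),
    clone2_pos = c(rep(NA_real_, length(solo1)), solo2))
  out <- rbind(ctrl_rows, gained_rows, solo_rows)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("boundary_class_table", "data.frame")
  attr(out, "n_control") <- length(pc)
  out
}

#' Adjacency of gained boundaries to lost boundaries
#'
#' Tests whether gained boundaries sit closer to lost boundaries than uniform
#' placement would put them. The statistic is the median distance from each
#' gained boundary to its nearest lost boundary; the null re-places the gained
#' set uniformly on the valid positions `n_random` times. The reported ratio
#' is null-median / observed (> 1 means gained boundaries are unusually close
#' to lost ones) with empirical p = (1 + #{null <= observed}) / (n_random + 1).
#'
#' @param gained,lost bp positions: numeric vectors (single chromosome) or
#'   data.frames with `chrom` and `pos` (distances never cross chromosomes;
#'   gained boundaries on chromosomes without any lost boundary are dropped).
#' @param valid_positions candidate bp positions for random placement: a
#'   numeric vector, or a named per-chromosome list of vectors.
#' @param n_random number of null placements (default 999).
#' @param seed integer seed.
#' @return list with `observed`, `null_median`, `ratio`, `p`, `n_random`,
#'   `n_gained`.
#' @export
gained_lost_adjacency <- function(gained, lost, valid_positions,
                                  n_random = 999, seed = 1) {
  if (!is.data.frame(gained))
    gained <- data.frame(chrom = rep(".", length(gained)), pos = as.numeric(gained))
  if (!is.data.frame(lost))
    lost <- data.frame(chrom = rep(".", length(lost)), pos = as.numeric(lost))
  if (!is.list(valid_positions))
    valid_positions <- stats::setNames(list(valid_positions), ".")
  assert_that(nrow(gained) >= 1 && nrow(lost) >= 1,
              "need at least one gained and one lost boundary")
  gained <- gained[gained$chrom %in% unique(lost$chrom), , drop = FALSE]
  assert_that(nrow(gained) >= 1, "no gained boundary shares a chromosome with a lost one")
  lost_by <- split(lost$pos, lost$chrom)
  nearest_median <- function(chrom, pos) {
    stats::median(vapply(seq_along(pos), function(i)
      min(abs(lost_by[[chrom[i]]] - pos[i])), 0))
  }
  obs <- nearest_median(gained$chrom, gained$pos)
  set.seed(seed)
  null_stats <- vapply(seq_len(n_random), function(i) {
    pos <- vapply(gained$chrom, function(ch)
      sample(valid_positions[[ch]], 1), 0)
    nearest_median(gained$chrom, pos)
  }, 0)
  list(observed = obs, null_median = stats::median(null_stats),
       ratio = stats::median(null_stats) / obs,
       p = empirical_p(sum(null_stats <= obs), n_random),
       n_random = n_random, n_gained = nrow(gained))
}

#' Export a boundary class table as BED (class in the name field)
#' @param table a `boundary_class_table`.
#' @param chrom chromosome name.
#' @param resolution bin size in bp (boundary interval width).
#' @return a `feature_set`.
#' @export
boundary_classes_to_bed <- function(table, chrom, resolution) {
  feature_set(data.frame(chrom = chrom, start = table$pos,
                         end = table$pos + resolution, name = table$class))
}
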