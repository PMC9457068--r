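#' Generate a nested TAD/subTAD domain hierarchy
#'
#' Tiles each chromosome with TADs whose sizes are drawn uniformly from
#' `tad_size` (default 100 kb - 1 Mb, the textbook TAD scale), then splits
#' each TAD into up to `subtads_per_tad` subTADs (jittered equal partition, so
#' subTADs tile their parent exactly). Every boundary carries an insulation
#' factor f in (0, 1]: the fraction of cross-boundary contacts retained by the
#' contact simulator; smaller f = stronger boundary.
#'
#' @param chrom_sizes named vector of chromosome lengths in bp.
#' @param resolution bin size in bp (default 10 kb).
#' @param tad_size length-2 vector, TAD size range in bp.
#' @param subtads_per_tad target subTAD count per TAD (fewer in small TADs;
#'   0 disables the subTAD level).
#' @param f_tad,f_subtad length-2 ranges for per-boundary insulation factors.
#' @param seed integer seed (same seed, same hierarchy).
#' @return object of class `domain_hierarchy`: `resolution` plus, per
#'   chromosome, `n_bins` and `tad` / `subtad` boundary tables (`bin`, `f`).
#' @export
generate_domain_hierarchy <- function(chrom_sizes, resolution = 1e4,
                                      tad_size = c(1e5, 1e6),
                                      subtads_per_tad = 3,
                                      f_tad = c(0.05, 0.2),
                                      f_subtad = c(0.6, 0.8),
                                      seed = 1) {
  assert_that(all(chrom_sizes >= 2 * max(tad_size)),
              "chromosome shorter than 2 x max TAD size")
  assert_that(mean(tad_size) <= min(chrom_sizes),
              "infeasible: mean TAD size exceeds a chromosome")
  set.seed(seed)
  min_bins <- max(2L, as.integer(floor(tad_size[1] / resolution)))
  max_bins <- as.integer(floor(tad_size[2] / resolution))
  min_sub_bins <- 10L  # keep subTADs resolvable by a 50-kb insulation window
  chroms <- lapply(chrom_sizes, function(len) {
    n <- as.integer(floor(len / resolution))
    sizes <- integer()
    while (sum(sizes) < n) {
      sizes <- c(sizes, as.integer(round(stats::runif(1, min_bins, max_bins))))
    }
    sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
    if (sizes[length(sizes)] < min_bins && length(sizes) > 1) {
      sizes[length(sizes) - 1] <- sizes[length(sizes) - 1] + sizes[length(sizes)]
      sizes <- sizes[-length(sizes)]
    }
    tad_b <- cumsum(sizes)[-length(sizes)]
    sub_b <- integer()
    starts <- c(0L, tad_b); ends <- c(tad_b, n)
    for (t in seq_along(starts)) {
      s <- ends[t] - starts[t]
      n_sub <- min(subtads_per_tad, floor(s / min_sub_bins))
      if (n_sub >= 2) {
        cuts <- starts[t] +
          round(seq_len(n_sub - 1) * s / n_sub +
                  stats::runif(n_sub - 1, -s / (4 * n_sub), s / (4 * n_sub)))
        cuts <- cuts[cuts > starts[t] + 1 & cuts < ends[t] - 1]
        sub_b <- c(sub_b, as.integer(cuts))
      }
    }
    list(n_bins = n,
         tad = data.frame(bin = as.integer(tad_b),
                          f = stats::runif(length(tad_b), f_tad[1], f_tad[2])),
         subtad = data.frame(bin = sort(unique(sub_b)),
                             f = stats::runif(length(unique(sub_b)),
                                              f_subtad[1], f_subtad[2])))
  })
  structure(list(resolution = resolution, chroms = chroms,
                 params = list(tad_size = tad_size, f_tad = f_tad,
                               f_subtad = f_subtad)),
            class = "domain_hierarchy")
}

#' Domain intervals implied by a hierarchy's boundaries
#'
#' @param hier a `domain_hierarchy`.
#' @param chrom chromosome name.
#' @param level "tad" (TAD tiling) or "subtad" (tiling by the union of TAD and
#'   subTAD boundaries, i.e. the finest domains).
#' @return data.frame with `start_bin`, `end_bin` (half-open, in bins).
#' @export
domain_intervals <- function(hier, chrom, level = c("tad", "subtad")) {
  level <- match.arg(level)
  ch <- hier$chroms[[chrom]]
  b <- if (level == "tad") ch$tad$bin else sort(c(ch$tad$bin, ch$subtad$bin))
  data.frame(start_bin = c(0L, b), end_bin = c(b, ch$n_bins))
}

#' Perturb a hierarchy: remove and add boundaries at both levels
#'
#' Removal counts are round(fraction x level count) drawn uniformly over the
#' genome (removing a TAD boundary merges the adjacent TADs). Added boundaries
#' are placed preferentially within `added_window` of a removed boundary
#' (uniform inside the window), falling back to uniform placement when no slot
#' is free, and never on or adjacent to an existing boundary. Default
#' fractions mirror a moderate-depletion experiment where subTAD boundaries
#' turn over more than TAD boundaries (17%/11% vs 10%/7%).
#'
#' @param hier a `domain_hierarchy`.
#' @param frac_subtad_removed,frac_subtad_added,frac_tad_removed,frac_tad_added
#'   perturbation fractions in [0, 1].
#' @param added_window placement window around removed boundaries in bp.
#' @param seed integer seed.
#' @return list with `hierarchy` (perturbed `domain_hierarchy`) and `record`
#'   (a `change_record`: data.frame chrom/level/change/bin/pos).
#' @export
perturb_hierarchy <- function(hier,
                              frac_subtad_removed = 0.17,
                              frac_subtad_added = 0.11,
                              frac_tad_removed = 0.10,
                              frac_tad_added = 0.07,
                              added_window = 1e5, seed = 1) {
  fr <- c(frac_subtad_removed, frac_subtad_added, frac_tad_removed, frac_tad_added)
  assert_that(all(fr >= 0 & fr <= 1), "perturbation fractions must be in [0, 1]")
  set.seed(seed)
  res <- hier$resolution
  out <- hier
  rec <- list()
  note <- function(chrom, level, change, bin) {
    rec[[length(rec) + 1]] <<- data.frame(chrom = chrom, level = level,
                                          change = change, bin = bin,
                                          pos = bin * res)
  }
  # --- removals, pooled across chromosomes per level
  for (level in c("tad", "subtad")) {
    frac <- if (level == "tad") frac_tad_removed else frac_subtad_removed
    pool <- do.call(rbind, lapply(names(out$chroms), function(ch) {
      b <- out$chroms[[ch]][[level]]
      if (nrow(b)) data.frame(chrom = ch, bin = b$bin) else NULL
    }))
    n_remove <- round(frac * (if (is.null(pool)) 0 else nrow(pool)))
    if (n_remove > 0) {
      take <- pool[sample(nrow(pool), n_remove), , drop = FALSE]
      for (r in seq_len(nrow(take))) {
        ch <- take$chrom[r]; b <- take$bin[r]
        tb <- out$chroms[[ch]][[level]]
        out$chroms[[ch]][[level]] <- tb[tb$bin != b, , drop = FALSE]
        note(ch, level, "removed", b)
      }
    }
  }
  rec_df <- if (length(rec)) do.call(rbind, rec) else
    data.frame(chrom = character(), level = character(), change = character(),
               bin = integer(), pos = numeric())
  # --- additions, near removed boundaries when possible
  win_bins <- as.integer(added_window / res)
  all_bounds <- function(ch) sort(c(out$chroms[[ch]]$tad$bin, out$chroms[[ch]]$subtad$bin))
  free_bins <- function(ch) {
    n <- out$chroms[[ch]]$n_bins
    cand <- setdiff(2:(n - 2), unlist(lapply(all_bounds(ch), function(b) (b - 2):(b + 2))))
    cand
  }
  removed <- rec_df[rec_df$change == "removed", , drop = FALSE]
  f_rng <- list(tad = hier$params$f_tad %||% c(0.05, 0.2),
                subtad = hier$params$f_subtad %||% c(0.6, 0.8))
  for (level in c("tad", "subtad")) {
    frac <- if (level == "tad") frac_tad_added else frac_subtad_added
    n_orig <- sum(vapply(hier$chroms, function(c) nrow(c[[level]]), 0L))
    n_add <- round(frac * n_orig)
    if (n_add > 0 && n_orig == 0 && nrow(removed) == 0)
      stop("cannot add boundaries: no parent structure remains", call. = FALSE)
    for (a in seq_len(n_add)) {
      placed <- FALSE
      if (nrow(removed) > 0) {
        anchor <- removed[sample(nrow(removed), 1), ]
        cand <- intersect(free_bins(anchor$chrom),
                          (anchor$bin - win_bins):(anchor$bin + win_bins))
        if (length(cand) > 0) {
          b <- cand[sample(length(cand), 1)]
          ch <- anchor$chrom; placed <- TRUE
        }
      }
      if (!placed) {
        ch <- sample(names(out$chroms), 1,
                     prob = vapply(out$chroms, function(c) c$n_bins, 0))
        cand <- free_bins(ch)
        assert_that(length(cand) > 0, "no free position for an added boundary")
        b <- cand[sample(length(cand), 1)]
      }
      tb <- out$chroms[[ch]][[level]]
      out$chroms[[ch]][[level]] <-
        rbind(tb, data.frame(bin = as.integer(b),
                             f = stats::runif(1, f_rng[[level]][1], f_rng[[level]][2])))
      out$chroms[[ch]][[level]] <-
        out$chroms[[ch]][[level]][order(out$chroms[[ch]][[level]]$bin), , drop = FALSE]
      note(ch, level, "added", b)
    }
  }
  if (length(rec)) rec_df <- do.call(rbind, rec)
  rec_df <- rec_df[order(rec_df$chrom, rec_df$level, rec_df$change, rec_df$bin), , drop = FALSE]
  rownames(rec_df) <- NULL
  class(rec_df) <- c("change_record", "data.frame")
  list(hierarchy = out, record = rec_df)
}
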