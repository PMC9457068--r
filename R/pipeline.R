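#' Default study configuration for the synthetic paired-condition design
#'
#' Two 20-Mb chromosomes at 10-kb bins, a control hierarchy plus a perturbed
#' hierarchy shared by two "clone" replicates with independent sequencing
#' noise, and the feature generator defaults of [feature_sim_params()].
#'
#' @param seed master integer seed; every stochastic stage derives its own
#'   sub-seed from it via [derive_seed()].
#' @return a named config list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    chrom_sizes = c(chrA = 2e7, chrB = 2e7),
    resolution = 1e4,
    depth = 100, alpha = 1, e_tad = 3, e_subtad = 2,
    perturb = list(frac_subtad_removed = 0.17, frac_subtad_added = 0.11,
                   frac_tad_removed = 0.10, frac_tad_added = 0.07,
                   added_window = 1e5),
    windows = list(coarse = 1e5, fine = 5e4),
    min_prominence = c(tad = 2, subtad = 0.5),
    boundary_tol = 1e4,
    thresholds = list(ctcf = list(fdr = 0.01, lfc = 1),
                      marks = list(fdr = 0.05, lfc = 1)),
    n_perm = 199,
    features = list()
  )
}

#' Read a run configuration from YAML
#' @param path YAML file; entries override [default_config()].
#' @return config list.
#' @export
read_run_config <- function(path) {
  assert_that(file.exists(path), paste("file not found:", path))
  cfg <- yaml::read_yaml(path)
  assert_that(!is.null(cfg$seed), "config must set a seed")
  base <- default_config(cfg$seed)
  cfg$chrom_sizes <- unlist(cfg$chrom_sizes) %||% base$chrom_sizes
  utils::modifyList(base, cfg)
}

#' Simulate a complete paired-condition study
#'
#' Generates the control hierarchy, perturbs it, simulates control and two
#' clone contact matrices per chromosome (clones share the perturbed
#' hierarchy, with independent Poisson noise), and simulates CTCF/mark/
#' expression features with ground truth.
#'
#' @param config list from [default_config()] (entries may be overridden).
#' @return list with `hier_ctl`, `hier_pert`, `record`, `matrices` (per
#'   chromosome: `ctl`, `clone1`, `clone2`), `features`, `config`.
#' @export
simulate_study <- function(config = default_config()) {
  cfg <- utils::modifyList(default_config(config$seed %||% 1), config)
  hier <- generate_domain_hierarchy(cfg$chrom_sizes, cfg$resolution,
                                    seed = derive_seed(cfg$seed, 1))
  pert <- do.call(perturb_hierarchy,
                  c(list(hier = hier, seed = derive_seed(cfg$seed, 2)),
                    cfg$perturb))
  mk <- function(h, k) {
    out <- lapply(names(cfg$chrom_sizes), function(ch)
      simulate_contact_matrix(h, ch, depth = cfg$depth, alpha = cfg$alpha,
                              e_tad = cfg$e_tad, e_subtad = cfg$e_subtad,
                              seed = derive_seed(cfg$seed, k + match(ch, names(cfg$chrom_sizes)) * 10)))
    names(out) <- names(cfg$chrom_sizes)
    out
  }
  matrices <- list(ctl = mk(hier, 3), clone1 = mk(pert$hierarchy, 4),
                   clone2 = mk(pert$hierarchy, 5))
  matrices <- lapply(names(matrices[[1]]), function(ch)
    list(ctl = matrices$ctl[[ch]], clone1 = matrices$clone1[[ch]],
         clone2 = matrices$clone2[[ch]]))
  names(matrices) <- names(cfg$chrom_sizes)
  feats <- simulate_features(hier, pert$record, cfg$features,
                             seed = derive_seed(cfg$seed, 6))
  list(hier_ctl = hier, hier_pert = pert$hierarchy, record = pert$record,
       matrices = matrices, features = feats, config = cfg)
}

#' Percentage summary of a boundary partition
#'
#' Lost and gained percentages are both reported relative to the control
#' boundary count (the convention under which 810 gained of 11,580 control
#' boundaries is a 7% gain).
#'
#' @param counts named counts with at least `constant`, `lost`, `gained`
#'   (e.g. from `table(classification$class)`).
#' @param control_total number of control boundaries; default
#'   constant + lost + discordant-from-control is not inferable from counts
#'   alone, so pass it explicitly when available.
#' @return data.frame with class, count, pct (full precision) and pct_rounded.
#' @export
summarize_partitions <- function(counts, control_total = NULL) {
  counts <- as.list(counts)
  for (cl in c("constant", "lost", "gained")) counts[[cl]] <- counts[[cl]] %||% 0
  if (is.null(control_total))
    control_total <- counts$constant + counts$lost + (counts$discordant %||% 0)
  assert_that(control_total > 0, "zero control boundary total")
  cls <- names(counts)
  cnt <- unlist(counts)
  data.frame(class = cls, count = as.numeric(cnt),
             pct = 100 * as.numeric(cnt) / control_total,
             pct_rounded = round(100 * as.numeric(cnt) / control_total))
}

boundary_positions <- function(hier, chrom, level) hier$chroms[[chrom]][[level]]$bin * hier$resolution

# truth-vs-called matching metrics at +/- tol bp
recovery_metrics <- function(truth_pos, called_pos, tol) {
  m <- match_positions(truth_pos, called_pos, tol)
  tp <- nrow(m)
  recall <- if (length(truth_pos)) tp / length(truth_pos) else NA_real_
  precision <- if (length(called_pos)) tp / length(called_pos) else NA_real_
  f1 <- if (!is.na(recall) && !is.na(precision) && (recall + precision) > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(tp = tp, recall = recall, precision = precision, f1 = f1)
}

#' Run the full differential-architecture workflow
#'
#' Orchestrates simulate -> balance/insulate -> call hierarchy -> classify
#' boundaries -> differential peaks -> colocalization enrichment ->
#' boundary-expression association -> pileups, and returns a report bundle.
#' With an `outdir`, tables are written as TSV/BED and the summary as JSON.
#' Deterministic under a fixed config seed.
#'
#' @param config config list (see [default_config()]) or a YAML path.
#' @param outdir optional output directory.
#' @param sim optional pre-built [simulate_study()] result (to avoid
#'   re-simulating when the caller already has one).
#' @return a report list: boundary tables, partition summaries, differential
#'   feature tables, enrichments, association tables, pileups and (for
#'   simulated input) truth-recovery metrics.
#' @export
run_differential_architecture <- function(config = default_config(),
                                          outdir = NULL, sim = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(sim)) sim <- simulate_study(config)
  cfg <- sim$config
  res <- cfg$resolution
  tol <- cfg$boundary_tol

  ## boundary calling per chromosome and condition
  calls <- lapply(names(sim$matrices), function(ch) {
    lapply(sim$matrices[[ch]], function(cm)
      call_hierarchy(cm, cfg$windows$coarse, cfg$windows$fine, cfg$min_prominence))
  })
  names(calls) <- names(sim$matrices)

  ## classification per level, pooled across chromosomes
  class_tables <- lapply(c(tad = "tad", subtad = "subtad"), function(level) {
    per_chrom <- lapply(names(calls), function(ch) {
      tab <- classify_boundaries(calls[[ch]]$ctl[[level]],
                                 calls[[ch]]$clone1[[level]],
                                 calls[[ch]]$clone2[[level]], tol)
      tab$chrom <- ch
      tab
    })
    out <- do.call(rbind, per_chrom)
    class(out) <- c("boundary_class_table", "data.frame")
    attr(out, "n_control") <- sum(vapply(per_chrom, function(t) attr(t, "n_control"), 0L))
    out
  })
  partitions <- lapply(class_tables, function(tab)
    summarize_partitions(table(tab$class), attr(tab, "n_control")))

  ## differential peaks and marks
  dens_cols <- function(df) as.matrix(df[, grep("^(ctl|trt)_", names(df)), drop = FALSE])
  cond <- rep(c("ctl", "trt"), each = sum(grepl("^ctl_", names(sim$features$ctcf))))
  ctcf_diff <- classify_differential(dens_cols(sim$features$ctcf), cond,
                                     cfg$thresholds$ctcf$fdr, cfg$thresholds$ctcf$lfc,
                                     peaks = sim$features$ctcf)
  ctcf_diff$truth_class <- sim$features$ctcf$truth_class
  mark_diff <- lapply(sim$features$marks, function(m)
    classify_differential(dens_cols(m), cond, cfg$thresholds$marks$fdr,
                          cfg$thresholds$marks$lfc, peaks = m))

  ## genomic context of lost vs constant CTCF sites
  ctx <- annotate_context(feature_set(ctcf_diff), sim$features$genes)
  context_table <- as.data.frame(table(class = ctcf_diff$class, context = ctx))

  ## colocalization enrichments
  valid_pos <- lapply(sim$hier_ctl$chroms, function(c) (seq_len(c$n_bins) - 1) * res)
  lost_sub <- class_tables$subtad[class_tables$subtad$class == "lost", ]
  gained_sub <- class_tables$subtad[class_tables$subtad$class == "gained", ]
  lost_ctcf_fs <- feature_set(ctcf_diff[ctcf_diff$class == "lost", ])
  enrich <- list()
  if (nrow(lost_ctcf_fs) > 0 && nrow(lost_sub) > 0)
    enrich$lost_ctcf_at_lost_subtad <- oe_boundary_enrichment(
      lost_ctcf_fs, lost_sub[, c("chrom", "pos")], valid_pos, tol,
      cfg$n_perm, derive_seed(cfg$seed, 20))
  gained_k27 <- feature_set(mark_diff$h3k27ac[mark_diff$h3k27ac$class == "gained", ])
  if (nrow(gained_k27) > 0 && nrow(gained_sub) > 0)
    enrich$gained_h3k27ac_at_gained_subtad <- oe_boundary_enrichment(
      gained_k27, gained_sub[, c("chrom", "pos")], valid_pos, tol,
      cfg$n_perm, derive_seed(cfg$seed, 21))

  ## gained-next-to-lost adjacency, pooled over levels and chromosomes
  all_cls <- rbind(class_tables$tad, class_tables$subtad)
  gained_any <- all_cls[all_cls$class == "gained", c("chrom", "pos")]
  lost_any <- all_cls[all_cls$class == "lost", c("chrom", "pos")]
  adjacency <- if (nrow(gained_any) > 0 && nrow(lost_any) > 0)
    gained_lost_adjacency(gained_any, lost_any, valid_pos,
                          n_random = cfg$n_perm, seed = derive_seed(cfg$seed, 22))

  ## boundary-expression association (subTAD level)
  assoc <- boundary_expression_association(class_tables$subtad,
                                           sim$features$expression, tol)

  ## delta-delta coupling on the correlation-coupled H3K27ac subset
  coupled <- mark_diff$h3k27ac[sim$features$marks$h3k27ac$coupled, ]
  dd <- delta_delta_correlation(coupled, sim$features$expression, tol = 3000)

  ## pileups: lost vs constant CTCF anchors, control vs clone
  ch1 <- names(sim$matrices)[1]
  anchors_of <- function(df, cl) {
    f <- df[df$truth_class == cl & df$chrom == ch1, ]
    (f$start + f$end) / 2
  }
  lost_anchor <- anchors_of(sim$features$ctcf, "lost")
  pile <- list(
    lost_ctl = anchor_pileup(sim$matrices[[ch1]]$ctl, lost_anchor, 2e5,
                             seed = derive_seed(cfg$seed, 23)),
    lost_clone = anchor_pileup(sim$matrices[[ch1]]$clone1, lost_anchor, 2e5,
                               seed = derive_seed(cfg$seed, 24)))
  removed_sub_ch1 <- sim$record[sim$record$change == "removed" &
                                  sim$record$level == "subtad" &
                                  sim$record$chrom == ch1, ]
  prof <- insulation_profile(
    list(ctl = calls[[ch1]]$ctl$fine_track, clone1 = calls[[ch1]]$clone1$fine_track),
    removed_sub_ch1$pos + res / 2, 2e5)

  ## truth recovery
  truth <- list()
  for (level in c("tad", "subtad")) {
    tp <- unlist(lapply(names(calls), function(ch) {
      truth_pos <- boundary_positions(sim$hier_ctl, ch, level)
      called <- calls[[ch]]$ctl[[level]]$pos
      recovery_metrics(truth_pos, called, res)$tp
    }))
    nt <- sum(vapply(names(calls), function(ch)
      length(boundary_positions(sim$hier_ctl, ch, level)), 0))
    nc <- sum(vapply(names(calls), function(ch) nrow(calls[[ch]]$ctl[[level]]), 0L))
    truth[[paste0(level, "_recall")]] <- sum(tp) / nt
    truth[[paste0(level, "_precision")]] <- sum(tp) / nc
  }
  rm_sub <- sim$record[sim$record$change == "removed" & sim$record$level == "subtad", ]
  lost_called <- class_tables$subtad[class_tables$subtad$class == "lost", ]
  tp <- sum(vapply(names(calls), function(ch) {
    recovery_metrics(rm_sub$pos[rm_sub$chrom == ch],
                     lost_called$pos[lost_called$chrom == ch], tol)$tp
  }, 0))
  truth$lost_subtad_recall <- tp / max(1, nrow(rm_sub))
  truth$lost_subtad_precision <- tp / max(1, nrow(lost_called))
  truth$lost_subtad_f1 <- 2 * truth$lost_subtad_recall * truth$lost_subtad_precision /
    max(1e-12, truth$lost_subtad_recall + truth$lost_subtad_precision)

  report <- list(config = cfg, calls = calls, class_tables = class_tables,
                 partitions = partitions, ctcf_diff = ctcf_diff,
                 mark_diff = mark_diff, context_table = context_table,
                 enrichment = enrich, adjacency = adjacency,
                 association = assoc, delta_delta = dd, pileups = pile,
                 insulation_profiles = prof, truth_recovery = truth)
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' Write the report bundle as TSV/BED/JSON under a directory
#' @param report list from [run_differential_architecture()].
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) data.table::fwrite(as.data.frame(df),
                                             file.path(outdir, name), sep = "\t")
  for (level in names(report$class_tables)) {
    w(report$class_tables[[level]], paste0("boundaries_", level, ".tsv"))
    w(report$partitions[[level]], paste0("partition_", level, ".tsv"))
  }
  w(report$ctcf_diff, "ctcf_differential.tsv")
  for (m in names(report$mark_diff)) w(report$mark_diff[[m]],
                                       paste0(m, "_differential.tsv"))
  w(report$context_table, "ctcf_context.tsv")
  w(report$association, "boundary_expression.tsv")
  summary <- list(
    schema_version = 1,
    partitions = lapply(report$partitions, function(p)
      stats::setNames(as.list(p$pct), p$class)),
    enrichment = lapply(report$enrichment, function(e)
      e[c("observed", "expected", "oe", "p")]),
    adjacency = report$adjacency[c("observed", "ratio", "p")],
    delta_delta = report$delta_delta,
    truth_recovery = report$truth_recovery)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
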