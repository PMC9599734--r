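#' Summarise a site-record metric by ligand class
#'
#' Filters records by resolution (headline aggregates use 2.5 ångström and
#' better) and, optionally, by QC pass, then computes per-class summaries of
#' the chosen metric plus an `all` row. The share of short hydrogen bonds uses
#' the `hbond_class` column when present.
#'
#' @param records site-record data frame (see [scan_structures()]).
#' @param metric name of a numeric column (default `"wb_k1_distance"`).
#' @param resolution_max records with worse (larger) or missing resolution are
#'   dropped; `Inf` disables the filter.
#' @param require_qc drop records with `qc_pass` not `TRUE`.
#' @return data frame with one row per class plus `"all"`: `ligand_class`,
#'   `n`, `mean`, `median`, `q1`, `q3`, `sd`, `share_short`. Empty groups have
#'   `n = 0` and `NA` moments.
#' @export
aggregate_by_class <- function(records, metric = "wb_k1_distance",
                               resolution_max = 2.5, require_qc = TRUE) {
  stopifnot(metric %in% names(records))
  r <- records
  if (is.finite(resolution_max)) {
    r <- r[!is.na(r$resolution) & r$resolution <= resolution_max, , drop = FALSE]
  }
  if (require_qc && "qc_pass" %in% names(r)) {
    r <- r[!is.na(r$qc_pass) & r$qc_pass, , drop = FALSE]
  }
  classes <- c(sort(unique(r$ligand_class)), "all")
  one <- function(v, hb) {
    v <- v[!is.na(v)]
    if (!length(v)) {
      return(data.frame(n = 0L, mean = NA_real_, median = NA_real_,
                        q1 = NA_real_, q3 = NA_real_, sd = NA_real_,
                        share_short = NA_real_))
    }
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(v), mean = mean(v), median = qs[2], q1 = qs[1],
               q3 = qs[3], sd = stats::sd(v),
               share_short = if (!is.null(hb)) mean(hb == "short", na.rm = TRUE)
                             else NA_real_)
  }
  out <- NULL
  for (cl in classes) {
    sub <- if (cl == "all") r else r[r$ligand_class == cl, , drop = FALSE]
    hb <- if ("hbond_class" %in% names(sub)) sub$hbond_class else NULL
    out <- rbind(out, cbind(data.frame(ligand_class = cl), one(sub[[metric]], hb)))
  }
  rownames(out) <- NULL
  out
}

#' Compare a metric between two ligand classes
#'
#' Two-sided Mann-Whitney U (midrank formula with the normal approximation
#' and tie correction, no continuity correction — so identical groups give
#' exactly p = 1). The distance distributions are visibly non-normal, hence a
#' rank test. Benjamini-Hochberg adjustment across all pairwise comparisons is
#' applied by [compare_all_classes()].
#'
#' @param records site-record data frame.
#' @param metric numeric column name.
#' @param class_a,class_b the two ligand classes.
#' @return list with `statistic` (U), `p_value`, `n_a`, `n_b`; `p_value` is
#'   `NA` with a warning when either group has fewer than 3 values.
#' @export
compare_classes <- function(records, metric, class_a, class_b) {
  va <- records[[metric]][records$ligand_class == class_a]
  vb <- records[[metric]][records$ligand_class == class_b]
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  if (length(va) < 3 || length(vb) < 3) {
    warning("group with fewer than 3 values: p reported NA")
    return(list(statistic = NA_real_, p_value = NA_real_,
                n_a = length(va), n_b = length(vb)))
  }
  wt <- stats::wilcox.test(va, vb, exact = FALSE, correct = FALSE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(va), n_b = length(vb))
}

#' All pairwise class comparisons with BH adjustment
#'
#' @param records site-record data frame.
#' @param metric numeric column name.
#' @return data frame: `class_a`, `class_b`, `statistic`, `p_value`,
#'   `p_adjusted` (Benjamini-Hochberg across the rows).
#' @export
compare_all_classes <- function(records, metric = "wb_k1_distance") {
  cls <- sort(unique(records$ligand_class))
  out <- NULL
  if (length(cls) >= 2) {
    for (i in seq_len(length(cls) - 1L)) for (j in (i + 1L):length(cls)) {
      cc <- suppressWarnings(compare_classes(records, metric, cls[i], cls[j]))
      out <- rbind(out, data.frame(class_a = cls[i], class_b = cls[j],
                                   statistic = cc$statistic,
                                   p_value = cc$p_value,
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    out <- data.frame(class_a = character(0), class_b = character(0),
                      statistic = numeric(0), p_value = numeric(0))
  }
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Write the per-class report: summary TSV, comparison TSV and figures
#'
#' One kernel-density + box figure per ligand class (Scott's-rule bandwidth;
#' presentational only) and two tab-separated tables. Re-running on the same
#' input reproduces the TSVs byte for byte.
#'
#' @param summaries output of [aggregate_by_class()].
#' @param comparisons output of [compare_all_classes()].
#' @param records the records the summaries were computed from (for figures;
#'   `NULL` skips figures).
#' @param out_dir output directory.
#' @param metric metric column used for the figures.
#' @return character vector of files written, invisibly.
#' @export
render_report <- function(summaries, comparisons, out_dir, records = NULL,
                          metric = "wb_k1_distance") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(file.path(out_dir, "class_summary.tsv"),
             file.path(out_dir, "class_comparisons.tsv"))
  utils::write.table(summaries, files[1], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  utils::write.table(comparisons, files[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  if (!is.null(records) && nrow(records)) {
    dev <- if (capabilities("cairo")) {
      function(f) grDevices::svg(sub("\\.EXT$", ".svg", f), width = 5, height = 4)
    } else {
      function(f) grDevices::pdf(sub("\\.EXT$", ".pdf", f), width = 5, height = 4)
    }
    ext <- if (capabilities("cairo")) "svg" else "pdf"
    for (cl in sort(unique(records$ligand_class))) {
      v <- records[[metric]][records$ligand_class == cl]
      v <- v[!is.na(v)]
      if (length(v) < 2) next
      f <- file.path(out_dir, paste0("class_", cl, ".EXT"))
      dev(f)
      graphics::layout(matrix(1:2, 2), heights = c(3, 1))
      graphics::par(mar = c(0.5, 4, 2, 1))
      dd <- stats::density(v, bw = "nrd")
      graphics::plot(dd, main = paste0(cl, " (n=", length(v), ")"),
                     xlab = "", xaxt = "n")
      graphics::rug(v)
      graphics::par(mar = c(4, 4, 0.5, 1))
      graphics::boxplot(v, horizontal = TRUE, xlab = metric,
                        ylim = range(dd$x))
      grDevices::dev.off()
      files <- c(files, sub("\\.EXT$", paste0(".", ext), f))
    }
  }
  invisible(files)
}
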