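#' Stratify metabolite pairs by pathway distance
#'
#' Joins a correlation result with a pathway distance matrix into a long
#' table: one row per applicable metabolite pair (finite or infinite
#' distance; pairs the pathway model does not cover are excluded), carrying
#' the partial and Pearson correlations, their p-values, significance flags
#' at the adjusted level, the distance stratum and the metabolite classes.
#'
#' @param result a `correlation_result`.
#' @param D distance matrix from [distance_matrix()] over the same panel.
#' @return data frame with columns `met_a`, `met_b`, `class_a`, `class_b`,
#'   `class` (shared class or `"mixed"`), `distance`, `partial`, `pearson`,
#'   `p_partial`, `p_pearson`, `sig_partial`, `sig_pearson`,
#'   `sig_positive`, `sig_negative`.
#' @export
stratify_by_distance <- function(result, D) {
  stopifnot(inherits(result, "correlation_result"))
  ids <- colnames(result$Z)
  if (!all(ids %in% rownames(D))) {
    stop("distance matrix does not cover the full metabolite panel")
  }
  D <- D[ids, ids]
  tab <- edge_table(result)
  tab$distance <- D[cbind(match(tab$met_a, ids), match(tab$met_b, ids))]
  tab <- tab[!is.na(tab$distance), , drop = FALSE]
  cls <- NULL
  if (!is.null(result$annotation)) {
    cls <- stats::setNames(result$annotation$class, result$annotation$id)
  } else {
    cls <- stats::setNames(rep("unknown", length(ids)), ids)
  }
  tab$class_a <- unname(cls[tab$met_a])
  tab$class_b <- unname(cls[tab$met_b])
  tab$class <- ifelse(tab$class_a == tab$class_b, tab$class_a, "mixed")
  tab$sig_positive <- tab$sig_partial & tab$partial > 0
  tab$sig_negative <- tab$sig_partial & tab$partial < 0
  rownames(tab) <- NULL
  tab
}

#' Confusion counts for direct-edge prediction
#'
#' A pair is predicted positive when its partial correlation is significant,
#' and is condition-positive when its pathway distance is exactly one.  By
#' default only significantly *positive* partial correlations count as
#' predictions (significant negatives are treated as negative predictions,
#' since they indicate distance-2 pairs); set `rule = "absolute"` to count
#' any significant partial correlation.
#'
#' @param table output of [stratify_by_distance()].
#' @param rule `"positive"` (default) or `"absolute"`.
#' @return list with `TP`, `FP`, `TN`, `FN` and an `empty_strata` flag set
#'   when the table lacks direct or indirect pairs.
#' @export
classify_edges <- function(table, rule = c("positive", "absolute")) {
  rule <- match.arg(rule)
  pred <- if (rule == "positive") table$sig_positive else table$sig_partial
  direct <- table$distance == 1
  out <- list(
    TP = sum(pred & direct), FP = sum(pred & !direct),
    TN = sum(!pred & !direct), FN = sum(!pred & direct)
  )
  out$empty_strata <- sum(direct) == 0 || sum(!direct) == 0
  out
}

#' Sensitivity, specificity and F1
#'
#' `sens = TP / (TP + FN)`, `spec = TN / (TN + FP)` and their harmonic mean
#' `F1 = 2 * sens * spec / (sens + spec)`.  Rates with a zero denominator
#' are undefined and returned as `NA`, not as zero.
#'
#' @param confusion list with `TP`, `FP`, `TN`, `FN` (from
#'   [classify_edges()]).
#' @return named vector `c(sens, spec, f1)`.
#' @export
sens_spec_f1 <- function(confusion) {
  sens <- if (confusion$TP + confusion$FN > 0) {
    confusion$TP / (confusion$TP + confusion$FN)
  } else NA_real_
  spec <- if (confusion$TN + confusion$FP > 0) {
    confusion$TN / (confusion$TN + confusion$FP)
  } else NA_real_
  f1 <- if (!is.na(sens) && !is.na(spec) && sens + spec > 0) {
    2 * sens * spec / (sens + spec)
  } else NA_real_
  c(sens = sens, spec = spec, f1 = f1)
}

#' Rank-sum test of direct versus indirect partial correlations
#'
#' Two-sided Wilcoxon rank-sum p-value comparing the partial correlations of
#' distance-1 pairs against those of pairs at distance two or more
#' (including infinity).  Returns `NA` when either group is empty.
#'
#' @param table output of [stratify_by_distance()].
#' @export
ranksum_direct_vs_indirect <- function(table) {
  direct <- table$partial[table$distance == 1]
  indirect <- table$partial[table$distance >= 2]
  if (!length(direct) || !length(indirect)) return(NA_real_)
  stats::wilcox.test(direct, indirect, exact = FALSE)$p.value
}

#' Significant-fraction comparison of Pearson versus partial correlations
#'
#' Counts and fractions of significant Pearson and partial correlations in
#' each pathway-distance stratum, the structure underlying a method
#' comparison: Pearson correlations tend to be significant regardless of
#' distance, while partial correlations concentrate on distance one.
#'
#' @param table output of [stratify_by_distance()].
#' @return data frame with one row per stratum: `distance`, `n_pairs`,
#'   `n_sig_pearson`, `frac_sig_pearson`, `n_sig_partial`,
#'   `frac_sig_partial` (fractions are `NA` for empty strata).
#' @export
pearson_vs_partial_summary <- function(table) {
  strata <- sort(unique(table$distance))
  rows <- lapply(strata, function(d) {
    sel <- table$distance == d
    n <- sum(sel)
    data.frame(
      distance = d, n_pairs = n,
      n_sig_pearson = sum(table$sig_pearson[sel]),
      frac_sig_pearson = if (n > 0) mean(table$sig_pearson[sel]) else NA_real_,
      n_sig_partial = sum(table$sig_partial[sel]),
      frac_sig_partial = if (n > 0) mean(table$sig_partial[sel]) else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Full discrimination report of a GGM against a pathway model
#'
#' Convenience wrapper producing, per metabolite class and overall, the
#' confusion counts, sensitivity/specificity/F1 and rank-sum p-value, plus
#' the per-stratum Pearson-versus-partial comparison.
#'
#' @param result a `correlation_result`.
#' @param D pathway distance matrix.
#' @param rule passed to [classify_edges()].
#' @return object of class `evaluation_report`: list with `table` (the long
#'   pair table), `by_class` (data frame of per-class metrics; the row
#'   `"(all)"` pools all applicable pairs) and `strata`.
#' @export
evaluate_against_model <- function(result, D, rule = "positive") {
  tab <- stratify_by_distance(result, D)
  groups <- c("(all)", sort(unique(tab$class[tab$class != "mixed"])))
  rows <- lapply(groups, function(g) {
    sub <- if (g == "(all)") tab else tab[tab$class == g, , drop = FALSE]
    conf <- classify_edges(sub, rule = rule)
    met <- sens_spec_f1(conf)
    data.frame(class = g, n_pairs = nrow(sub),
               TP = conf$TP, FP = conf$FP, TN = conf$TN, FN = conf$FN,
               sens = met[["sens"]], spec = met[["spec"]], f1 = met[["f1"]],
               p_ranksum = ranksum_direct_vs_indirect(sub),
               stringsAsFactors = FALSE)
  })
  structure(
    list(table = tab, by_class = do.call(rbind, rows),
         strata = pearson_vs_partial_summary(tab)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$by_class, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write an evaluation report to delimited text
#'
#' Writes three tab-separated files under `dir`: the pair table, the
#' per-class metrics and the per-stratum summary.
#'
#' @param report an `evaluation_report`.
#' @param dir output directory (created if missing).
#' @export
write_evaluation_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(report$table, file.path(dir, "pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$by_class, file.path(dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$strata, file.path(dir, "strata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
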