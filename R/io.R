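#' Read a concentration table
#'
#' Reads a delimited samples-x-metabolites table (header row of metabolite
#' ids) into a [concentration_ensemble()].  Raw concentrations are
#' natural-log transformed; tables that are already on log scale are taken
#' as-is with `logged = TRUE`.  Missing values and (for raw input)
#' non-positive concentrations are rejected rather than imputed.
#'
#' @param path input file.
#' @param logged are the stored values already log-transformed?
#' @param sep field separator; `NULL` auto-detects comma versus tab.
#' @param classes optional character vector of metabolite classes, or
#'   `"parse"` to infer them from the identifiers via
#'   [parse_metabolite_name()].
#' @return a [concentration_ensemble()].
#' @export
read_concentration_table <- function(path, logged = FALSE, sep = NULL,
                                     classes = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(names(df))) stop("duplicate metabolite ids in header")
  X <- as.matrix(df)
  if (!is.numeric(X)) stop("table body must be numeric")
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop("missing value at row ", bad[1], ", column '", colnames(X)[bad[2]],
         "' (no imputation is performed)")
  }
  if (!logged) {
    if (any(X <= 0)) {
      bad <- which(X <= 0, arr.ind = TRUE)[1, ]
      stop("non-positive raw concentration at row ", bad[1], ", column '",
           colnames(X)[bad[2]], "'; log transform is undefined")
    }
    X <- log(X)
  }
  if (identical(classes, "parse")) {
    classes <- vapply(colnames(X),
                      function(id) parse_metabolite_name(id)$class, "")
  }
  concentration_ensemble(X, classes)
}

#' Write a concentration table
#'
#' One header row of metabolite ids, one row per sample; values are written
#' on the scale requested (`logged = TRUE` keeps the stored log values).
#'
#' @param ensemble a [concentration_ensemble()].
#' @param path output file.
#' @param logged write log-scale (default) or raw concentrations.
#' @param sep field separator.
#' @export
write_concentration_table <- function(ensemble, path, logged = TRUE,
                                      sep = "\t") {
  X <- if (logged) ensemble$X else exp(ensemble$X)
  utils::write.table(X, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Per-metabolite log-normality preference
#'
#' For every metabolite, correlates the ordered raw and ordered
#' log-transformed values against standard normal quantiles (the numerical
#' summary of a QQ-plot) and reports which transform is closer to linear.
#' Metabolites whose concentrations are log-normally distributed prefer the
#' log transform.
#'
#' @param X_raw numeric matrix of raw (positive) concentrations, samples in
#'   rows.
#' @return data frame with columns `id`, `r_raw`, `r_log`, `prefer`
#'   (`"log"`, `"raw"` or `NA` for constant columns, which are flagged).
#' @export
lognormality_check <- function(X_raw) {
  X_raw <- as.matrix(X_raw)
  if (nrow(X_raw) < 10) stop("at least 10 samples are required")
  if (is.null(colnames(X_raw))) colnames(X_raw) <- paste0("V", seq_len(ncol(X_raw)))
  q <- stats::qnorm(stats::ppoints(nrow(X_raw)))
  rows <- lapply(colnames(X_raw), function(id) {
    x <- X_raw[, id]
    if (stats::var(x) == 0) {
      return(data.frame(id = id, r_raw = NA_real_, r_log = NA_real_,
                        prefer = NA_character_, stringsAsFactors = FALSE))
    }
    r_raw <- stats::cor(sort(x), q)
    r_log <- if (all(x > 0)) stats::cor(sort(log(x)), q) else NA_real_
    prefer <- if (is.na(r_log)) "raw" else if (r_log >= r_raw) "log" else "raw"
    data.frame(id = id, r_raw = r_raw, r_log = r_log, prefer = prefer,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write correlation matrices of a result
#'
#' Writes the Pearson, partial and p-value matrices of a
#' `correlation_result` as tab-separated files under `dir`, plus the long
#' edge table.
#'
#' @param result a `correlation_result`.
#' @param dir output directory (created if missing).
#' @export
write_correlation_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wm <- function(M, name) {
    utils::write.table(M, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
  }
  wm(result$P, "pearson.tsv")
  wm(result$Z, "partial.tsv")
  wm(result$p_pearson, "p_pearson.tsv")
  wm(result$p_partial, "p_partial.tsv")
  utils::write.table(edge_table(result), file.path(dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
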