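#' Ranking curves and AUC for a scored decoy table
#'
#' For each selection size n, the n lowest-scoring decoys are selected and
#' the distribution of their structure-difference values (RMSD or s-score)
#' is summarized: a probability distribution over equal-width bins spanning
#' `[0, max difference]` of the *full* decoy set, the cumulative curve, and
#' the area under the cumulative curve (AUC) computed by the trapezoid rule
#' on the difference axis normalized to the largest difference, so
#' AUC is in `[0, 1]` and equals 1 when every selected decoy is identical to
#' the native.  A larger AUC means the score concentrates its selection at
#' small structure differences.
#'
#' @param table Data frame with one row per decoy.
#' @param score_column Name of the score column (lower = better).
#' @param difference_column Name of the structure-difference column
#'   (e.g. `"rmsd"` or `"s_score"`).
#' @param n_select Integer vector of selection sizes; NA means "all".
#' @param bins Number of difference bins (default 25).
#' @return A `ranking_curves` object: list of per-n curves (`n`, `edges`,
#'   `prob`, `cumulative`, `auc`) plus an `auc` summary data frame.
#' @export
ranking_curves <- function(table, score_column, difference_column = "rmsd",
                           n_select = c(25L, 100L, NA), bins = 25L) {
  stopifnot(is.data.frame(table), nrow(table) >= 1L,
            score_column %in% names(table),
            difference_column %in% names(table))
  score <- table[[score_column]]
  diffv <- table[[difference_column]]
  stopifnot(all(is.finite(score)), all(is.finite(diffv)), all(diffv >= 0))
  dmax <- max(diffv)
  curves <- lapply(n_select, function(n) {
    if (is.na(n)) n <- nrow(table)
    if (n < 1L || n > nrow(table))
      stop("selection size out of range: ", n)
    sel <- diffv[order(score)[seq_len(n)]]
    if (dmax == 0) {
      # all decoys identical to the native: cumulative is 1 everywhere
      return(list(n = n, edges = c(0, 1), prob = 1,
                  cumulative = c(1, 1), auc = 1))
    }
    edges <- seq(0, dmax, length.out = bins + 1L)
    cdf <- vapply(edges, function(e) mean(sel <= e), numeric(1))
    prob <- diff(c(0, cdf[-1L]))
    prob[1L] <- cdf[2L]          # mass at exactly zero goes to the first bin
    x <- edges / dmax
    auc <- sum(diff(x) * (cdf[-1L] + cdf[-length(cdf)]) / 2)
    list(n = n, edges = edges, prob = prob, cumulative = cdf, auc = auc)
  })
  auc <- data.frame(
    score = score_column, difference = difference_column,
    n = vapply(curves, function(cv) cv$n, numeric(1)),
    auc = vapply(curves, function(cv) cv$auc, numeric(1)))
  structure(list(curves = curves, auc = auc,
                 score_column = score_column,
                 difference_column = difference_column),
            class = "ranking_curves")
}

#' @export
print.ranking_curves <- function(x, ...) {
  cat(sprintf("ranking_curves (%s vs %s):\n", x$score_column,
              x$difference_column))
  print(x$auc, row.names = FALSE)
  invisible(x)
}

#' Correlation between a score and a structure-difference measure
#'
#' @param table Data frame with one row per decoy.
#' @param score_column,difference_column Column names.
#' @param method `"pearson"` (default, the linear correlation reported in
#'   this field) or `"spearman"`.
#' @return Correlation coefficient.
#' @export
score_difference_correlation <- function(table, score_column,
                                         difference_column = "rmsd",
                                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(nrow(table) >= 3L)
  s <- table[[score_column]]
  d <- table[[difference_column]]
  if (stats::sd(s) == 0 || stats::sd(d) == 0)
    stop("zero-variance column; correlation undefined")
  stats::cor(s, d, method = method)
}

#' Write / read a score table as TSV with commented header metadata
#'
#' @param table Data frame of per-decoy scores.
#' @param path File path.
#' @param meta Named list written as `# key: value` header lines.
#' @return `write_score_table` invisibly returns `path`;
#'   `read_score_table` returns the data frame with a `"meta"` attribute.
#' @export
write_score_table <- function(table, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", lines[h])
    k <- sub(":.*$", "", kv)
    meta[[trimws(k)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  tab <- utils::read.table(text = lines[setdiff(seq_along(lines), hdr)],
                           sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  attr(tab, "meta") <- meta
  tab
}
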