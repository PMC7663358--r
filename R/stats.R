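# Differential statistics for two-group abundance tables and concordance
# analysis (correlation, clustering) of log fold-change profiles across
# exposure conditions.

#' Construct a two-group sample table
#'
#' @param values numeric matrix, features x samples, raw (non-negative)
#'   abundances; \code{NA} marks a missing measurement.
#' @param group named character vector mapping sample id to \code{"control"}
#'   or \code{"treated"}; names must match \code{colnames(values)}.
#' @return object of class \code{sample_table}.
#' @export
sample_table <- function(values, group) {
  values <- as.matrix(values)
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      is.null(colnames(values)))
    stop("values must have feature rownames and sample colnames")
  if (!setequal(names(group), colnames(values)))
    stop("group names must match sample ids")
  group <- group[colnames(values)]
  if (!all(group %in% c("control", "treated")))
    stop("group labels must be 'control' or 'treated'")
  if (any(values < 0, na.rm = TRUE))
    stop("raw abundances must be non-negative")
  structure(list(values = values, group = group,
                 log_transformed = FALSE, log_base = NA_character_),
            class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat("sample_table:", nrow(x$values), "features x", ncol(x$values),
      "samples (", sum(x$group == "control"), "control /",
      sum(x$group == "treated"), "treated );",
      if (x$log_transformed) paste0("log-", x$log_base) else "raw", "scale\n")
  invisible(x)
}

#' Impute missing values and log-transform a sample table
#'
#' Missing entries of each feature are replaced by that feature's minimum
#' observed value (a conservative stand-in for measurements below the
#' detection limit), then all values are log-transformed. Features with no
#' observed value at all are dropped with a warning (or raise an error when
#' \code{drop_all_missing = FALSE}).
#'
#' @param table a \code{sample_table} on the raw scale.
#' @param log_base \code{"e"} (natural log; conventional for metabolite fold
#'   changes) or \code{"2"} (conventional for gene expression).
#' @param drop_all_missing drop all-missing features instead of erroring.
#' @return a \code{sample_table} on the log scale.
#' @export
preprocess <- function(table, log_base = c("e", "2"),
                       drop_all_missing = TRUE) {
  stopifnot(inherits(table, "sample_table"))
  if (table$log_transformed) stop("table is already log-transformed")
  log_base <- match.arg(log_base)
  v <- table$values
  n_obs <- rowSums(!is.na(v))
  if (any(n_obs == 0)) {
    bad <- rownames(v)[n_obs == 0]
    if (!drop_all_missing)
      stop("feature(s) with no observed values: ", paste(bad, collapse = ", "))
    warning("dropping all-missing feature(s): ", paste(bad, collapse = ", "))
    v <- v[n_obs > 0, , drop = FALSE]
  }
  for (i in seq_len(nrow(v))) {
    miss <- is.na(v[i, ])
    if (any(miss)) v[i, miss] <- min(v[i, !miss])
  }
  if (any(v <= 0))
    stop("non-positive abundances cannot be log-transformed")
  v <- if (log_base == "e") log(v) else log2(v)
  out <- table
  out$values <- v
  out$log_transformed <- TRUE
  out$log_base <- log_base
  out
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. The degenerate case where both groups have zero
#' variance returns \code{t = 0, p = 1} when the means agree and errors
#' otherwise (the difference would be infinitely significant).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
welch_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("welch_test requires at least 2 observations per group")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop("zero variance in both groups with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false discovery rate adjustment with enforced monotonicity, capped
#' at 1; input order is preserved.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-feature differential statistics for a two-group table
#'
#' For each feature: log fold change (treated mean minus control mean on the
#' log scale), Welch t statistic, two-sided p-value, and BH q-value across
#' the full feature list. Features with \code{q < q_threshold} are flagged
#' significant (the conventional screen is q < 0.1).
#'
#' @param table a log-transformed \code{sample_table} (see [preprocess()]).
#' @param q_threshold FDR significance threshold.
#' @return data.frame with columns \code{feature}, \code{log_fc}, \code{t},
#'   \code{p}, \code{q}, \code{significant}; attribute \code{log_base} records
#'   the fold-change scale.
#' @export
differential <- function(table, q_threshold = 0.1) {
  stopifnot(inherits(table, "sample_table"))
  if (!table$log_transformed)
    stop("differential() expects a log-transformed table; run preprocess()")
  v <- table$values
  ctrl <- table$group == "control"
  trt <- table$group == "treated"
  if (sum(ctrl) < 2 || sum(trt) < 2)
    stop("need at least 2 samples per group")
  if (nrow(v) == 0) {
    out <- data.frame(feature = character(), log_fc = numeric(),
                      t = numeric(), p = numeric(), q = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
    attr(out, "log_base") <- table$log_base
    return(out)
  }
  res <- lapply(seq_len(nrow(v)), function(i) {
    w <- welch_test(v[i, trt], v[i, ctrl])
    c(log_fc = mean(v[i, trt]) - mean(v[i, ctrl]), t = w$t, p = w$p)
  })
  res <- do.call(rbind, res)
  q <- bh_fdr(res[, "p"])
  out <- data.frame(feature = rownames(v), log_fc = res[, "log_fc"],
                    t = res[, "t"], p = res[, "p"], q = q,
                    significant = q < q_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "log_base") <- table$log_base
  out
}

#' Pearson correlation between two conditions' fold-change profiles
#'
#' Correlates log fold changes over the features shared by the two results.
#' In \code{"significant"} mode only features significant (q below threshold)
#' in both conditions enter, mirroring the common practice of comparing
#' screened profiles.
#'
#' @param a,b data.frames with columns \code{feature}, \code{log_fc},
#'   \code{q} (as returned by [differential()]).
#' @param mode \code{"all"} or \code{"significant"}.
#' @param q_threshold FDR threshold used in \code{"significant"} mode.
#' @param labels length-2 character vector naming the conditions.
#' @return list of class \code{correlation_report}: \code{pair},
#'   \code{n_common}, \code{r}, \code{mode}.
#' @export
pairwise_correlation <- function(a, b, mode = c("all", "significant"),
                                 q_threshold = 0.1,
                                 labels = c("a", "b")) {
  mode <- match.arg(mode)
  if (mode == "significant") {
    a <- a[a$q < q_threshold, , drop = FALSE]
    b <- b[b$q < q_threshold, , drop = FALSE]
  }
  common <- intersect(a$feature, b$feature)
  if (length(common) < 3)
    stop("fewer than 3 common features for pair (", labels[1], ", ",
         labels[2], ")")
  r <- stats::cor(a$log_fc[match(common, a$feature)],
                  b$log_fc[match(common, b$feature)],
                  method = "pearson")
  structure(list(pair = labels, n_common = length(common), r = r,
                 mode = mode),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("correlation_report: %s vs %s  r = %.4f  (n = %d, mode = %s)\n",
              x$pair[1], x$pair[2], x$r, x$n_common, x$mode))
  invisible(x)
}

#' Hierarchical clustering of condition fold-change profiles
#'
#' Agglomerates conditions with correlation distance (1 - Pearson r between
#' fold-change profiles) and average linkage.
#'
#' @param profiles numeric matrix, conditions x features (complete; inner-join
#'   features upstream), with condition rownames.
#' @return an \code{hclust} object (merge order, heights, labels).
#' @export
hier_cluster <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2)
    stop("hier_cluster requires at least 2 conditions")
  if (anyNA(profiles))
    stop("profiles must be complete across conditions")
  d <- stats::as.dist(1 - stats::cor(t(profiles), method = "pearson"))
  stats::hclust(d, method = "average")
}

#' All-pairs correlation matrix over condition profiles
#'
#' Convenience wrapper applying [pairwise_correlation()] to every pair of a
#' named list of differential results.
#'
#' @param diffs named list of data.frames from [differential()].
#' @inheritParams pairwise_correlation
#' @return symmetric numeric matrix of Pearson r with unit diagonal.
#' @export
correlation_matrix <- function(diffs, mode = c("all", "significant"),
                               q_threshold = 0.1) {
  mode <- match.arg(mode)
  k <- length(diffs)
  if (k < 2) stop("need at least 2 conditions")
  nm <- names(diffs)
  R <- diag(1, k)
  dimnames(R) <- list(nm, nm)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    rep <- pairwise_correlation(diffs[[i]], diffs[[j]], mode = mode,
                                q_threshold = q_threshold,
                                labels = c(nm[i], nm[j]))
    R[i, j] <- R[j, i] <- rep$r
  }
  R
}
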