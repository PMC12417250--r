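# Variable clustering of the thirteen measures into compound exploration
# dimensions: z-scoring, sign inversion, hierarchical clustering on
# 1 - r^2 dissimilarity, kneedle selection of the cluster count, compound
# scores and the outlier screen.

#' Z-score the measure columns of a feature table
#'
#' Each measure column is centered and scaled to unit variance (n - 1
#' denominator). Missing entries are ignored when computing the moments and
#' stay missing.
#'
#' @param table feature table data frame (`participant_id` + measure
#'   columns).
#' @return the standardized table.
#' @export
standardize <- function(table) {
  cols <- setdiff(names(table), "participant_id")
  if (nrow(table) < 3) {
    et_error("standardization needs at least 3 participants",
             "et_data_error")
  }
  for (col in cols) {
    v <- table[[col]]
    s <- sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      et_error(sprintf("column '%s' has zero variance", col),
               "et_data_error")
    }
    table[[col]] <- (v - mean(v, na.rm = TRUE)) / s
  }
  table
}

#' Negate the inverted measures
#'
#' Four measures quantify the absence of exploration; negating their
#' z-scores makes "higher = more exploration" hold for every column.
#'
#' @param table a standardized feature table.
#' @param inverted character vector of measure names to negate
#'   (default [inverted_measures()], 4 members).
#' @return the table with the listed columns negated.
#' @export
apply_inversion <- function(table, inverted = inverted_measures()) {
  unknown <- setdiff(inverted, names(table))
  if (length(unknown)) {
    et_error(paste0("unknown measure(s) in inversion set: ",
                    paste(unknown, collapse = ", ")), "et_config_error")
  }
  for (col in inverted) table[[col]] <- -table[[col]]
  table
}

#' Dissimilarity between measures: 1 - squared Pearson correlation
#'
#' Pairwise-complete Pearson correlations between measure columns; the
#' squared correlation is the similarity, so sign inversions do not affect
#' the clustering.
#'
#' @param table feature table (standardized or not; r is scale-free).
#' @return symmetric measures-by-measures matrix with zero diagonal.
#' @export
variable_dissimilarity <- function(table) {
  m <- as.matrix(table[, setdiff(names(table), "participant_id")])
  cc <- !is.na(m)
  n_complete <- crossprod(cc)
  if (any(n_complete < 3)) {
    et_error("a measure pair has fewer than 3 complete observations",
             "et_data_error")
  }
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  d <- 1 - r^2
  diag(d) <- 0
  d[d < 0] <- 0
  (d + t(d)) / 2
}

#' Agglomerative clustering of the measures
#'
#' Average-linkage hierarchical clustering on the dissimilarity matrix.
#' Average linkage is monotone, so aggregation heights never decrease.
#'
#' @param dissim symmetric non-negative dissimilarity matrix with zero
#'   diagonal (from [variable_dissimilarity()]).
#' @return an object of class `hclust`.
#' @export
hierarchical_cluster <- function(dissim) {
  if (!is.matrix(dissim) || nrow(dissim) != ncol(dissim) ||
      max(abs(dissim - t(dissim))) > 1e-8 || any(dissim < 0)) {
    et_error("dissimilarity must be a symmetric non-negative matrix",
             "et_validation_error")
  }
  hclust(as.dist(dissim), method = "average")
}

#' Kneedle knee detection on aggregation heights
#'
#' The merge-index/height curve of an agglomeration with block structure is
#' convex increasing: cheap within-block merges, then a jump. The curve is
#' normalized to the unit square and the knee is the maximum of the
#' difference curve `y_norm - x_norm` (sensitivity 1, no smoothing; first
#' index on numerically tied maxima), which lands on the first expensive
#' merge. The returned `k` is the number of clusters present just before
#' that merge is performed. On a flat (structureless) curve the tie
#' convention selects the first merge, i.e. no merge is accepted and every
#' variable stays a singleton; knees located exactly at the final merge
#' cannot be distinguished from that degenerate case (a known boundary
#' limitation of knee detection).
#'
#' @param heights aggregation height per merge, non-decreasing, length
#'   `n_vars - 1` with at least 3 merges.
#' @return the selected number of clusters `k`.
#' @export
kneedle_k <- function(heights) {
  m <- length(heights)
  if (m < 3) {
    et_warn("fewer than 3 merges; falling back to k = 1",
            "et_config_warning")
    return(1L)
  }
  x <- (seq_len(m) - 1) / (m - 1)
  rng <- max(heights) - min(heights)
  y <- if (rng > 0) (heights - min(heights)) / rng else rep(0, m)
  diffc <- y - x
  # first index among (numerically) tied maxima
  knee <- which(diffc >= max(diffc) - 1e-12)[1]
  # n_vars = m + 1 clusters before any merge; merges 1..(knee-1) accepted
  as.integer(m - knee + 2L)
}

#' Cut the dendrogram and label the clusters
#'
#' Cuts the tree at `k` clusters. When the partition equals the reference
#' three-dimension membership ([reference_clusters()]) the clusters are
#' labelled `activity`, `shape` and `efficiency`; otherwise generic
#' `cluster_i` labels are used with a warning.
#'
#' @param tree an `hclust` object over the measures.
#' @param k number of clusters.
#' @return named character vector: measure -> cluster label.
#' @export
cut_assignment <- function(tree, k) {
  memb <- cutree(tree, k = k)
  groups <- split(names(memb), memb)
  ref <- reference_clusters()
  canonical <- rep(NA_character_, length(groups))
  if (length(groups) == length(ref)) {
    for (i in seq_along(groups)) {
      hit <- which(vapply(ref, function(r) {
        setequal(r, groups[[i]])
      }, logical(1)))
      if (length(hit) == 1) canonical[i] <- names(ref)[hit]
    }
  }
  if (anyNA(canonical)) {
    if (length(groups) == length(ref)) {
      et_warn("partition does not match the reference three-dimension membership; using generic labels",
              "et_cluster_warning")
    }
    canonical <- paste0("cluster_", seq_along(groups))
  }
  out <- character(length(memb))
  names(out) <- names(memb)
  for (i in seq_along(groups)) out[groups[[i]]] <- canonical[i]
  out
}

#' Fit the full variable-clustering model
#'
#' Standardizes, inverts, computes the dissimilarity, clusters, selects k
#' via kneedle and cuts the tree. By default the cut uses `k_forced = 3`
#' (the three-dimension solution the downstream statistics are defined
#' for) while the kneedle-selected k is reported alongside; in strict mode
#' the two must agree.
#'
#' @param table raw feature table.
#' @param inverted inversion set (default [inverted_measures()]).
#' @param k_forced cluster count used for the cut (`NULL` to use the
#'   kneedle selection).
#' @param strict error if kneedle disagrees with `k_forced`.
#' @return an object of class `cluster_model`: list with `tree`,
#'   `heights`, `k_kneedle`, `k`, `assignment`, `inverted`, and the
#'   standardized+inverted `table_z`.
#' @export
fit_cluster_model <- function(table, inverted = inverted_measures(),
                              k_forced = 3, strict = FALSE) {
  z <- standardize(table)
  zi <- apply_inversion(z, inverted)
  d <- variable_dissimilarity(zi)
  tree <- hierarchical_cluster(d)
  k_kneedle <- kneedle_k(tree$height)
  k <- if (is.null(k_forced)) k_kneedle else as.integer(k_forced)
  if (strict && !is.null(k_forced) && k_kneedle != k_forced) {
    et_error(sprintf("kneedle selected k = %d but k_forced = %d",
                     k_kneedle, k_forced), "et_cluster_error")
  }
  assignment <- cut_assignment(tree, k)
  structure(
    list(tree = tree, heights = tree$height, k_kneedle = k_kneedle,
         k = k, assignment = assignment, inverted = inverted,
         table_z = zi),
    class = "cluster_model")
}

#' @exportS3Method base::print
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model: k = %d (kneedle %d), %d measures>\n",
              x$k, x$k_kneedle, length(x$assignment)))
  for (lab in unique(x$assignment)) {
    cat(sprintf("  %s: %s\n", lab,
                paste(names(x$assignment)[x$assignment == lab],
                      collapse = ", ")))
  }
  invisible(x)
}

#' Compound exploration scores
#'
#' Per participant, each compound is the arithmetic mean of its member
#' z-scored (sign-aligned) columns. Missing members are skipped; a
#' participant is flagged when fewer than half of a compound's members are
#' available.
#'
#' @param table_z standardized and inverted feature table.
#' @param assignment named vector measure -> cluster label (from
#'   [cut_assignment()] or a `cluster_model`).
#' @return data frame `participant_id` + one column per cluster label, with
#'   attribute `flagged` listing participants with sparse compounds.
#' @export
compound_scores <- function(table_z, assignment) {
  if (inherits(table_z, "cluster_model")) {
    assignment <- table_z$assignment
    table_z <- table_z$table_z
  }
  labs <- unique(assignment)
  out <- data.frame(participant_id = table_z$participant_id,
                    stringsAsFactors = FALSE)
  flagged <- character(0)
  for (lab in labs) {
    members <- names(assignment)[assignment == lab]
    m <- as.matrix(table_z[, members, drop = FALSE])
    avail <- rowSums(!is.na(m))
    flagged <- union(flagged,
                     out$participant_id[avail < length(members) / 2])
    out[[lab]] <- rowMeans(m, na.rm = TRUE)
    out[[lab]][avail == 0] <- NA_real_
  }
  attr(out, "flagged") <- flagged
  out
}

#' Screen compound scores for outliers
#'
#' A participant is excluded (from all compounds) when any compound
#' deviates from that compound's mean by more than `threshold_sd` standard
#' deviations. The screen runs once (no re-iteration).
#'
#' @param scores compound-score data frame from [compound_scores()].
#' @param threshold_sd exclusion threshold in standard deviations
#'   (default 3).
#' @return the scores of the retained participants, with attribute
#'   `excluded`: data frame (`participant_id`, `reason`) naming the
#'   offending compound.
#' @export
outlier_screen <- function(scores, threshold_sd = 3) {
  comp_cols <- setdiff(names(scores), "participant_id")
  bad <- character(0)
  reason <- character(0)
  for (col in comp_cols) {
    v <- scores[[col]]
    mu <- mean(v, na.rm = TRUE)
    s <- sd(v, na.rm = TRUE)
    hit <- which(!is.na(v) & abs(v - mu) > threshold_sd * s)
    new <- setdiff(scores$participant_id[hit], bad)
    bad <- c(bad, new)
    reason <- c(reason, rep(col, length(new)))
  }
  keep <- !(scores$participant_id %in% bad)
  out <- scores[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "flagged") <- attr(scores, "flagged")
  attr(out, "excluded") <- data.frame(participant_id = bad,
                                      reason = reason,
                                      stringsAsFactors = FALSE)
  out
}
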