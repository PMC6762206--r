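#' Soft confusion matrix from pooled test probabilities
#'
#' Mean predicted probability vector per true class, computed on pooled
#' test-set predictions before thresholding. Carries strictly more
#' structure than a thresholded confusion: the off-diagonal mass is the
#' model's learned uncertainty between classes.
#'
#' @param probabilities `[trial x class]` matrix of softmax outputs with
#'   class column names.
#' @param true_labels True class per trial.
#' @return A `soft_confusion`: `[class x class]` matrix (rows = true
#'   class, unit row sums), rows ordered like the columns.
#' @export
soft_confusion <- function(probabilities, true_labels) {
  probabilities <- as.matrix(probabilities)
  classes <- colnames(probabilities)
  if (is.null(classes)) stop("probability matrix needs class column names")
  true_labels <- as.character(true_labels)
  missing <- setdiff(classes, unique(true_labels))
  if (length(missing) > 0) {
    stop("class with zero test trials: ", paste(missing, collapse = ", "))
  }
  rows <- t(vapply(classes, function(cl) {
    colMeans(probabilities[true_labels == cl, , drop = FALSE])
  }, numeric(ncol(probabilities))))
  dimnames(rows) <- list(classes, classes)
  structure(rows, class = c("soft_confusion", "matrix"))
}

#' Ward hierarchical clustering of soft-confusion rows
#'
#' Agglomerative clustering (Ward's method) of the per-class prediction
#' probability vectors, using Euclidean distances between rows. The result
#' is deterministic given the input.
#'
#' @param sc A [soft_confusion()] (or any `[class x feature]` matrix with
#'   row names).
#' @return An `hclust` tree over the classes (`n - 1` merges, non-decreasing
#'   heights).
#' @export
ward_tree <- function(sc) {
  m <- unclass(as.matrix(sc))
  if (nrow(m) < 2) stop("need at least 2 rows to cluster")
  if (anyNA(m)) stop("NaN/NA features cannot be clustered")
  stats::hclust(stats::dist(m), method = "ward.D2")
}

#' Cluster count as a function of cutoff distance
#'
#' For a cutoff between merge `k` and merge `k + 1` there are `n - k`
#' clusters; the curve is stepwise non-increasing in the cutoff.
#'
#' @param tree An [ward_tree()] / `hclust` object.
#' @return Data frame with `cutoff` (0 and each merge height) and
#'   `n_clusters` (count holding from that cutoff up to the next).
#' @export
cluster_count_curve <- function(tree) {
  h <- tree$height
  n <- length(h) + 1L
  data.frame(cutoff = c(0, h), n_clusters = c(n, n - seq_along(h)))
}

#' Top-level partition at the largest merge-height gap
#'
#' Reproducible replacement for the by-eye dendrogram threshold: the cutoff
#' is placed in the largest gap between consecutive merge heights (the point
#' where the cluster count jumps fastest as the cutoff shrinks).
#'
#' @param tree An [ward_tree()] / `hclust` object.
#' @return Integer cluster membership vector named by leaf labels.
#' @export
cut_top_level <- function(tree) {
  h <- sort(tree$height)
  n <- length(h) + 1L
  if (n == 2) return(stats::cutree(tree, k = 2))
  gaps <- diff(h)
  k <- n - which.max(gaps)
  stats::cutree(tree, k = k)
}

#' Pairwise distances between syllables in one articulatory grouping
#'
#' Euclidean distances between the binary feature vectors of a grouping;
#' two syllables in different categories of a one-hot grouping sit at
#' distance `sqrt(2)`, same-category pairs at 0. Syllables on which the
#' grouping is undefined are excluded.
#'
#' @param inventory A [make_inventory()].
#' @param grouping One of `"articulator"`, `"location"`, `"degree"`,
#'   `"vowel"`.
#' @return Symmetric distance matrix with syllable dimnames and zero
#'   diagonal.
#' @export
articulatory_distances <- function(inventory,
                                   grouping = c("articulator", "location",
                                                "degree", "vowel")) {
  grouping <- match.arg(grouping)
  m <- feature_matrix(inventory, grouping, drop_undefined = TRUE)
  if (nrow(m) == 0) stop("grouping has no defined syllables")
  as.matrix(stats::dist(m))
}

#' Pairwise distances between classes in prediction space
#'
#' @param sc A [soft_confusion()].
#' @return Symmetric Euclidean distance matrix between its rows.
#' @export
prediction_distances <- function(sc) {
  as.matrix(stats::dist(unclass(as.matrix(sc))))
}

#' Correlate prediction-space and articulatory-feature distances
#'
#' For every syllable, the Pearson (or Spearman) correlation between its
#' row of prediction-space pairwise distances and its row of
#' feature-space distances, over the syllables common to both matrices
#' (self-pairs excluded). Syllables with a constant distance row are
#' flagged (correlation undefined).
#'
#' @param pred_dists,artic_dists Symmetric distance matrices with syllable
#'   dimnames; only their common syllables are used.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `per_cv` (named correlations, `NA` where undefined),
#'   `median`, `interval` (central 50% interval), `n_undefined`.
#' @export
prediction_articulatory_correlation <- function(pred_dists, artic_dists,
                                                method = c("pearson",
                                                           "spearman")) {
  method <- match.arg(method)
  common <- intersect(rownames(pred_dists), rownames(artic_dists))
  if (length(common) < 3) stop("need at least 3 common syllables")
  p <- pred_dists[common, common]
  a <- artic_dists[common, common]
  per_cv <- vapply(seq_along(common), function(i) {
    x <- p[i, -i]; y <- a[i, -i]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = method)
  }, numeric(1))
  names(per_cv) <- common
  ok <- per_cv[!is.na(per_cv)]
  list(per_cv = per_cv,
       median = stats::median(ok),
       interval = stats::quantile(ok, c(0.25, 0.75), names = FALSE),
       n_undefined = sum(is.na(per_cv)))
}

#' Distance-correlation summary across articulatory groupings
#'
#' Convenience wrapper running [prediction_articulatory_correlation()] for
#' each grouping against one soft confusion.
#'
#' @param sc A [soft_confusion()].
#' @param inventory A [make_inventory()].
#' @param groupings Groupings to evaluate.
#' @param method Correlation type.
#' @return Data frame with `grouping`, `median`, `q25`, `q75`, `n`.
#' @export
hierarchy_correlations <- function(sc, inventory,
                                   groupings = c("articulator", "location",
                                                 "degree", "vowel"),
                                   method = "pearson") {
  pd <- prediction_distances(sc)
  rows <- lapply(groupings, function(g) {
    res <- prediction_articulatory_correlation(
      pd, articulatory_distances(inventory, g), method = method)
    data.frame(grouping = g, median = res$median,
               q25 = res$interval[1], q75 = res$interval[2],
               n = sum(!is.na(res$per_cv)))
  })
  do.call(rbind, rows)
}
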