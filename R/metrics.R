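# Foreground-restricted Rand scoring and semantic overlap metrics.
#
# The score is the pair-counting agreement
#   V_alpha = sum_ij p_ij^2 / (alpha * sum_k s_k^2 + (1 - alpha) * sum_k t_k^2)
# where p_ij is the joint probability that a voxel belongs to inferred object
# i and ground-truth object j, s_i / t_j the marginals. alpha -> 0 gives the
# split score (precision on voxel pairs), alpha -> 1 the merge score (recall).
# "Foreground-restricted" drops voxels whose ground-truth id is 0 before
# counting, the ISBI-challenge convention.

#' Joint label-overlap contingency table
#'
#' Builds the joint probability table `p_ij` between a predicted and a
#' ground-truth label volume. In `"semantic"` mode both volumes are first
#' collapsed to binary (`id > 0`). With `foreground_restricted = TRUE`
#' (default) voxels whose ground-truth id is 0 are excluded from counting.
#'
#' @param gt,pred [label_volume()]s (or bare integer arrays) of equal shape;
#'   rows of the table are predicted objects, columns ground-truth objects.
#' @param mode `"instance"` or `"semantic"`.
#' @param foreground_restricted drop gt-background voxels before counting.
#' @return A `contingency_table`: list with the joint matrix `p` (rows named
#'   by predicted id, columns by ground-truth id), marginals `s` (predicted)
#'   and `t` (ground truth), and `n_eval`, the number of voxels counted.
#' @export
contingency <- function(gt, pred, mode = c("instance", "semantic"),
                        foreground_restricted = TRUE) {
  mode <- match.arg(mode)
  g <- as.vector(as_array3d(gt))
  p <- as.vector(as_array3d(pred))
  if (length(g) != length(p)) stop("gt and pred must have the same shape")
  if (mode == "semantic") {
    g <- as.integer(g > 0)
    p <- as.integer(p > 0)
  }
  if (foreground_restricted) {
    keep <- g != 0
    if (!any(keep)) {
      stop("empty table: ground truth is all background under foreground restriction")
    }
    g <- g[keep]
    p <- p[keep]
  }
  n <- length(g)
  tab <- table(pred = factor(p), gt = factor(g))
  pm <- unclass(tab) / n
  structure(list(p = pm, s = rowSums(pm), t = colSums(pm), n_eval = n),
            class = "contingency_table")
}

#' Rand score with split/merge limits
#'
#' Evaluates `V_alpha = sum(p^2) / (alpha*sum(s^2) + (1-alpha)*sum(t^2))` on a
#' contingency table, together with its two limits: the split score
#' (`alpha -> 0`, pair precision) and the merge score (`alpha -> 1`, pair
#' recall). Equals 1 exactly when the segmentation matches the ground truth up
#' to a relabeling.
#'
#' @param table a `contingency_table` from [contingency()].
#' @param alpha weight in `[0, 1]`; the conventional F-score uses 0.5.
#' @return A `rand_result`: list with `alpha`, `score`, `split`, `merge`.
#' @export
rand_score <- function(table, alpha = 0.5) {
  if (!inherits(table, "contingency_table")) stop("need a contingency_table")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (table$n_eval == 0) stop("undefined score: contingency table is empty")
  sp2 <- sum(table$p^2)
  ss2 <- sum(table$s^2)
  st2 <- sum(table$t^2)
  structure(list(alpha = alpha,
                 score = sp2 / (alpha * ss2 + (1 - alpha) * st2),
                 split = sp2 / st2,
                 merge = sp2 / ss2),
            class = "rand_result")
}

#' @export
print.rand_result <- function(x, ...) {
  cat(sprintf("Rand score (alpha=%.2f): %.4f  [split %.4f, merge %.4f]\n",
              x$alpha, x$score, x$split, x$merge))
  invisible(x)
}

#' Semantic overlap scores (Jaccard, Dice, conformity)
#'
#' @param gt_mask,pred_mask [binary_volume()]s (or logical arrays) of equal
#'   shape; `gt_mask` must be nonempty.
#' @return named numeric vector `c(jaccard, dice, conformity)`; conformity is
#'   `(3*dice - 2)/dice`, reported as `-Inf` when dice is 0.
#' @export
semantic_overlap <- function(gt_mask, pred_mask) {
  a <- as.vector(as_array3d(gt_mask)) > 0
  b <- as.vector(as_array3d(pred_mask)) > 0
  if (length(a) != length(b)) stop("masks must have the same shape")
  if (!any(a) && !any(b)) stop("undefined overlap: both masks are empty")
  inter <- sum(a & b)
  jaccard <- inter / sum(a | b)
  dice <- 2 * inter / (sum(a) + sum(b))
  conformity <- if (dice == 0) -Inf else (3 * dice - 2) / dice
  c(jaccard = jaccard, dice = dice, conformity = conformity)
}

#' One-call segmentation evaluation report
#'
#' Convenience wrapper combining [contingency()], [rand_score()] and (for
#' semantic mode or binary-collapsible volumes) [semantic_overlap()].
#'
#' @inheritParams contingency
#' @param alpha Rand F-score weight.
#' @return a one-row [tibble::tibble()] with `score`, `split`, `merge`,
#'   `jaccard`, `dice`, `conformity`, `n_eval`.
#' @export
evaluate_segmentation <- function(gt, pred, mode = c("instance", "semantic"),
                                  alpha = 0.5, foreground_restricted = TRUE) {
  mode <- match.arg(mode)
  tab <- contingency(gt, pred, mode, foreground_restricted)
  r <- rand_score(tab, alpha)
  ov <- semantic_overlap(as_array3d(gt) > 0, as_array3d(pred) > 0)
  tibble::tibble(mode = mode, score = r$score, split = r$split,
                 merge = r$merge, jaccard = ov[["jaccard"]],
                 dice = ov[["dice"]], conformity = ov[["conformity"]],
                 n_eval = tab$n_eval)
}
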