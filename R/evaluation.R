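# Per-protein evaluation: ROC and recall-precision curves from a ranked
# residue list against catalytic/noncatalytic labels, plus vertical curve
# averaging across a dataset.

new_curve <- function(x, y, auc, type) {
  structure(list(points = data.frame(x = x, y = y), auc = auc, type = type),
            class = "catres_curve")
}

#' @export
print.catres_curve <- function(x, ...) {
  cat("<catres_curve> ", x$type, ", ", nrow(x$points), " points, AUC = ",
      format(x$auc, digits = 6), "\n", sep = "")
  invisible(x)
}

# threshold sweep shared by both curve types: descending distinct scores,
# ties processed together; returns cumulative TP / FP per threshold
sweep_counts <- function(score, label) {
  stopifnot(length(score) == length(label))
  label <- as.logical(label)
  thr <- sort(unique(score), decreasing = TRUE)
  grp <- factor(match(score, thr), levels = seq_along(thr))
  tp <- cumsum(as.numeric(tapply(label, grp, sum, default = 0)))
  n <- cumsum(as.numeric(tapply(rep(1L, length(score)), grp, sum, default = 0)))
  list(tp = tp, fp = n - tp, P = sum(label), Neg = sum(!label))
}

#' ROC curve of a labeled ranking
#'
#' Standard threshold sweep over the distinct score values in descending
#' order, with tied scores processed together; the curve starts at (0,0)
#' and ends at (1,1) and the AUC is computed by the trapezoid rule (which
#' makes it equal to the Mann-Whitney U statistic of the ranking, with
#' ties counted half).
#'
#' @param score numeric prediction scores (higher = more likely catalytic).
#' @param label logical (or 0/1) catalytic labels.
#' @return a `catres_curve` with `points` (FPR, TPR) and `auc`.
#' @export
roc_curve <- function(score, label) {
  label <- as.logical(label)
  if (!any(label) || all(label))
    stop("ROC needs both catalytic and noncatalytic residues")
  sw <- sweep_counts(score, label)
  fpr <- c(0, sw$fp / sw$Neg)
  tpr <- c(0, sw$tp / sw$P)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  new_curve(fpr, tpr, auc, "roc")
}

#' Recall-precision curve of a labeled ranking
#'
#' Recall and precision over the same descending threshold sweep as
#' [roc_curve()]. The curve is anchored at recall 0 with the precision of
#' the top-ranked prediction group. AUC here is the trapezoid area under
#' precision as a function of recall.
#'
#' @inheritParams roc_curve
#' @return a `catres_curve` with `points` (recall, precision) and `auc`.
#' @export
recall_precision_curve <- function(score, label) {
  label <- as.logical(label)
  if (!any(label)) stop("recall-precision curve needs at least one positive")
  sw <- sweep_counts(score, label)
  recall <- sw$tp / sw$P
  precision <- sw$tp / (sw$tp + sw$fp)
  recall <- c(0, recall)
  precision <- c(precision[1], precision)
  auc <- sum(diff(recall) * (head(precision, -1) + precision[-1]) / 2)
  new_curve(recall, precision, auc, "rp")
}

#' Average curves across proteins
#'
#' Vertical averaging: each per-protein curve is evaluated at a fixed grid
#' of `grid_n` evenly spaced x values in \[0, 1\] by step (right-continuous)
#' interpolation -- y at grid value g is the y of the last sweep point with
#' x <= g -- and the y values are averaged per grid point. The dataset AUC
#' is the trapezoid area of the averaged curve.
#'
#' @param curves list of `catres_curve` objects (same type).
#' @param grid_n number of grid points (default 101).
#' @return a `catres_curve` of the same type on the x grid, with the
#'   averaged `auc`.
#' @export
average_curves <- function(curves, grid_n = 101) {
  if (length(curves) == 0) stop("no curves to average")
  stopifnot(all(vapply(curves, inherits, TRUE, "catres_curve")))
  type <- curves[[1]]$type
  grid <- seq(0, 1, length.out = grid_n)
  ys <- vapply(curves, function(cv) {
    x <- cv$points$x; y <- cv$points$y
    pos <- findInterval(grid + 1e-12, x)
    ifelse(pos == 0, y[1], y[pmax(pos, 1)])
  }, numeric(grid_n))
  ym <- if (is.matrix(ys)) rowMeans(ys) else ys
  auc <- sum(diff(grid) * (head(ym, -1) + ym[-1]) / 2)
  new_curve(grid, ym, auc, type)
}

#' Label residues of a prediction against a site annotation table
#'
#' Matches the annotation rows for one structure id against the (chain,
#' residue number, insertion code) identifiers of a ranked score table.
#'
#' @param scores a ranked `catres_scores` data frame.
#' @param annotations data frame from [read_site_annotations()].
#' @param structure_id id to select in the annotation table.
#' @return logical vector: TRUE where the residue is annotated catalytic.
#' @export
residue_labels <- function(scores, annotations, structure_id) {
  ann <- annotations[annotations$structure_id == structure_id, , drop = FALSE]
  key <- paste(scores$chain, scores$resno, scores$icode, sep = "\r")
  akey <- paste(ann$chain, ann$resnum, ann$icode, sep = "\r")
  key %in% akey
}

#' Evaluate a set of predictions against annotations
#'
#' Builds the per-protein ROC and recall-precision curves and their
#' vertical averages. Proteins with no annotated (positive) residue among
#' the ranked list, or with no negatives, are excluded with a warning.
#'
#' @param predictions named list of ranked `catres_scores` data frames;
#'   names are structure ids matching the annotation table.
#' @param annotations data frame from [read_site_annotations()], or a path.
#' @param use_fused use `S_prime` when available (default TRUE).
#' @return list with `per_protein` (data frame of ids and AUCs), `roc`
#'   and `rp` (averaged `catres_curve`s), `auc_roc` (dataset AUCROC).
#' @export
evaluate_predictions <- function(predictions, annotations, use_fused = TRUE) {
  if (is.character(annotations)) annotations <- read_site_annotations(annotations)
  rocs <- list(); rps <- list(); ids <- character(0); aucs <- numeric(0)
  for (id in names(predictions)) {
    sc <- predictions[[id]]
    lab <- residue_labels(sc, annotations, id)
    if (!any(lab) || all(lab)) {
      warning("structure ", id, " lacks both label classes; excluded")
      next
    }
    key <- if (use_fused && "S_prime" %in% names(sc) && !all(is.na(sc$S_prime)))
      sc$S_prime else sc$S
    rocs[[length(rocs) + 1]] <- roc_curve(key, lab)
    rps[[length(rps) + 1]] <- recall_precision_curve(key, lab)
    ids <- c(ids, id)
    aucs <- c(aucs, rocs[[length(rocs)]]$auc)
  }
  if (length(rocs) == 0) stop("no evaluable predictions")
  avg_roc <- average_curves(rocs)
  avg_rp <- average_curves(rps)
  list(per_protein = data.frame(structure_id = ids, auc_roc = aucs),
       roc = avg_roc, rp = avg_rp, auc_roc = avg_roc$auc)
}
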