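# enumerate all permutations of 1..k (k <= 8)
.permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in .permutations(k - 1L))
    for (pos in seq_len(k))
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  out
}

#' Match unsupervised clusters to true classes
#'
#' Finds the cluster-to-class assignment maximizing total agreement, by
#' exhaustive search over permutations (k <= 8; exact, unlike greedy
#' matching). For two clusters this includes the global sign flip. When
#' the numbers of clusters and classes differ, the best injective
#' assignment of the smaller set into the larger is used (logged).
#'
#' @param pred predicted cluster labels (any discrete coding).
#' @param truth true class labels, same length.
#' @return list with \code{map} (named vector: cluster level -> class
#'   level), \code{mapped} (pred recoded into class levels, factor),
#'   and \code{agreement} (fraction of matching labels).
#' @export
matchClusters <- function(pred, truth) {
  stopIfNot(length(pred) == length(truth), "length mismatch")
  pl <- sort(unique(as.character(pred)))
  tl <- sort(unique(as.character(truth)))
  stopIfNot(max(length(pl), length(tl)) <= 8,
            "exhaustive matching supports at most 8 classes")
  if (length(pl) != length(tl))
    message("cluster count (", length(pl), ") != class count (", length(tl),
            "); using best injective assignment")
  tab <- table(factor(as.character(pred), pl), factor(as.character(truth), tl))
  small <- min(length(pl), length(tl)); big <- max(length(pl), length(tl))
  bestAgree <- -1; bestMap <- NULL
  for (p in .permutations(big)) {
    sel <- p[seq_len(small)]
    a <- if (length(pl) <= length(tl))
      sum(tab[cbind(seq_len(small), sel)])
    else sum(tab[cbind(sel, seq_len(small))])
    if (a > bestAgree) { bestAgree <- a; bestMap <- sel }
  }
  map <- if (length(pl) <= length(tl)) {
    stats::setNames(tl[bestMap], pl)
  } else {
    m <- rep(NA_character_, length(pl)); m[bestMap] <- tl
    # unmatched clusters keep their own id prefixed, never silently merged
    m[is.na(m)] <- paste0("unmatched.", pl[is.na(m)])
    stats::setNames(m, pl)
  }
  mapped <- factor(unname(map[as.character(pred)]),
                   levels = unique(c(tl, unname(map))))
  list(map = map, mapped = mapped, agreement = bestAgree / length(pred))
}

#' Confusion matrix of true class vs matched cluster
#'
#' @param truth true class labels.
#' @param pred matched predicted labels (same coding as truth, e.g. the
#'   \code{mapped} element of [matchClusters()]).
#' @param classes optional class name ordering.
#' @return Integer matrix, rows = true class, columns = assigned cluster.
#' @export
clusterConfusion <- function(truth, pred, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(as.character(truth)))
  stopIfNot(all(as.character(truth) %in% classes),
            "truth contains labels outside `classes`")
  predC <- as.character(pred)
  bad <- !(predC %in% classes)
  if (any(bad)) stop("prediction contains unknown label(s): ",
                     paste(unique(predC[bad]), collapse = ", "), call. = FALSE)
  as.matrix(table(factor(as.character(truth), classes),
                  factor(predC, classes)))
}

#' Per-class detection metrics from a confusion matrix
#'
#' One-vs-rest pooling per class c: TP = cm[c,c]; FN = rest of row c;
#' FP = rest of column c; TN = everything else; then
#' sensitivity = TP/(TP+FN), specificity = TN/(FP+TN),
#' accuracy = (TP+TN)/n, reported in percent. Classes with an empty row
#' get NA metrics (undefined, never NaN).
#'
#' @param cm square confusion matrix (rows = truth, columns = prediction,
#'   aligned).
#' @return data.frame: class, TP, FN, FP, TN, sensitivity, specificity,
#'   accuracy, plus a \code{Total} row with the micro (pooled) sensitivity
#'   and the macro (unweighted mean) specificity and accuracy.
#' @export
classMetrics <- function(cm) {
  cm <- as.matrix(cm)
  stopIfNot(nrow(cm) == ncol(cm), "confusion matrix must be square")
  n <- sum(cm)
  stopIfNot(n > 0, "empty confusion matrix")
  cls <- rownames(cm)
  if (is.null(cls)) cls <- as.character(seq_len(nrow(cm)))
  rows <- lapply(seq_len(nrow(cm)), function(i) {
    TP <- cm[i, i]; FN <- sum(cm[i, ]) - TP; FP <- sum(cm[, i]) - TP
    TN <- n - TP - FN - FP
    if (TP + FN == 0)
      return(data.frame(class = cls[i], TP = TP, FN = FN, FP = FP, TN = TN,
                        sensitivity = NA_real_, specificity = NA_real_,
                        accuracy = NA_real_))
    data.frame(class = cls[i], TP = TP, FN = FN, FP = FP, TN = TN,
               sensitivity = 100 * TP / (TP + FN),
               specificity = if (FP + TN == 0) NA_real_
                             else 100 * TN / (FP + TN),
               accuracy = 100 * (TP + TN) / n)
  })
  out <- do.call(rbind, rows)
  meanOrNA <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  total <- data.frame(class = "Total", TP = sum(diag(cm)),
                      FN = n - sum(diag(cm)), FP = n - sum(diag(cm)),
                      TN = NA_integer_,
                      sensitivity = microSensitivity(cm),
                      specificity = meanOrNA(out$specificity),
                      accuracy = meanOrNA(out$accuracy))
  rbind(out, total)
}

#' Micro (pooled) sensitivity
#'
#' 100 x trace / total of an aligned confusion matrix: the fraction of all
#' beats assigned to their matched cluster.
#'
#' @param cm square confusion matrix with clusters matched to classes.
#' @return Percentage in [0, 100].
#' @export
microSensitivity <- function(cm) {
  cm <- as.matrix(cm)
  stopIfNot(sum(cm) > 0, "empty confusion matrix")
  100 * sum(diag(cm)) / sum(cm)
}

#' Packaged reference tables
#'
#' Loaders for the bundled reference record inventory (seven ambulatory records,
#' 1682 beats across the five AAMI classes), the bundled reference IEMMC
#' clustering confusion matrix, and the bundled reference per-class metric table.
#' Numbers are stored verbatim. In the reference confusion-matrix layout
#' the cluster columns are already matched to the classes positionally
#' (the row labels run N,S,V,F,Q while the printed column header runs
#' N,S,F,V,Q — an apparent V/F label swap also visible in the row sums);
#' the loader therefore names the cluster columns c1..c5 and the diagonal
#' is the matched-cluster diagonal.
#'
#' @return \code{referenceBeatInventory}: data.frame of per-record beat counts per
#'   class. \code{referenceConfusion}: 5x5 integer matrix (rows N,S,V,F,Q,
#'   columns matched clusters). \code{referenceMetrics}: data.frame of the
#'   reference per-class sensitivity/specificity/accuracy percentages.
#' @export
referenceBeatInventory <- function() {
  utils::read.csv(system.file("extdata", "reference_beat_inventory.csv",
                              package = "iemmc"), check.names = FALSE)
}

#' @rdname referenceBeatInventory
#' @export
referenceConfusion <- function() {
  df <- utils::read.csv(system.file("extdata", "reference_confusion.csv",
                                    package = "iemmc"))
  m <- as.matrix(df[, -1])
  rownames(m) <- df$class
  m
}

#' @rdname referenceBeatInventory
#' @export
referenceMetrics <- function() {
  utils::read.csv(system.file("extdata", "reference_metrics.csv",
                              package = "iemmc"))
}

#' Seeded K-means baseline
#'
#' Standard Lloyd iterations from seeded random centroids, the
#' conventional clustering baseline the margin-based method is compared
#' against. Empty clusters are re-seeded by restarting with a derived
#' seed (logged).
#'
#' @param X numeric feature matrix.
#' @param k number of clusters.
#' @param seed integer seed; identical seeds give identical partitions.
#' @return Integer cluster labels 1..k.
#' @export
kmeansBaseline <- function(X, k, seed = 1) {
  X <- as.matrix(X)
  stopIfNot(nrow(X) >= k, "need n >= k")
  for (attempt in 0:4) {
    km <- tryCatch(
      withSubSeed(seed + attempt, "kmeans",
                  stats::kmeans(X, centers = min(k, nrow(X)), nstart = 1,
                                iter.max = 100, algorithm = "Lloyd")),
      warning = function(w) NULL, error = function(e) NULL)
    if (!is.null(km) && length(unique(km$cluster)) == k)
      return(as.integer(km$cluster))
    message("kmeans produced an empty cluster; re-seeding centroid(s)")
  }
  km <- withSubSeed(seed, "kmeans-final",
                    stats::kmeans(X, centers = k, nstart = 10, iter.max = 100))
  as.integer(km$cluster)
}
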