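#' IEMMC configuration
#'
#' Parameters of the immune-evolutionary maximum-margin clustering run.
#' The balance bound defaults to \code{floor(0.2 n)}. The regularization
#' constant C defaults to 1 (candidates 1, 10, 100, 500 are the usual scan
#' set): since the square loss is summed over all n samples, moderate C
#' already weights the data term heavily, and larger values make the
#' kernel machine memorize arbitrary labelings, flattening the refinement
#' descent. Evolutionary sizes follow common clonal-selection practice and
#' are deliberately small — the Lamarckian bias/label refinement does most
#' of the local work, the immune loop supplies global search.
#'
#' @param C regularization constant (> 0).
#' @param l class-balance bound; NULL (default) means \code{floor(0.2 n)}.
#' @param sigma RBF bandwidth; NULL selects a widened median heuristic
#'   (median pairwise kernel value ~0.9) so the refinement descent sees
#'   cluster-scale structure.
#' @param kernel \code{"rbf_printed"}, \code{"rbf_squared"} or
#'   \code{"linear"}; see [kernelMatrix()].
#' @param popSize population size (>= 2).
#' @param nClone number of top antibodies cloned per generation.
#' @param nMut number of antibodies hypermutated per generation.
#' @param editFrac fraction of the non-memory population replaced by fresh
#'   random antibodies each generation (receptor editing), in [0, 1).
#' @param ts suppression threshold: minimum pairwise Hamming distance
#'   (under canonical sign) between initial antibodies; NULL means n/10.
#' @param fMax largest number of pair flips in hypermutation (lowest
#'   affinity rank); NULL means \code{max(2, ceiling(n/10))}.
#' @param maxGen generation cap.
#' @param stall stop after this many generations without best-objective
#'   improvement.
#' @param init \code{"random"} or \code{"kmeans"} (one antibody seeded
#'   from a centroid-based 2-means split, the rest random).
#' @param seed master seed; all randomness flows from it via named
#'   substreams (init, mutation, editing).
#' @return A validated list of class \code{"IEMMCConfig"}.
#' @export
iemmcConfig <- function(C = 1, l = NULL, sigma = NULL,
                        kernel = c("rbf_printed", "rbf_squared", "linear"),
                        popSize = 20, nClone = 5, nMut = 5, editFrac = 0.2,
                        ts = NULL, fMax = NULL, maxGen = 50, stall = 10,
                        init = c("random", "kmeans"), seed = 1) {
  kernel <- match.arg(kernel); init <- match.arg(init)
  stopIfNot(C > 0, "C must be positive")
  stopIfNot(popSize >= 2, "popSize must be >= 2")
  stopIfNot(editFrac >= 0 && editFrac < 1, "editFrac must be in [0, 1)")
  stopIfNot(nClone >= 1 && nMut >= 1, "nClone and nMut must be >= 1")
  stopIfNot(is.null(l) || l >= 0, "balance bound must be >= 0")
  structure(list(C = C, l = l, sigma = sigma, kernel = kernel,
                 popSize = popSize, nClone = nClone, nMut = nMut,
                 editFrac = editFrac, ts = ts, fMax = fMax,
                 maxGen = maxGen, stall = stall, init = init, seed = seed),
            class = "IEMMCConfig")
}

# canonical sign: first component forced positive
canonicalSign <- function(y) if (y[1] < 0) -y else y

.hamming <- function(a, b) sum(canonicalSign(a) != canonicalSign(b))

# feasible counts of -1 labels under |sum(y)| <= l (parity rounded outward)
.feasibleNegCounts <- function(n, l) {
  leff <- max(l, (n + l) %% 2)
  p <- seq_len(n - 1)
  p[abs(n - 2 * p) <= leff]
}

.randomBalancedY <- function(n, l) {
  p <- sample(.feasibleNegCounts(n, l), 1)
  y <- rep(1, n)
  y[sample.int(n, p)] <- -1
  y
}

.newAntibody <- function(y) list(y = y, J = Inf, F = 0, evaluated = FALSE)

#' Evaluate an antibody: inner solve plus Lamarckian refinement
#'
#' Computes the margin objective of a candidate labeling by the
#' least-squares SVM inner solve, then runs the bias/label refinement on
#' the resulting raw scores; whenever the refined labeling attains a
#' strictly lower objective (re-solved), it replaces the antibody's
#' labeling and the solve/refine cycle repeats until it stops improving
#' (capped). The refinement thus feeds back into the evolutionary state:
#' the immune loop supplies global moves, this local descent finishes them.
#'
#' @param K kernel matrix.
#' @param y labeling in \{-1, +1\} satisfying the balance constraint.
#' @param C regularization constant.
#' @param l balance bound.
#' @param maxRefine cap on solve/refine descent steps.
#' @return list with \code{y} (possibly refined), \code{J}, \code{F} and
#'   the fitted [MMCModel-class] as \code{model}.
#' @export
evaluateAntibody <- function(K, y, C, l, maxRefine = 25) {
  m <- innerSolve(K, y, C)
  out <- list(y = y, J = m@J, F = m@F, model = m, evaluated = TRUE)
  for (it in seq_len(maxRefine)) {
    ref <- tryCatch(refineBiasLabels(m@scores, l), error = function(e) NULL)
    if (is.null(ref) || all(ref$y == out$y)) break
    m2 <- innerSolve(K, ref$y, C)
    if (m2@J >= out$J - 1e-12) break
    out <- list(y = ref$y, J = m2@J, F = m2@F, model = m2, evaluated = TRUE)
    m <- m2
  }
  out
}

#' Initialize the antibody population
#'
#' Seeded random balanced labelings whose pairwise Hamming distance (under
#' canonical sign) exceeds the suppression threshold; optionally one
#' antibody seeded from a 2-means centroid split.
#'
#' @param n number of samples.
#' @param config an [iemmcConfig()].
#' @param X feature matrix, required for \code{init = "kmeans"}.
#' @return list of unevaluated antibodies (fields y, J, F, evaluated).
#' @export
initPopulation <- function(n, config, X = NULL) {
  l <- if (is.null(config$l)) floor(0.2 * n) else config$l
  ts <- if (is.null(config$ts)) n / 10 else config$ts
  pop <- list()
  if (config$init == "kmeans") {
    stopIfNot(!is.null(X), "init = 'kmeans' needs the feature matrix X")
    km <- withSubSeed(config$seed, "init-km",
                      stats::kmeans(X, centers = 2, nstart = 1,
                                    algorithm = "Lloyd", iter.max = 50))
    y <- ifelse(km$cluster == 1, 1, -1)
    y <- withSubSeed(config$seed, "init-km-fix", .rebalance(y, l))
    pop[[1]] <- .newAntibody(y)
  }
  withSubSeed(config$seed, "init", {
    tries <- 0
    while (length(pop) < config$popSize) {
      y <- .randomBalancedY(n, l)
      farEnough <- all(vapply(pop, function(a) .hamming(a$y, y) > ts, logical(1)))
      if (farEnough) pop[[length(pop) + 1]] <- .newAntibody(y)
      tries <- tries + 1
      if (tries > 200 * config$popSize)
        stop("cannot place ", config$popSize, " antibodies at suppression ",
             "threshold ", ts, "; reduce ts", call. = FALSE)
    }
  })
  pop
}

# flip random members of the larger class until |sum(y)| <= l
.rebalance <- function(y, l) {
  while (abs(sum(y)) > l) {
    big <- if (sum(y) > 0) which(y > 0) else which(y < 0)
    i <- big[sample.int(length(big), 1)]
    y[i] <- -y[i]
  }
  y
}

#' Clonal selection
#'
#' Clones the highest-affinity antibodies: the best of the \code{nc}
#' selected gets \code{nc} copies, the next \code{nc - 1}, down to one —
#' clone counts proportional to affinity rank. Clones are exact copies.
#'
#' @param pop list of evaluated antibodies.
#' @param nc number of antibodies to clone (<= length(pop)).
#' @return list of clone antibodies.
#' @export
cloneSelect <- function(pop, nc) {
  stopIfNot(nc <= length(pop), "nc exceeds population size")
  Fs <- vapply(pop, `[[`, numeric(1), "F")
  sel <- order(Fs, decreasing = TRUE)[seq_len(nc)]
  clones <- list()
  for (r in seq_along(sel)) {
    copies <- nc - r + 1
    for (cpy in seq_len(copies)) clones[[length(clones) + 1]] <- pop[[sel[r]]]
  }
  clones
}

# pure pair-flip mutation: flips `f` opposite-signed pairs, conserving sum(y)
mutateLabels <- function(y, f) {
  pos <- which(y > 0); neg <- which(y < 0)
  if (!length(pos) || !length(neg))
    stop("labeling has a single class; no opposite-signed pair to flip",
         call. = FALSE)
  f <- min(f, length(pos), length(neg))
  ip <- sample(pos, f); im <- sample(neg, f)
  y[ip] <- -1; y[im] <- 1
  y
}

#' Affinity-proportional hypermutation
#'
#' Flips \code{f} opposite-signed label pairs (conserving the label sum
#' exactly), with \code{f} growing linearly in affinity rank: the best
#' antibody gets one pair flip, the worst \code{fMax}. The mutant is
#' evaluated and kept only when its affinity improves; otherwise the
#' parent is returned unchanged.
#'
#' @param ab an evaluated antibody (list with y, J, F).
#' @param f number of pair flips (>= 1).
#' @param K kernel matrix.
#' @param C regularization constant.
#' @param seed substream seed for the flip draw.
#' @return The improved antibody, or the parent.
#' @export
hypermutate <- function(ab, f, K, C, seed) {
  y2 <- withSubSeed(seed, "mutation", mutateLabels(ab$y, f))
  m <- innerSolve(K, y2, C)
  if (m@F > ab$F) list(y = y2, J = m@J, F = m@F, model = m, evaluated = TRUE)
  else ab
}

#' Reselection
#'
#' Pools the current population with clones and mutants, removes exact
#' duplicates (canonical sign), and keeps the \code{popSize} highest
#' affinity antibodies; the global best is never lost.
#'
#' @param pop,clones,mutants antibody lists.
#' @param popSize target population size.
#' @return list of antibodies of length \code{popSize} (or fewer when the
#'   distinct pool is smaller).
#' @export
reselect <- function(pop, clones, mutants, popSize) {
  pool <- c(pop, clones, mutants)
  Fs <- vapply(pool, `[[`, numeric(1), "F")
  pool <- pool[order(Fs, decreasing = TRUE)]   # sort first so dedup keeps best
  keys <- vapply(pool, function(a) paste(canonicalSign(a$y), collapse = ""),
                 character(1))
  pool <- pool[!duplicated(keys)]
  pool[seq_len(min(popSize, length(pool)))]
}

#' Receptor editing
#'
#' Replaces the lowest-affinity antibodies outside the memory set with
#' fresh random balanced antibodies, maintaining diversity.
#'
#' @param pop antibody list, sorted or not.
#' @param fraction fraction of the non-memory population replaced.
#' @param n,l labeling length and balance bound.
#' @param memorySize number of top antibodies protected from editing.
#' @param seed substream seed.
#' @return The edited antibody list (new antibodies unevaluated).
#' @export
receptorEdit <- function(pop, fraction, n, l, memorySize, seed) {
  if (fraction <= 0) return(pop)
  Fs <- vapply(pop, `[[`, numeric(1), "F")
  ord <- order(Fs)                        # worst first
  editable <- ord[!(ord %in% order(Fs, decreasing = TRUE)[seq_len(memorySize)])]
  nEdit <- floor(fraction * length(editable))
  if (nEdit < 1) return(pop)
  withSubSeed(seed, "editing", {
    for (i in editable[seq_len(nEdit)])
      pop[[i]] <- .newAntibody(.randomBalancedY(n, l))
  })
  pop
}

#' Run immune-evolutionary maximum-margin clustering
#'
#' The full clonal-selection loop: evaluate affinities (inner solve plus
#' Lamarckian bias/label refinement), clone the best, hypermutate the next
#' best with affinity-proportional intensity (keep-if-better), reselect,
#' and receptor-edit, until the generation cap or an objective stall.
#' Every antibody at every generation satisfies the class balance
#' constraint; the best affinity history is non-decreasing (elitism).
#'
#' @param X numeric feature matrix (n x d), n >= 4.
#' @param config an [iemmcConfig()].
#' @return list with \code{y} (best labeling, canonical sign),
#'   \code{model} (its [MMCModel-class]), \code{history} (data.frame:
#'   generation, bestJ, bestF, meanF), \code{l}, \code{sigma} and
#'   \code{config}.
#' @export
runIEMMC <- function(X, config = iemmcConfig()) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopIfNot(n >= 4, "need at least 4 samples")
  l <- if (is.null(config$l)) floor(0.2 * n) else config$l
  stopIfNot(l <= n, "balance bound exceeds n")
  sigma <- if (is.null(config$sigma)) medianSigma(X) else config$sigma
  fMax <- if (is.null(config$fMax)) max(2, ceiling(n / 10)) else config$fMax
  K <- kernelMatrix(X, config$kernel, sigma)
  kern <- list(kind = config$kernel, sigma = sigma)
  pop <- initPopulation(n, config, X = X)
  evalAb <- function(a) {
    if (isTRUE(a$evaluated)) return(a)
    e <- evaluateAntibody(K, a$y, config$C, l)
    e$model@kernel <- kern
    e
  }
  hist <- data.frame(generation = integer(0), bestJ = numeric(0),
                     bestF = numeric(0), meanF = numeric(0))
  bestJ <- Inf; sinceImprove <- 0; best <- NULL
  for (gen in seq_len(config$maxGen)) {
    pop <- lapply(pop, evalAb)
    Fs <- vapply(pop, `[[`, numeric(1), "F")
    Js <- vapply(pop, `[[`, numeric(1), "J")
    gBest <- which.min(Js)
    if (Js[gBest] < bestJ - 1e-12) {
      bestJ <- Js[gBest]; best <- pop[[gBest]]; sinceImprove <- 0
    } else sinceImprove <- sinceImprove + 1
    hist <- rbind(hist, data.frame(generation = gen, bestJ = bestJ,
                                   bestF = affinityFromObjective(bestJ),
                                   meanF = mean(Fs)))
    if (sinceImprove >= config$stall) break
    nc <- min(config$nClone, length(pop))
    clones <- cloneSelect(pop, nc)
    selIdx <- order(Fs, decreasing = TRUE)
    rest <- selIdx[-seq_len(nc)]
    mutIdx <- rest[seq_len(min(config$nMut, length(rest)))]
    mutants <- list()
    for (r in seq_along(mutIdx)) {
      f <- 1 + round((r - 1) / max(1, length(mutIdx) - 1) * (fMax - 1))
      mutants[[r]] <- hypermutate(pop[[mutIdx[r]]], f, K, config$C,
                                  subSeed(config$seed, paste0("mut", gen, "-", r)))
    }
    pop <- reselect(pop, clones, mutants, config$popSize)
    while (length(pop) < config$popSize)
      pop[[length(pop) + 1]] <- withSubSeed(config$seed, paste0("fill", gen),
                                            .newAntibody(.randomBalancedY(n, l)))
    pop <- receptorEdit(pop, config$editFrac, n, l,
                        memorySize = min(config$nMut, length(pop)),
                        seed = subSeed(config$seed, paste0("edit", gen)))
  }
  y <- canonicalSign(best$y)
  list(y = y, model = best$model, history = hist, l = l, sigma = sigma,
       config = config)
}

#' Recursive bipartition into k clusters
#'
#' The binary maximum-margin objective is extended to k classes by
#' recursive bipartition: the current largest cluster is split with
#' [runIEMMC()] until k clusters exist. Deterministic for a fixed seed
#' (each split uses a derived substream).
#'
#' @param X numeric feature matrix.
#' @param k number of clusters (>= 2), with \code{n >= 2k}. \code{k = 2}
#'   is exactly one [runIEMMC()] call with \code{config} as given.
#' @param config an [iemmcConfig()]; intermediate splits (k > 2) relax
#'   the balance bound to \code{floor(m/3)} for a subset of size m —
#'   intermediate clusters legitimately hold several classes, so splits
#'   up to 1:2 must stay feasible while the trivial one-cluster solution
#'   remains excluded.
#' @return Integer labels in 1..k.
#' @export
recursiveMulticlass <- function(X, k, config = iemmcConfig()) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopIfNot(k >= 2, "k must be >= 2")
  stopIfNot(n >= 2 * k, "need n >= 2k")
  if (k == 2) {
    fit <- runIEMMC(X, config)
    return(ifelse(fit$y > 0, 1L, 2L))
  }
  labels <- rep(1L, n)
  nextLab <- 2L
  split <- 0L
  while (nextLab <= k) {
    sizes <- table(labels)
    target <- as.integer(names(sizes)[which.max(sizes)])
    idx <- which(labels == target)
    if (length(idx) < 4)
      stop("cluster ", target, " too small to split (", length(idx),
           " members)", call. = FALSE)
    split <- split + 1L
    sub <- config
    sub$l <- floor(length(idx) / 3)
    sub$seed <- subSeed(config$seed, paste0("split", split))
    fit <- runIEMMC(X[idx, , drop = FALSE], sub)
    labels[idx[fit$y < 0]] <- nextLab
    nextLab <- nextLab + 1L
  }
  labels
}
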