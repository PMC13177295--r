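## Spectral classification chain: ROI correlation heatmaps, Z-score -> PCA
## -> UMAP embedding, silhouette separation metrics, and ridge-logistic
## wavenumber importance.

#' Pearson correlation matrix of ROI mean spectra
#'
#' @param roiMeans numeric matrix, one row per ROI (baseline-corrected mean
#'   spectra on a common axis); row names label the ROIs
#' @return symmetric correlation matrix with unit diagonal
#' @export
roiCorrelationMatrix <- function(roiMeans) {
  if (nrow(roiMeans) < 2L) stop("need at least 2 ROIs")
  s <- apply(roiMeans, 1L, stats::sd)
  if (any(s == 0)) stop("constant ROI mean spectrum: correlation undefined")
  r <- stats::cor(t(roiMeans))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' PCA reduction of Z-scored spectra
#'
#' Principal component scores in decreasing explained-variance order.
#' Component signs are fixed deterministically: the loading of largest
#' magnitude in each component is made positive.
#'
#' @param x numeric matrix (rows = spectra), typically Z-scored
#' @param nComponents number of components; reduced with a warning when the
#'   input rank cannot support it
#' @return list: `scores` (n x nComponents), `evr` (explained-variance
#'   fractions), `rotation`, `center`
#' @export
pcaReduce <- function(x, nComponents = 20L) {
  maxC <- min(nrow(x) - 1L, ncol(x))
  if (nComponents > maxC) {
    warning(sprintf("nComponents reduced from %d to %d (input rank limit)",
                    nComponents, maxC))
    nComponents <- maxC
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  keep <- seq_len(nComponents)
  rot <- p$rotation[, keep, drop = FALSE]
  sc <- p$x[, keep, drop = FALSE]
  for (j in keep) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sc[, j] <- -sc[, j]
    }
  }
  list(scores = sc, evr = (ev / sum(ev))[keep], rotation = rot,
       center = p$center)
}

# smooth-kNN calibration: per-point bandwidths such that the effective
# number of neighbours is log2(k), as in the UMAP fuzzy simplicial set
smoothKnnWeights <- function(knnDist, nIter = 64L, localConnectivity = 1L) {
  n <- nrow(knnDist); k <- ncol(knnDist)
  target <- log2(k)
  rho <- numeric(n); sigma <- numeric(n)
  for (i in seq_len(n)) {
    di <- knnDist[i, ]
    nz <- di[di > 0]
    rho[i] <- if (length(nz) >= localConnectivity) nz[localConnectivity] else 0
    lo <- 0; hi <- Inf; mid <- 1
    for (it in seq_len(nIter)) {
      psum <- sum(exp(-pmax(di - rho[i], 0) / mid))
      if (abs(psum - target) < 1e-5) break
      if (psum > target) {
        hi <- mid; mid <- (lo + hi) / 2
      } else {
        lo <- mid
        mid <- if (is.finite(hi)) (lo + hi) / 2 else mid * 2
      }
    }
    sigma[i] <- mid
  }
  w <- exp(-pmax(sweep(knnDist, 1L, rho), 0) / sigma)
  list(weights = w, rho = rho, sigma = sigma)
}

# fit the (a, b) low-dimensional kernel parameters for a given min_dist
fitAB <- function(minDist) {
  d <- seq(0, 3, length.out = 300)
  y <- ifelse(d <= minDist, 1, exp(-(d - minDist)))
  df <- data.frame(d = d, y = y)
  fit <- minpack.lm::nlsLM(y ~ 1 / (1 + a * d^(2 * b)), data = df,
                           start = list(a = 1.6, b = 0.9),
                           control = stats::nls.control(maxiter = 200))
  stats::coef(fit)
}

#' UMAP embedding
#'
#' Two-dimensional uniform manifold approximation and projection of PCA
#' scores: exact k-nearest-neighbour graph, smooth-kNN fuzzy weights
#' symmetrized by probabilistic union, and a stochastic-gradient layout
#' with negative sampling. Fully deterministic for a given seed (the layout
#' uses its own seeded RNG).
#'
#' @param scores numeric matrix of reduced spectra (rows = spectra, >= 10)
#' @param nNeighbors neighbourhood size (default 15)
#' @param minDist minimum embedding distance parameter (default 0.1)
#' @param seed integer seed
#' @param nEpochs optimization epochs (default 200)
#' @param labels optional data.frame of per-spectrum labels carried into the
#'   result
#' @return data.frame with `x`, `y` and any label columns; attributes
#'   `seed`, `nNeighbors`, `minDist`
#' @export
umapEmbed <- function(scores, nNeighbors = 15L, minDist = 0.1, seed = 42L,
                      nEpochs = 200L, labels = NULL) {
  n <- nrow(scores)
  if (n < 10L) stop("UMAP needs at least 10 spectra")
  if (!is.null(labels) && nrow(labels) != n)
    stop("labels must have one row per spectrum")
  k <- min(nNeighbors, n - 1L)
  knn <- cpp_knn(as.matrix(scores), k)
  sk <- smoothKnnWeights(knn$dist)
  # symmetrize: w = w1 + w2 - w1 w2 over directed kNN weights
  i <- rep(seq_len(n), each = k)
  j <- as.vector(t(knn$idx))
  w <- as.vector(t(sk$weights))
  key <- paste(pmin(i, j), pmax(i, j))
  first <- !duplicated(key)
  dirW <- stats::setNames(w, paste(i, j))
  revW <- dirW[paste(j, i)]
  revW[is.na(revW)] <- 0
  symW <- w + revW - w * revW
  head <- pmin(i, j)[first]; tail <- pmax(i, j)[first]
  weight <- symW[first]
  keepE <- weight > 0
  head <- head[keepE]; tail <- tail[keepE]; weight <- weight[keepE]

  ab <- fitAB(minDist)
  p2 <- pcaReduce(as.matrix(scores), 2L)$scores
  init <- 10 * p2 / max(abs(p2))
  emb <- cpp_umap_layout(as.integer(head), as.integer(tail),
                         as.numeric(weight), init, as.integer(nEpochs),
                         ab[["a"]], ab[["b"]], 1.0, 1.0, 5L,
                         as.numeric(seed))
  out <- data.frame(x = emb[, 1L], y = emb[, 2L])
  if (!is.null(labels)) out <- cbind(out, labels)
  attr(out, "seed") <- seed
  attr(out, "nNeighbors") <- nNeighbors
  attr(out, "minDist") <- minDist
  out
}

#' Cluster separation on an embedding
#'
#' Mean silhouette width and centroid distance for every unordered pair of
#' labels, computed on the 2-D embedding coordinates.
#'
#' @param embedding data.frame/matrix with columns `x`, `y`
#' @param labels factor/character labels, one per embedded spectrum; at
#'   least two distinct labels with two points each
#' @return data.frame: `label_a`, `label_b`, `silhouette`, `centroid_dist`
#' @export
clusterSeparationMetrics <- function(embedding, labels) {
  xy <- as.matrix(embedding[, c("x", "y")])
  labels <- as.character(labels)
  ul <- sort(unique(labels))
  if (length(ul) < 2L) stop("need at least two distinct labels")
  if (any(table(labels) < 2L)) stop("every label needs at least two points")
  pairs <- utils::combn(ul, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(p) {
    la <- pairs[1L, p]; lb <- pairs[2L, p]
    sel <- labels %in% c(la, lb)
    sub <- xy[sel, , drop = FALSE]
    cl <- as.integer(factor(labels[sel]))
    sil <- cluster::silhouette(cl, stats::dist(sub))
    ca <- colMeans(xy[labels == la, , drop = FALSE])
    cb <- colMeans(xy[labels == lb, , drop = FALSE])
    data.frame(label_a = la, label_b = lb,
               silhouette = mean(sil[, "sil_width"]),
               centroid_dist = sqrt(sum((ca - cb)^2)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Logistic-regression wavenumber importance
#'
#' Fits an L2-regularized (ridge) logistic regression of a binary label
#' (FF vs FFPE within a tissue) on Z-scored spectra, so that coefficients
#' map one-to-one onto wavenumbers; importance is the absolute coefficient.
#' Regularization guarantees a solution under perfect separation.
#'
#' @param x numeric matrix of Z-scored spectra; column names (or `axis`)
#'   give the wavenumbers
#' @param labels binary labels (factor/character), both classes present
#' @param topN ranking length (default 40)
#' @param axis optional \linkS4class{SpectralAxis} naming the columns
#' @param lambda ridge penalty on the mean-log-likelihood objective;
#'   default 1 (unit strength). A penalty of this magnitude keeps the
#'   importance ranking stable against chance correlations among the many
#'   collinear wavenumber channels while leaving a genuinely
#'   discriminative band dominant.
#' @return data.frame: `wavenumber`, `importance`, `rank` (1..topN,
#'   descending importance; ties broken toward the lower wavenumber)
#' @export
logisticFeatureImportance <- function(x, labels, topN = 40L, axis = NULL,
                                      lambda = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("exactly two classes required; got ", nlevels(labels))
  if (any(table(labels) < 2L)) stop("a class is (nearly) absent")
  if (any(table(labels) < 50L))
    warning("fewer than 50 spectra in a class; importance may be unstable")
  wn <- if (!is.null(axis)) wavenumbers(axis)
        else as.numeric(colnames(x))
  if (is.null(wn) || anyNA(wn))
    stop("wavenumbers unavailable: supply 'axis' or numeric column names")
  if (is.null(lambda)) lambda <- 1
  fit <- glmnet::glmnet(x, labels, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE,
                        thresh = 1e-10)
  beta <- as.numeric(fit$beta[, 1L])
  imp <- abs(beta)
  ord <- order(-imp, wn)
  topN <- min(topN, length(wn))
  data.frame(wavenumber = wn[ord[seq_len(topN)]],
             importance = imp[ord[seq_len(topN)]],
             rank = seq_len(topN))
}
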