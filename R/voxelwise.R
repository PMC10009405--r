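#' @useDynLib isacog, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Separable 3D Gaussian smoothing. Each axis uses a truncated (3 sigma)
# kernel assembled into a column-normalized convolution matrix, so every
# input voxel distributes exactly unit mass: the in-volume sum is
# conserved without zero padding.
gaussianSmooth3d <- function(arr, sigma_vox) {
  stopifnot(length(dim(arr)) == 3L, length(sigma_vox) == 3L)
  kernel_matrix <- function(d, sigma) {
    if (sigma <= 0) return(NULL)
    r <- max(1L, ceiling(3 * sigma))
    K <- outer(seq_len(d), seq_len(d),
               function(i, j) ifelse(abs(i - j) <= r,
                                     stats::dnorm(i - j, sd = sigma), 0))
    sweep(K, 2L, colSums(K), "/")
  }
  d <- dim(arr)
  for (ax in 1:3) {
    K <- kernel_matrix(d[ax], sigma_vox[ax])
    if (is.null(K)) next
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    a <- array(K %*% matrix(a, nrow = d[ax]), dim = d[perm])
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Gaussian smoothing of a volume stack
#'
#' Separable Gaussian filter with `sigma = fwhm / (2 sqrt(2 ln 2))` per
#' axis in mm, converted to voxels via the affine (anisotropic voxels are
#' handled per axis). `fwhm = 0` is the identity. Kernels are
#' column-normalized so the in-volume sum is conserved.
#'
#' @param stack a [VolumeStack-class]
#' @param fwhm full width at half maximum in mm (default 6)
#' @return a smoothed [VolumeStack-class]
#' @export
smoothStack <- function(stack, fwhm = 6) {
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (fwhm == 0) return(stack)
  vs <- voxelSizes(stackAffine(stack))
  sigma_vox <- fwhm / (2 * sqrt(2 * log(2))) / vs
  grid <- gridDim(stack)
  dat <- stackData(stack)
  for (i in seq_len(nrow(dat)))
    dat[i, ] <- as.numeric(gaussianSmooth3d(array(dat[i, ], dim = grid),
                                            sigma_vox))
  initialize(stack, data = dat)
}

#' Default analysis mask from mean uptake
#'
#' Voxels whose across-subject mean uptake exceeds `threshold_frac` times
#' the grand mean, intersected with an optional user mask — the
#' conventional implicit masking rule of metabolic mapping software.
#'
#' @param stack a [VolumeStack-class]
#' @param grand_mean target grand mean of proportional scaling (default 50)
#' @param threshold_frac fraction of the grand mean (default 0.2)
#' @param user_mask optional logical array to intersect with
#' @return logical array with dim = grid
#' @export
computeAnalysisMask <- function(stack, grand_mean = 50,
                                threshold_frac = 0.2, user_mask = NULL) {
  m <- array(colMeans(stackData(stack)) > threshold_frac * grand_mean,
             dim = gridDim(stack))
  if (!is.null(user_mask)) {
    stopifnot(identical(dim(user_mask), dim(m)))
    m <- m & user_mask
  }
  m
}

#' Global normalization by proportional scaling
#'
#' Multiplies each subject's volume by `grand_mean / (its in-mask mean)`,
#' so every scaled volume has in-mask mean exactly `grand_mean`. The
#' operation is idempotent.
#'
#' @param stack a [VolumeStack-class] (its mask defines "global")
#' @param grand_mean positive target mean (default 50, the conventional
#'   default of metabolic mapping software)
#' @return the scaled [VolumeStack-class]
#' @export
proportionalScaling <- function(stack, grand_mean = 50) {
  stopifnot(grand_mean > 0)
  idx <- as.logical(stackMask(stack))
  dat <- stackData(stack)
  gm <- rowMeans(dat[, idx, drop = FALSE])
  if (any(gm <= 0))
    stop("non-positive in-mask global mean for subject(s): ",
         paste(subjectIds(stack)[gm <= 0], collapse = ", "))
  initialize(stack, data = dat * (grand_mean / gm))
}

#' Build a design matrix with a designated regressor of interest
#'
#' Intercept + regressor + covariates. Character/factor covariates with
#' two levels (e.g. sex) are binary 0/1 coded. Covariates are not centered
#' by default (centering does not change the regressor's t-map).
#'
#' @param data data.frame with one row per subject
#' @param regressor column name of the regressor of interest (default
#'   `"isacog_magnitude"`)
#' @param covariates character, nuisance column names (default the
#'   canonical patient set: age, sex, BDI-2, UPDRS-III, LEDD)
#' @param center center regressor and numeric covariates (default FALSE)
#' @return a [DesignMatrix-class]
#' @export
designMatrix <- function(data, regressor = "isacog_magnitude",
                         covariates = c("age", "sex", "bdi2", "updrs3",
                                        "ledd"),
                         center = FALSE) {
  stopifnot(regressor %in% names(data), all(covariates %in% names(data)))
  code <- function(v, nm) {
    if (is.numeric(v)) return(v)
    f <- factor(v)
    if (nlevels(f) != 2L)
      stop("covariate '", nm, "' is categorical with ", nlevels(f),
           " levels; only binary coding is supported")
    as.numeric(f) - 1
  }
  cols <- c(list(data[[regressor]]),
            lapply(covariates, function(nm) code(data[[nm]], nm)))
  X <- do.call(cbind, cols)
  colnames(X) <- c(regressor, covariates)
  if (center) X <- sweep(X, 2L, colMeans(X))
  X <- cbind(`(intercept)` = 1, X)
  new("DesignMatrix", matrix = X, regressor = regressor)
}

# Split a design into regressor of interest x and nuisance Z.
design_parts <- function(design) {
  X <- design@matrix
  j <- match(design@regressor, colnames(X))
  list(x = X[, j], Z = X[, -j, drop = FALSE], X = X)
}

#' Voxel-wise OLS t-map for the regressor of interest
#'
#' Per in-mask voxel, ordinary least squares of uptake on the full design;
#' the returned map holds the t statistic of the regressor of interest
#' (`t = coefficient / SE`, `df = n - rank(design)`). Perfect (noiseless)
#' fits produce unbounded t values; these are capped at `t_cap` and
#' flagged.
#'
#' @param stack a [VolumeStack-class] (proportionally scaled, masked)
#' @param design a [DesignMatrix-class] aligned row-wise to the stack
#' @param t_cap cap for infinite t values (default 1e8)
#' @return list with `t` (3D array, NA outside mask), `df`, and
#'   `capped` (logical array marking perfect-fit voxels)
#' @export
fitVoxelGlm <- function(stack, design) {
  fitVoxelGlmImpl(stack, design, t_cap = 1e8)
}

fitVoxelGlmImpl <- function(stack, design, t_cap = 1e8) {
  validObject(design)
  p <- design_parts(design)
  n <- nSubjects(stack)
  if (nrow(p$X) != n) stop("design rows must match stack subjects")
  if (n <= ncol(p$X) + 1L)
    stop("need n > design columns + 1 (n = ", n, ")")
  if (stats::var(p$x) == 0)
    stop("regressor of interest '", design@regressor, "' is constant")
  idx <- as.logical(stackMask(stack))
  Y <- stackData(stack)[, idx, drop = FALSE]
  qrZ <- qr(p$Z)
  xr <- qr.resid(qrZ, p$x)
  Ey <- qr.resid(qrZ, Y)
  xx <- sum(xr^2)
  beta <- as.numeric(crossprod(xr, Ey)) / xx
  rss <- pmax(colSums(Ey^2) - beta^2 * xx, 0)
  df <- n - ncol(p$X)
  se <- sqrt(rss / df / xx)
  tv <- beta / se
  capped_v <- !is.finite(tv) | abs(tv) > t_cap
  tv[capped_v] <- sign(beta[capped_v]) * t_cap
  tv[capped_v & beta == 0] <- 0
  tmap <- array(NA_real_, dim = gridDim(stack))
  tmap[idx] <- tv
  capped <- array(FALSE, dim = gridDim(stack))
  capped[idx] <- capped_v
  if (any(capped_v))
    message(sum(capped_v), " voxel(s) with perfect fit; t capped at ",
            format(t_cap))
  list(t = tmap, df = df, capped = capped)
}

#' Supra-threshold clusters of a t-map
#'
#' Thresholds the t-map at the upper-tail t quantile for `cluster_p` in
#' the requested direction (cluster-forming threshold, conventionally
#' p < 0.005 uncorrected) and labels connected components under the
#' chosen voxel connectivity (default 18: faces + edges).
#'
#' @param tmap 3D t array (NA outside the analysis mask)
#' @param df residual degrees of freedom
#' @param cluster_p cluster-forming uncorrected p (default 0.005)
#' @param direction `"negative"` or `"positive"` association
#' @param connectivity 6, 18 or 26
#' @param affine 4x4 voxel-to-mm transform for peak coordinates
#' @param statistic cluster summary for later inference: `"extent"`
#'   (voxel count, default) or `"mass"` (sum of supra-threshold t excess)
#' @return a [ClusterResult-class] with `fwe_p = NA` (see
#'   [clusterFwePermutation()] for inference)
#' @export
formClusters <- function(tmap, df, cluster_p = 0.005,
                         direction = c("negative", "positive"),
                         connectivity = 18L, affine = diag(4),
                         statistic = c("extent", "mass")) {
  direction <- match.arg(direction)
  statistic <- match.arg(statistic)
  stopifnot(df >= 1)
  thr <- stats::qt(1 - cluster_p, df)
  supra <- if (direction == "positive") tmap > thr else tmap < -thr
  supra[is.na(supra)] <- FALSE
  labels <- array(.label_components_cpp(as.logical(supra), dim(tmap),
                                        as.integer(connectivity)),
                  dim = dim(tmap))
  k <- max(labels)
  if (k == 0L) {
    tab <- data.frame(cluster = integer(0), size = integer(0),
                      peak_t = numeric(0), peak_x = numeric(0),
                      peak_y = numeric(0), peak_z = numeric(0),
                      mass = numeric(0), fwe_p = numeric(0))
  } else {
    tab <- do.call(rbind, lapply(seq_len(k), function(ci) {
      vox <- which(labels == ci)
      tvals <- tmap[vox]
      peak <- vox[if (direction == "positive") which.max(tvals)
                  else which.min(tvals)]
      ijk <- arrayInd(peak, dim(tmap))
      mm <- voxelToMm(affine, ijk)
      data.frame(cluster = ci, size = length(vox),
                 peak_t = tmap[peak], peak_x = mm[1], peak_y = mm[2],
                 peak_z = mm[3], mass = sum(abs(tvals) - thr),
                 fwe_p = NA_real_)
    }))
    ord <- order(tab$size, decreasing = TRUE)
    tab <- tab[ord, , drop = FALSE]
    rownames(tab) <- NULL
  }
  new("ClusterResult", labels = labels, table = tab, df = df,
      threshold = thr, direction = direction,
      connectivity = as.integer(connectivity), statistic = statistic)
}

# Internal engine shared by the observed fit and the permutation loop:
# given residualized quantities, return the t vector over mask voxels.
t_from_resid <- function(num, csw, css, xx, df) {
  rss <- pmax(css - csw - num^2 / xx, 0)
  (num / xx) / sqrt(rss / df / xx)
}

#' Cluster-level FWE inference by Freedman-Lane permutation
#'
#' Fits the voxel-wise GLM, forms supra-threshold clusters, and assigns
#' each cluster a family-wise-error-corrected p value from the permutation
#' distribution of the maximum cluster statistic. Nuisance covariates are
#' handled by the Freedman-Lane scheme: volumes are residualized on the
#' covariates, the residual rows are permuted, and the full model is refit
#' — the standard approach for testing a single regressor in the presence
#' of nuisance variables. `fwe_p = (1 + #\{perm max >= observed\}) /
#' (1 + n_perm)`, so the smallest attainable p is `1/(1 + n_perm)`.
#'
#' @inheritParams formClusters
#' @param stack a [VolumeStack-class] (scaled, with analysis mask set)
#' @param design a [DesignMatrix-class]
#' @param n_perm number of permutations (>= 100)
#' @param seed RNG seed for the permutation draw
#' @return a [ClusterResult-class] with `fwe_p` filled in; attribute
#'   `perm_max` carries the null maximum-statistic distribution
#' @export
clusterFwePermutation <- function(stack, design, cluster_p = 0.005,
                                  n_perm = 1000L, seed = 1L,
                                  direction = c("negative", "positive"),
                                  connectivity = 18L,
                                  statistic = c("extent", "mass")) {
  direction <- match.arg(direction)
  statistic <- match.arg(statistic)
  validObject(design)
  n <- nSubjects(stack)
  if (n < 7L)
    stop("permutation inference needs >= 7 subjects (n = ", n,
         "): the permutation space is too small")
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (n_perm < 500L)
    warning("n_perm = ", n_perm,
            ": coarse p-value resolution (minimum attainable ",
            signif(1 / (1 + n_perm), 3), ")")
  p <- design_parts(design)
  idx <- as.logical(stackMask(stack))
  Y <- stackData(stack)[, idx, drop = FALSE]
  qrZ <- qr(p$Z)
  Qz <- qr.Q(qrZ)
  xr <- qr.resid(qrZ, p$x)
  xx <- sum(xr^2)
  if (xx <= .Machine$double.eps)
    stop("regressor of interest '", design@regressor,
         "' has no variance after covariate removal")
  Ey <- qr.resid(qrZ, Y)
  df <- n - ncol(p$X)
  css <- colSums(Ey^2)

  # observed map
  tv <- t_from_resid(as.numeric(crossprod(xr, Ey)), 0 * css, css, xx, df)
  tv[!is.finite(tv)] <- 0
  tmap <- array(NA_real_, dim = gridDim(stack))
  tmap[idx] <- tv
  obs <- formClusters(tmap, df, cluster_p, direction, connectivity,
                      stackAffine(stack), statistic)

  thr <- obs@threshold
  grid <- gridDim(stack)
  conn <- as.integer(connectivity)
  perms <- with_seed(seed,
                     replicate(n_perm, sample.int(n), simplify = FALSE))
  perm_max <- vapply(perms, function(pm) {
    Eyp <- Ey[pm, , drop = FALSE]
    W <- crossprod(Qz, Eyp)
    num <- as.numeric(crossprod(xr, Eyp))
    tp <- t_from_resid(num, colSums(W^2), css, xx, df)
    tp[!is.finite(tp)] <- 0
    supra_v <- if (direction == "positive") tp > thr else tp < -thr
    supra <- logical(prod(grid))
    supra[idx] <- supra_v
    if (!any(supra_v)) return(0)
    if (statistic == "extent") {
      .max_component_size_cpp(supra, grid, conn)
    } else {
      labs <- .label_components_cpp(supra, grid, conn)
      excess <- numeric(prod(grid))
      excess[idx] <- abs(tp) - thr
      max(rowsum(excess[labs > 0], labs[labs > 0]))
    }
  }, numeric(1))

  tab <- obs@table
  if (nrow(tab)) {
    stat_obs <- if (statistic == "extent") tab$size else tab$mass
    tab$fwe_p <- vapply(stat_obs,
                        function(s) (1 + sum(perm_max >= s)) / (1 + n_perm),
                        numeric(1))
  }
  out <- initialize(obs, table = tab)
  attr(out, "perm_max") <- perm_max
  out
}

#' Per-subject mean uptake over a volume of interest
#'
#' @param stack a [VolumeStack-class] (proportionally scaled)
#' @param voi logical array (a significant cluster or an atlas-label
#'   union), nonempty
#' @return named numeric, one mean per subject
#' @export
extractVoiMeans <- function(stack, voi) {
  stopifnot(identical(dim(voi), as.integer(gridDim(stack))))
  idx <- as.logical(voi)
  if (!any(idx)) stop("empty VOI")
  stats::setNames(rowMeans(stackData(stack)[, idx, drop = FALSE]),
                  subjectIds(stack))
}

#' Logical VOI from one cluster of a ClusterResult
#' @param clusters a [ClusterResult-class]
#' @param cluster cluster id (row of the cluster table)
#' @return logical array
#' @export
voiFromCluster <- function(clusters, cluster) {
  voi <- clusterLabels(clusters) == cluster
  if (!any(voi)) stop("cluster ", cluster, " is empty")
  voi
}

#' Subgroup partial correlations between VOI uptake and ISAcog
#'
#' For each subgroup, the covariate-adjusted partial correlation between
#' mean VOI uptake and ISAcog ([partialCorrelation()]); subgroups too
#' small for the covariate set are skipped with a message.
#'
#' @param voi_means numeric, per-subject VOI means
#' @param isacog numeric, per-subject ISAcog (magnitude convention)
#' @param covariates data.frame of nuisance covariates
#' @param group_labels factor/character subgroup per subject
#' @return data.frame: `group`, `n`, `r_partial`, `p_value`, `df`
#' @export
subgroupVoiAnalysis <- function(voi_means, isacog, covariates,
                                group_labels) {
  covariates <- as.data.frame(covariates)
  k <- ncol(covariates)
  rows <- lapply(unique(as.character(group_labels)), function(g) {
    sel <- group_labels == g
    if (sum(sel) <= k + 2L) {
      message("subgroup '", g, "' skipped: n = ", sum(sel),
              " <= covariates + 2")
      return(NULL)
    }
    pc <- partialCorrelation(voi_means[sel], isacog[sel],
                             covariates[sel, , drop = FALSE])
    data.frame(group = g, n = sum(sel), r_partial = pc$r_partial,
               p_value = pc$p_value, df = pc$df,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(group = character(0), n = integer(0),
                      r_partial = numeric(0), p_value = numeric(0),
                      df = integer(0))
  rownames(out) <- NULL
  out
}

#' Specificity check: rerun the analysis with objective cognition
#'
#' Substitutes the overall cognition z-score for ISAcog in the same design
#' and reruns the voxel-wise cluster inference, plus (optionally) the VOI
#' correlations against cognition — verifying that clusters associated
#' with ISAcog are not simply cognition effects.
#'
#' @inheritParams clusterFwePermutation
#' @param overall_z numeric, per-subject overall cognition z
#' @param vois optional named list of logical VOI arrays to correlate
#'   against cognition
#' @return list with `clusters` (a [ClusterResult-class] for the
#'   cognition regressor) and `voi_table` (data.frame or NULL)
#' @export
specificityCheck <- function(stack, design, overall_z, vois = NULL,
                             cluster_p = 0.005, n_perm = 1000L,
                             seed = 1L,
                             direction = c("negative", "positive"),
                             connectivity = 18L,
                             statistic = c("extent", "mass")) {
  direction <- match.arg(direction)
  statistic <- match.arg(statistic)
  X <- design@matrix
  X[, design@regressor] <- overall_z
  colnames(X)[colnames(X) == design@regressor] <- "overall_z"
  design2 <- new("DesignMatrix", matrix = X, regressor = "overall_z")
  cl <- clusterFwePermutation(stack, design2, cluster_p, n_perm, seed,
                              direction, connectivity, statistic)
  voi_table <- NULL
  if (!is.null(vois)) {
    covs <- as.data.frame(
      X[, setdiff(colnames(X), c("overall_z", "(intercept)")),
        drop = FALSE])
    voi_table <- do.call(rbind, lapply(names(vois), function(nm) {
      vm <- extractVoiMeans(stack, vois[[nm]])
      pc <- partialCorrelation(vm, overall_z, covs)
      data.frame(voi = nm, r_partial = pc$r_partial,
                 p_value = pc$p_value, df = pc$df,
                 stringsAsFactors = FALSE)
    }))
  }
  list(clusters = cl, voi_table = voi_table)
}

#' Region-level structural follow-up restricted to metabolic clusters
#'
#' Builds the restricted search mask as the union of atlas labels that
#' intersect the significant metabolic clusters, then correlates each such
#' region's structural scalar (e.g. mean cortical thickness) with ISAcog
#' under the same covariates, Holm-correcting across regions.
#'
#' @param structural data.frame/matrix, one row per subject and one
#'   column per atlas region, columns named `region_<label>`
#' @param atlas integer-labeled array (same grid as the clusters)
#' @param clusters a [ClusterResult-class] with permutation `fwe_p`
#' @param isacog numeric per-subject ISAcog (magnitude convention)
#' @param covariates data.frame of nuisance covariates
#' @param alpha cluster significance level defining the mask (default
#'   0.05)
#' @return list with `regions` (data.frame: `region`, `r_partial`,
#'   `p_value`, `p_holm`, `significant`), `mask` (logical array) and
#'   `labels` (integer vector of atlas labels in the mask)
#' @export
restrictedMaskStructuralAnalysis <- function(structural, atlas, clusters,
                                             isacog, covariates,
                                             alpha = 0.05) {
  stopifnot(identical(dim(atlas), dim(clusterLabels(clusters))))
  sig <- significantMap(clusters, alpha)
  labs <- sort(unique(atlas[sig & atlas > 0]))
  if (length(labs) == 0L) {
    message("no atlas label intersects a significant cluster")
    return(list(regions = data.frame(region = integer(0),
                                     r_partial = numeric(0),
                                     p_value = numeric(0),
                                     p_holm = numeric(0),
                                     significant = logical(0)),
                mask = array(FALSE, dim = dim(atlas)),
                labels = integer(0)))
  }
  mask <- array(atlas %in% labs, dim = dim(atlas))
  structural <- as.data.frame(structural)
  rows <- lapply(labs, function(lb) {
    col <- paste0("region_", lb)
    if (!col %in% names(structural))
      stop("structural table has no column '", col, "'")
    pc <- partialCorrelation(structural[[col]], isacog, covariates)
    data.frame(region = lb, r_partial = pc$r_partial,
               p_value = pc$p_value)
  })
  regions <- do.call(rbind, rows)
  regions$p_holm <- stats::p.adjust(regions$p_value, method = "holm")
  regions$significant <- regions$p_holm < alpha
  rownames(regions) <- NULL
  list(regions = regions, mask = mask, labels = labs)
}
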