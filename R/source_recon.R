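#' LCMV beamformer spatial filters
#'
#' Linearly constrained minimum-variance filters with diagonal regularization
#' of 5 percent of the average trace of the sensor covariance (a common
#' filter, i.e. one covariance pooled over conditions). Per source the
#' three-orientation filter is reduced to the orientation of maximal output
#' power (dominant eigenvector of the 3 x 3 source output-power matrix), and
#' the final one-dimensional filter has unit gain in that direction:
#' `w' L theta = 1`.
#'
#' @param cov sensor covariance matrix (symmetric positive semidefinite),
#'   computed from eyes-open and eyes-closed epochs jointly.
#' @param lf a [generate_leadfield()] result (or any list with a `gain`
#'   sensors x sources x 3 array).
#' @param reg_frac regularization as a fraction of `mean(diag(cov))`
#'   (default 0.05).
#' @return list of class `lcmv_filters` with `weights` (sensors x sources),
#'   `orientations` (sources x 3) and `output_power` (sources).
#' @export
lcmv_filters <- function(cov, lf, reg_frac = 0.05) {
  stopifnot(isSymmetric(unname(cov), tol = 1e-6))
  n_sens <- nrow(cov)
  stopifnot(dim(lf$gain)[1] == n_sens)
  creg <- cov + reg_frac * mean(diag(cov)) * diag(n_sens)
  cinv <- solve(creg)
  n_src <- dim(lf$gain)[2]
  w <- matrix(0, n_sens, n_src)
  ors <- matrix(0, n_src, 3)
  pow <- numeric(n_src)
  for (q in seq_len(n_src)) {
    l <- lf$gain[, q, ]
    m <- crossprod(l, cinv %*% l)   # L' C^-1 L (3x3)
    minv <- tryCatch(solve(m), error = function(e)
      stop(sprintf("singular constrained power matrix at source %d", q)))
    # max-power orientation: dominant eigenvector of (L' Creg^-1 L)^-1
    eg <- eigen((minv + t(minv)) / 2, symmetric = TRUE)
    theta <- eg$vectors[, 1]
    lq <- drop(l %*% theta)
    denom <- drop(crossprod(lq, cinv %*% lq))
    wq <- drop(cinv %*% lq) / denom
    w[, q] <- wq
    ors[q, ] <- theta
    pow[q] <- drop(crossprod(wq, cov %*% wq))
  }
  structure(list(weights = w, orientations = ors, output_power = pow),
            class = "lcmv_filters")
}

#' Project sensor epochs to source space
#'
#' @param epochs an [epoch_set()] in sensor space.
#' @param filters a [lcmv_filters()] result.
#' @return an `epoch_set` whose "channels" are sources.
#' @export
apply_lcmv <- function(epochs, filters) {
  stopifnot(inherits(epochs, "epoch_set"))
  w <- filters$weights
  n_src <- ncol(w)
  d <- epochs$data
  out <- array(0, c(n_src, dim(d)[2], dim(d)[3]))
  for (e in seq_len(dim(d)[3]))
    out[, , e] <- crossprod(w, matrix(d[, , e], nrow = dim(d)[1]))
  epoch_set(out, epochs$condition, epochs$srate, paste0("src", seq_len(n_src)))
}

#' Sensor covariance from an epoch set
#'
#' Pooled covariance over all epochs and samples (both conditions), the
#' common-filter convention.
#'
#' @param epochs an [epoch_set()].
#' @return channels x channels covariance matrix.
#' @export
sensor_covariance <- function(epochs) {
  d <- epochs$data
  n_ch <- dim(d)[1]
  x <- matrix(d, nrow = n_ch)
  x <- x - rowMeans(x)
  tcrossprod(x) / (ncol(x) - 1)
}

#' Partition sources into mirror-symmetric ROIs
#'
#' k-means clustering of one hemisphere's source positions, mirrored across
#' the midline to the other hemisphere, giving `2 k` regions. Midline sources
#' (x = 0) join the nearest right-hemisphere cluster and its mirror twin is
#' identified with the left copy. Two ROIs are adjacent when at least one
#' cross pair of member sources is grid-adjacent (within 1.5 times the grid
#' spacing).
#'
#' @param positions sources x 3 matrix of mirror-symmetric positions (mm).
#' @param k_per_hemisphere clusters per hemisphere (default 25).
#' @param seed integer seed for the k-means initialization.
#' @param spacing grid spacing in mm used for source adjacency (default 15).
#' @return list of class `roi_partition` with `labels` (per-source ROI id,
#'   1..2k), `centroids`, `adjacency` (symmetric, irreflexive logical matrix)
#'   and `sizes`.
#' @export
make_rois <- function(positions, k_per_hemisphere = 25, seed = 1,
                      spacing = 15) {
  k <- k_per_hemisphere
  right <- which(positions[, 1] > 1e-9)
  left <- which(positions[, 1] < -1e-9)
  mid <- which(abs(positions[, 1]) <= 1e-9)
  stopifnot(length(right) >= k)
  km <- NULL
  for (attempt in seq_len(10)) {
    set.seed(substream_seed(seed, attempt))
    km <- try(suppressWarnings(
      stats::kmeans(positions[right, , drop = FALSE], centers = k,
                    nstart = 10, iter.max = 300)), silent = TRUE)
    if (!inherits(km, "try-error") && !any(km$size == 0)) break
    km <- NULL
  }
  if (is.null(km)) stop("k-means failed to produce k non-empty clusters")
  rlab <- balance_cluster_sizes(positions[right, , drop = FALSE], km$cluster,
                                min_size = 4, max_size = 13)
  labels <- integer(nrow(positions))
  labels[right] <- rlab
  # left hemisphere: mirror of the right clustering (ROI ids k+1 .. 2k)
  mirr <- positions[left, , drop = FALSE]
  mirr[, 1] <- -mirr[, 1]
  # exact mirror-pair matching
  key <- function(p) paste(round(p[, 1], 3), round(p[, 2], 3), round(p[, 3], 3))
  right_key <- key(positions[right, , drop = FALSE])
  idx <- match(key(mirr), right_key)
  if (anyNA(idx)) {
    # fall back to nearest mirrored centroid for unpaired sources
    d2 <- as.matrix(stats::dist(rbind(km$centers, mirr)))[-seq_len(k), seq_len(k)]
    labels[left] <- max.col(-d2) + k
  } else {
    labels[left] <- rlab[idx] + k
  }
  if (length(mid)) {
    # midline sources join the nearest right-hemisphere ROI that still has
    # room below the maximal ROI size
    d2 <- as.matrix(stats::dist(rbind(km$centers,
                                      positions[mid, , drop = FALSE])))[
      -seq_len(k), seq_len(k), drop = FALSE]
    cnt <- tabulate(labels[right], k)
    for (m in order(apply(d2, 1, min))) {
      open <- which(cnt < 13)
      tgt <- open[which.min(d2[m, open])]
      labels[mid[m]] <- tgt
      cnt[tgt] <- cnt[tgt] + 1L
    }
  }
  n_roi <- 2L * k
  cent <- t(vapply(seq_len(n_roi), function(r)
    colMeans(positions[labels == r, , drop = FALSE]), numeric(3)))
  # source adjacency within 1.5 * spacing; ROI adjacency from cross pairs
  dmat <- as.matrix(stats::dist(positions))
  src_adj <- dmat > 1e-9 & dmat <= 1.5 * spacing
  adj <- matrix(FALSE, n_roi, n_roi)
  for (r in seq_len(n_roi - 1)) {
    for (s in (r + 1):n_roi) {
      if (any(src_adj[labels == r, labels == s])) adj[r, s] <- adj[s, r] <- TRUE
    }
  }
  structure(list(labels = labels, centroids = cent, adjacency = adj,
                 sizes = tabulate(labels, n_roi), k = k),
            class = "roi_partition")
}

# internal: greedy repair moving boundary sources so every cluster size
# falls inside [min_size, max_size]; each move picks the member closest to
# the receiving cluster's centroid
balance_cluster_sizes <- function(pts, lab, min_size, max_size,
                                  max_moves = 200L) {
  k <- max(lab)
  cent <- function() t(vapply(seq_len(k), function(c)
    colMeans(pts[lab == c, , drop = FALSE]), numeric(ncol(pts))))
  for (mv in seq_len(max_moves)) {
    sizes <- tabulate(lab, k)
    small <- which(sizes < min_size)
    big <- which(sizes > max_size)
    if (!length(small) && !length(big)) break
    cc <- cent()
    if (length(small)) {
      tgt <- small[which.min(sizes[small])]
      # steal the nearest outside source from any cluster that can spare one
      cand <- which(lab != tgt & sizes[lab] > min_size)
      if (!length(cand)) break
      d <- colSums((t(pts[cand, , drop = FALSE]) - cc[tgt, ])^2)
      lab[cand[which.min(d)]] <- tgt
    } else {
      src <- big[which.max(sizes[big])]
      mem <- which(lab == src)
      # give the member farthest from its centroid to its nearest other
      # cluster with room
      room <- which(sizes < max_size)
      room <- setdiff(room, src)
      if (!length(room)) break
      dfar <- colSums((t(pts[mem, , drop = FALSE]) - cc[src, ])^2)
      mover <- mem[which.max(dfar)]
      drec <- colSums((t(cc[room, , drop = FALSE]) - pts[mover, ])^2)
      lab[mover] <- room[which.min(drec)]
    }
  }
  lab
}

#' First-principal-component ROI time series
#'
#' For every ROI, the first principal component score series of its member
#' source time series, with the sign fixed so the component correlates
#' positively with the mean member series.
#'
#' @param source_ts sources x time matrix.
#' @param part a [make_rois()] partition.
#' @return rois x time matrix.
#' @export
roi_timeseries <- function(source_ts, part) {
  n_roi <- length(part$sizes)
  out <- matrix(0, n_roi, ncol(source_ts))
  for (r in seq_len(n_roi)) {
    mem <- which(part$labels == r)
    if (!length(mem)) stop("empty ROI")
    x <- source_ts[mem, , drop = FALSE]
    xc <- x - rowMeans(x)
    if (length(mem) == 1L) {
      sc <- drop(xc)
    } else {
      sv <- svd(xc, nu = 1, nv = 0)
      sc <- drop(crossprod(sv$u[, 1], xc))
    }
    m <- colMeans(x)
    if (stats::sd(sc) > 0 && stats::sd(m) > 0 && stats::cor(sc, m) < 0)
      sc <- -sc
    out[r, ] <- sc
  }
  out
}

#' ROI projection of a source-space epoch set
#'
#' Computes per-ROI first principal components with loadings estimated on all
#' epochs pooled, then applies the same loadings epoch by epoch (so the ROI
#' series is a single linear combination of member sources throughout).
#'
#' @param src_epochs source-space [epoch_set()] (from [apply_lcmv()]).
#' @param part a [make_rois()] partition.
#' @return an `epoch_set` whose channels are ROIs.
#' @export
roi_epochs <- function(src_epochs, part) {
  d <- src_epochs$data
  n_src <- dim(d)[1]
  pooled <- matrix(d, nrow = n_src)
  n_roi <- length(part$sizes)
  load <- vector("list", n_roi)
  for (r in seq_len(n_roi)) {
    mem <- which(part$labels == r)
    x <- pooled[mem, , drop = FALSE]
    xc <- x - rowMeans(x)
    if (length(mem) == 1L) u <- matrix(1, 1, 1)
    else u <- svd(xc, nu = 1, nv = 0)$u
    sc <- drop(crossprod(u, xc))
    if (stats::sd(sc) > 0 && stats::cor(sc, colMeans(x)) < 0) u <- -u
    load[[r]] <- drop(u)
  }
  out <- array(0, c(n_roi, dim(d)[2], dim(d)[3]))
  for (e in seq_len(dim(d)[3])) {
    xe <- matrix(d[, , e], nrow = n_src)
    for (r in seq_len(n_roi))
      out[r, , e] <- drop(crossprod(load[[r]],
                                    xe[part$labels == r, , drop = FALSE]))
  }
  epoch_set(out, src_epochs$condition, src_epochs$srate,
            paste0("roi", seq_len(n_roi)))
}
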