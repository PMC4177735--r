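#' Side-chain direction vectors
#'
#' For every residue with a designated side-chain vector atom present, the
#' (un-normalized) vector s_k from its C-alpha to that atom. Residues whose
#' vector atom coincides with the C-alpha (zero-length vector) are excluded
#' with a warning.
#'
#' @param struct a `catres_structure` (read and stripped).
#' @return data frame with columns `idx` (row index into
#'   `struct$residues`), `sx`, `sy`, `sz`, `norm` (Angstrom).
#' @export
side_chain_vectors <- function(struct) {
  stopifnot(inherits(struct, "catres_structure"))
  r <- struct$residues
  i <- which(r$has_sv)
  sx <- r$sv_x[i] - r$ca_x[i]
  sy <- r$sv_y[i] - r$ca_y[i]
  sz <- r$sv_z[i] - r$ca_z[i]
  nrm <- sqrt(sx^2 + sy^2 + sz^2)
  bad <- nrm == 0
  if (any(bad)) {
    warning(sum(bad), " residue(s) with zero-length side-chain vector excluded")
    i <- i[!bad]; sx <- sx[!bad]; sy <- sy[!bad]; sz <- sz[!bad]; nrm <- nrm[!bad]
  }
  data.frame(idx = i, sx = sx, sy = sy, sz = sz, norm = nrm)
}

#' Build the scanning grid
#'
#' The structure is embedded in a 30 x 30 x 30 grid of points spanning the
#' axis-aligned bounding box of its C-alpha atoms: the origin is the box
#' minimum corner and the per-axis spacing is extent/(points - 1), so the
#' outermost grid planes touch the box faces. A fixed point count (rather
#' than fixed spacing) keeps the scan cost independent of protein size; for
#' typical proteins this yields spacings of roughly 1.3-2.1 Angstrom.
#' Degenerate axes (zero extent, e.g. a planar arrangement) fall back to a
#' 0.5 Angstrom spacing.
#'
#' @param struct a `catres_structure`.
#' @param n_points grid points per axis (default 30).
#' @return A `catres_grid`: list with `origin` (3-vector), `spacing`
#'   (3-vector, Angstrom) and `n` points per axis.
#' @export
build_grid <- function(struct, n_points = 30) {
  stopifnot(inherits(struct, "catres_structure"), n_points >= 2)
  ca <- as.matrix(struct$residues[, c("ca_x", "ca_y", "ca_z")])
  if (nrow(ca) == 0) stop("structure has no residues")
  lo <- apply(ca, 2, min)
  hi <- apply(ca, 2, max)
  ext <- hi - lo
  if (max(ext) < 1e-9)
    stop("degenerate structure: all C-alpha atoms coincide")
  spacing <- ext / (n_points - 1)
  spacing[ext < 1e-9] <- 0.5
  structure(list(origin = unname(lo), spacing = unname(spacing),
                 n = as.integer(n_points)),
            class = "catres_grid")
}

# all grid point coordinates as an (n^3 x 3) matrix, x fastest
grid_points <- function(grid) {
  s <- seq_len(grid$n) - 1
  g <- as.matrix(expand.grid(x = s, y = s, z = s))
  sweep(g * rep(grid$spacing, each = nrow(g)), 2, grid$origin, "+")
}

#' Surrounding residues of a point
#'
#' The vector-bearing residues whose C-alpha lies strictly within `radius`
#' of the point. Residues without a valid side-chain vector are never
#' "surrounding", since the orientation angle is undefined for them.
#'
#' @param point numeric 3-vector (Angstrom).
#' @param struct a `catres_structure`.
#' @param radius cutoff in Angstrom (default 10, strict `<`).
#' @return integer vector of row indices into `struct$residues`.
#' @export
surrounding_residues <- function(point, struct, radius = 10) {
  sv <- side_chain_vectors(struct)
  ca <- as.matrix(struct$residues[sv$idx, c("ca_x", "ca_y", "ca_z"), drop = FALSE])
  d2 <- (ca[, 1] - point[1])^2 + (ca[, 2] - point[2])^2 + (ca[, 3] - point[3])^2
  sv$idx[d2 < radius^2]
}

#' Angle between a residue's side chain and the direction to a point
#'
#' theta is the angle between v = point - C-alpha and the residue's
#' side-chain vector s, in degrees. A small theta means the side chain
#' points at the candidate site center.
#'
#' @param point numeric 3-vector.
#' @param struct a `catres_structure`.
#' @param idx residue row index (must have a valid side-chain vector).
#' @return angle in degrees, in \[0, 180\].
#' @export
angle_theta <- function(point, struct, idx) {
  r <- struct$residues[idx, ]
  if (!isTRUE(r$has_sv)) stop("residue has no side-chain vector")
  v <- c(point[1] - r$ca_x, point[2] - r$ca_y, point[3] - r$ca_z)
  s <- c(r$sv_x - r$ca_x, r$sv_y - r$ca_y, r$sv_z - r$ca_z)
  nv <- sqrt(sum(v^2)); ns <- sqrt(sum(s^2))
  if (nv == 0) stop("point coincides with the residue C-alpha: angle undefined")
  if (ns == 0) stop("zero-length side-chain vector: angle undefined")
  cosang <- sum(v * s) / (nv * ns)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Candidate catalytic-site centers
#'
#' Scans every grid point: a point survives if it has at least
#' `min_surrounding` surrounding residues (vector-bearing C-alpha strictly
#' within `radius`) and the mean of its per-residue theta angles does not
#' exceed `theta_cutoff` (strictly greater is removed; a mean of exactly
#' the cutoff is kept). Surviving points are the probable catalytic-site
#' centers over which residue triplets are scored.
#'
#' @param struct a `catres_structure`.
#' @param grid a `catres_grid` from [build_grid()] (default: built here).
#' @param radius surrounding-residue cutoff, Angstrom (default 10).
#' @param theta_cutoff mean-angle cutoff, degrees (default 80).
#' @param min_surrounding minimum surrounding residues (default 3).
#' @return A `catres_candidates`: list with `points` (m x 3 matrix),
#'   `surrounding` (list of integer residue-index vectors), `theta` (list
#'   of per-residue angles, degrees), `mean_theta` (numeric), and the
#'   filter parameters; plus counts `n_grid`, `n_after_min`, `n_after_theta`.
#' @export
candidate_points <- function(struct, grid = NULL, radius = 10,
                             theta_cutoff = 80, min_surrounding = 3) {
  stopifnot(inherits(struct, "catres_structure"))
  if (is.null(grid)) grid <- build_grid(struct)
  gp <- grid_points(grid)
  sv <- side_chain_vectors(struct)
  if (nrow(sv) == 0)
    return(structure(list(points = gp[0, , drop = FALSE], surrounding = list(),
                          theta = list(), mean_theta = numeric(0),
                          radius = radius, theta_cutoff = theta_cutoff,
                          min_surrounding = min_surrounding,
                          n_grid = nrow(gp), n_after_min = 0L, n_after_theta = 0L),
                     class = "catres_candidates"))
  ca <- as.matrix(struct$residues[sv$idx, c("ca_x", "ca_y", "ca_z"), drop = FALSE])
  shat <- cbind(sv$sx, sv$sy, sv$sz) / sv$norm
  ca_dot_s <- rowSums(ca * shat)

  keep_pts <- list(); keep_surr <- list(); keep_theta <- list(); keep_mean <- list()
  n_after_min <- 0L
  chunk <- 4000L
  starts <- seq(1L, nrow(gp), by = chunk)
  for (st in starts) {
    en <- min(st + chunk - 1L, nrow(gp))
    G <- gp[st:en, , drop = FALSE]
    # squared distances point x residue
    d2 <- outer(rowSums(G^2), rowSums(ca^2), "+") - 2 * tcrossprod(G, ca)
    d2[d2 < 0] <- 0
    within <- d2 < radius^2
    N <- rowSums(within)
    ok <- which(N >= min_surrounding)
    if (!length(ok)) next
    n_after_min <- n_after_min + length(ok)
    # cos theta = (G . s_hat - CA . s_hat) / |G - CA|
    num <- tcrossprod(G[ok, , drop = FALSE], shat) -
      matrix(ca_dot_s, nrow = length(ok), ncol = nrow(ca), byrow = TRUE)
    dist <- sqrt(d2[ok, , drop = FALSE])
    cosang <- num / dist
    cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
    th <- acos(cosang) * 180 / pi
    w <- within[ok, , drop = FALSE]
    mth <- rowSums(th * w) / N[ok]
    pass <- which(mth <= theta_cutoff)
    for (p in pass) {
      j <- which(w[p, ])
      keep_pts[[length(keep_pts) + 1L]] <- G[p, ]
      keep_surr[[length(keep_surr) + 1L]] <- sv$idx[j]
      keep_theta[[length(keep_theta) + 1L]] <- th[p, j]
      keep_mean[[length(keep_mean) + 1L]] <- mth[p]
    }
  }
  pts <- if (length(keep_pts)) do.call(rbind, keep_pts) else gp[0, , drop = FALSE]
  mth_all <- if (length(keep_mean)) unlist(keep_mean, use.names = FALSE) else numeric(0)
  structure(list(points = pts, surrounding = keep_surr, theta = keep_theta,
                 mean_theta = mth_all,
                 radius = radius, theta_cutoff = theta_cutoff,
                 min_surrounding = min_surrounding,
                 n_grid = nrow(gp), n_after_min = n_after_min,
                 n_after_theta = length(keep_surr)),
            class = "catres_candidates")
}

#' @export
print.catres_candidates <- function(x, ...) {
  cat("<catres_candidates> ", x$n_grid, " grid points; ", x$n_after_min,
      " with >= ", x$min_surrounding, " surrounding residues; ",
      x$n_after_theta, " with mean theta <= ", x$theta_cutoff, " deg\n", sep = "")
  invisible(x)
}
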