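# Convex hull geometry for canopy structure features.
# 2-D area uses grDevices::chull; the 3-D hull is a quickhull implementation
# (no 3-D hull routine ships with the environment's packages).

#' Convex hull area of the horizontal footprint
#'
#' Area of the 2-D convex hull of the (x, y) projection, in square metres.
#' @param points n x 3 (or n x 2) coordinate matrix.
#' @return area; 0 with a warning for degenerate (collinear) input.
#' @export
convex_hull_area <- function(points) {
  xy <- unique(points[, 1:2, drop = FALSE])
  if (nrow(xy) < 3) {
    warning("fewer than 3 distinct points; hull area reported as 0")
    return(0)
  }
  h <- grDevices::chull(xy[, 1], xy[, 2])
  if (length(h) < 3) {
    warning("collinear points; hull area reported as 0")
    return(0)
  }
  x <- xy[h, 1]; y <- xy[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Convex hull volume of a point cloud
#'
#' Volume of the 3-D convex hull (quickhull), in cubic metres.
#' @param points n x 3 coordinate matrix.
#' @param tol relative degeneracy tolerance.
#' @return volume; 0 with a warning for degenerate (coplanar or fewer than
#'   4 distinct points) input.
#' @export
convex_hull_volume <- function(points, tol = 1e-10) {
  P <- unique(unname(as.matrix(points)))
  if (nrow(P) < 4) {
    warning("fewer than 4 distinct points; hull volume reported as 0")
    return(0)
  }
  scale <- max(apply(P, 2, function(v) diff(range(v))))
  if (scale == 0) {
    warning("degenerate geometry; hull volume reported as 0")
    return(0)
  }
  eps <- tol * scale
  faces <- quickhull3d(P, eps)
  if (is.null(faces)) {
    warning("coplanar points; hull volume reported as 0")
    return(0)
  }
  c0 <- colMeans(P)
  vol <- 0
  for (f in faces) {
    a <- P[f[1], ]; b <- P[f[2], ]; cc <- P[f[3], ]
    n <- cross3(b - a, cc - a)
    vol <- vol + sum(n * (a - c0)) / 6
  }
  abs(vol)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

# Quickhull. Returns a list of index triples (outward-oriented faces), or
# NULL when the input is degenerate (rank < 3).
quickhull3d <- function(P, eps) {
  n <- nrow(P)
  # initial simplex: extremes along x, farthest from their line, then plane
  i1 <- which.min(P[, 1]); i2 <- which.max(P[, 1])
  if (i1 == i2) { i1 <- which.min(P[, 2]); i2 <- which.max(P[, 2]) }
  d <- P[i2, ] - P[i1, ]
  if (sqrt(sum(d^2)) < eps) return(NULL)
  rel <- sweep(P, 2, P[i1, ])
  crossn <- cbind(rel[, 2] * d[3] - rel[, 3] * d[2],
                  rel[, 3] * d[1] - rel[, 1] * d[3],
                  rel[, 1] * d[2] - rel[, 2] * d[1])
  ld <- sqrt(rowSums(crossn^2)) / sqrt(sum(d^2))
  i3 <- which.max(ld)
  if (ld[i3] < eps) return(NULL)
  nrm <- cross3(P[i2, ] - P[i1, ], P[i3, ] - P[i1, ])
  pd <- abs(rel %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(pd)
  if (pd[i4] < eps) return(NULL)

  verts <- c(i1, i2, i3, i4)
  ctr <- colMeans(P[verts, ])
  orient <- function(f) {  # outward wrt simplex centre
    a <- P[f[1], ]; nn <- cross3(P[f[2], ] - a, P[f[3], ] - a)
    if (sum(nn * (ctr - a)) > 0) f[c(1, 3, 2)] else f
  }
  faces <- lapply(list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4)),
                  orient)
  face_norm <- function(f) {
    a <- P[f[1], ]; nn <- cross3(P[f[2], ] - a, P[f[3], ] - a)
    list(n = nn, a = a)
  }
  norms <- lapply(faces, face_norm)
  # outside sets: points strictly above a face
  above <- function(fn, idx) {
    if (length(idx) == 0) return(integer())
    h <- sweep(P[idx, , drop = FALSE], 2, fn$a) %*% fn$n
    idx[h > eps * sqrt(sum(fn$n^2))]
  }
  pool <- setdiff(seq_len(n), verts)
  outside <- lapply(norms, above, idx = pool)

  repeat {
    fi <- which(lengths(outside) > 0)[1]
    if (is.na(fi)) break
    fn <- norms[[fi]]
    cand <- outside[[fi]]
    h <- sweep(P[cand, , drop = FALSE], 2, fn$a) %*% fn$n
    p <- cand[which.max(h)]
    # visible faces from p
    vis <- vapply(seq_along(faces), function(j) {
      fj <- norms[[j]]
      sum(fj$n * (P[p, ] - fj$a)) > eps * sqrt(sum(fj$n^2))
    }, logical(1))
    # horizon: edges of visible faces shared with a hidden face
    edge_key <- function(i, j) paste(min(i, j), max(i, j))
    cnt <- new.env()
    for (j in which(vis)) {
      f <- faces[[j]]
      for (e in list(f[1:2], f[2:3], f[c(3, 1)])) {
        k <- edge_key(e[1], e[2])
        prev <- if (is.null(cnt[[k]])) NULL else cnt[[k]]
        cnt[[k]] <- if (is.null(prev)) e else "dup"
      }
    }
    horizon <- Filter(function(e) !identical(e, "dup"), as.list(cnt))
    cand_all <- unique(unlist(outside[vis]))
    cand_all <- setdiff(cand_all, p)
    faces <- faces[!vis]; norms <- norms[!vis]; outside <- outside[!vis]
    for (e in horizon) {
      f <- c(e[1], e[2], p)
      a <- P[f[1], ]; nn <- cross3(P[f[2], ] - a, P[f[3], ] - a)
      # orient outward using the hull interior (simplex centre)
      if (sum(nn * (ctr - a)) > 0) { f <- f[c(1, 3, 2)]; nn <- -nn }
      fnew <- list(n = nn, a = a)
      faces[[length(faces) + 1]] <- f
      norms[[length(norms) + 1]] <- fnew
      outside[[length(outside) + 1]] <- above(fnew, cand_all)
    }
  }
  faces
}
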