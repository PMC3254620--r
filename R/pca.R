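#' Correlation-matrix PCA of distal-phalanx shape
#'
#' Principal component analysis of the nine shape variables (the eight
#' GM-standardized linear measurements plus FSA) on the correlation matrix,
#' so that the eigenvalues sum to the number of variables and the first
#' component's share of variance can be read directly as eigenvalue/9.
#' Loadings are returned as Pearson correlations between each variable and
#' each component score. Component signs are fixed so that the loading of
#' \code{BH_GM} on component 1 is positive.
#'
#' @param x data.frame or matrix of shape variables (rows = specimens,
#'   typically the output columns of \code{\link{standardize_phalanx}} plus
#'   FSA). At least 3 specimens.
#' @return object of class \code{"unguis_pca"}: list with
#'   \code{eigenvalues}, \code{proportion_variance}, \code{loadings}
#'   (variables x components, correlations) and \code{scores}.
#' @export
pca_shape <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need >= 3 specimens for a PCA")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate variable(s) with zero variance: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  eig <- fit$sdev^2
  # correlation loading of standardized variable i with component j is
  # rotation[i, j] * sdev[j]
  load <- sweep(fit$rotation, 2, fit$sdev, `*`)
  scores <- fit$x
  anchor <- if ("BH_GM" %in% rownames(load)) "BH_GM" else rownames(load)[1]
  flip <- sign(load[anchor, ])
  flip[flip == 0] <- 1
  load <- sweep(load, 2, flip, `*`)
  scores <- sweep(scores, 2, flip, `*`)
  structure(list(eigenvalues = eig,
                 proportion_variance = eig / sum(eig),
                 loadings = load,
                 scores = scores),
            class = "unguis_pca")
}

#' @export
print.unguis_pca <- function(x, ...) {
  k <- min(4, length(x$eigenvalues))
  cat("Correlation-matrix PCA:", length(x$eigenvalues), "variables,",
      nrow(x$scores), "specimens\n")
  cat("Eigenvalues:", paste(round(x$eigenvalues[1:k], 2), collapse = ", "),
      "...\n")
  cat("Variance explained:",
      paste0(round(100 * x$proportion_variance[1:k]), "%", collapse = ", "),
      "...\n")
  invisible(x)
}

# Signed point-in-polygon with edge tolerance. Polygon vertices in order
# (closed implicitly). Returns "inside", "edge" or "outside".
point_in_polygon <- function(px, py, vx, vy, tol = 1e-9) {
  n <- length(vx)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    # distance to segment j-i
    dx <- vx[i] - vx[j]; dy <- vy[i] - vy[j]
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) ((px - vx[j]) * dx + (py - vy[j]) * dy) / len2 else 0
    t <- min(1, max(0, t))
    qx <- vx[j] + t * dx; qy <- vy[j] + t * dy
    if (sqrt((px - qx)^2 + (py - qy)^2) <= tol) return("edge")
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- vx[j] + (py - vy[j]) / (vy[i] - vy[j]) * dx
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  if (inside) "inside" else "outside"
}

#' Assign fossil PCA scores to extant group convex hulls
#'
#' For each fossil point in the plane of the first two components, reports
#' which extant groups' convex hulls contain it. Points within \code{tol}
#' of a hull boundary are flagged \code{"edge"}.
#'
#' @param fossil_scores matrix/data.frame of fossil points (2 columns).
#' @param extant_scores matrix/data.frame of extant points (2 columns).
#' @param groups group label per extant point; every group needs >= 3
#'   non-collinear points.
#' @param tol boundary tolerance in score units.
#' @return data.frame, fossils x groups, entries "inside"/"edge"/"outside";
#'   attribute \code{"member"} lists per-fossil containing groups.
#' @export
convex_hull_assign <- function(fossil_scores, extant_scores, groups,
                               tol = 1e-9) {
  f <- as.matrix(fossil_scores)[, 1:2, drop = FALSE]
  e <- as.matrix(extant_scores)[, 1:2, drop = FALSE]
  groups <- as.character(groups)
  stopifnot(nrow(e) == length(groups))
  out <- matrix(NA_character_, nrow(f), length(unique(groups)),
                dimnames = list(rownames(f), unique(groups)))
  for (g in unique(groups)) {
    pts <- e[groups == g, , drop = FALSE]
    if (nrow(pts) < 3)
      stop("degenerate hull: group ", g, " has fewer than 3 points")
    h <- grDevices::chull(pts)
    hx <- pts[h, 1]; hy <- pts[h, 2]
    # collinearity check: polygon area
    area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    if (length(h) < 3 || area < .Machine$double.eps * max(abs(c(hx, hy)))^2)
      stop("degenerate hull: group ", g, " points are collinear")
    for (i in seq_len(nrow(f)))
      out[i, g] <- point_in_polygon(f[i, 1], f[i, 2], hx, hy, tol)
  }
  res <- as.data.frame(out, stringsAsFactors = FALSE)
  attr(res, "member") <- apply(out, 1, function(r)
    colnames(out)[r %in% c("inside", "edge")], simplify = FALSE)
  res
}
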