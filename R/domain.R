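#' Fit a PCA applicability domain on training descriptors
#'
#' Standardizes every descriptor to zero mean and unit variance, projects
#' onto the two leading principal components (descriptor scales differ by
#' orders of magnitude, so unstandardized PCA would be dominated by a few
#' columns), and records the convex hull of the training projections as the
#' applicability region. A bounding-box region is available as a looser
#' alternative.
#'
#' @param X_train descriptor matrix with at least 3 molecules and at least 2
#'   varying columns (run [filter_descriptors()] first so no column is
#'   constant).
#' @param method `"hull"` (convex hull of training projections, the tightest
#'   convex region) or `"bbox"` (axis-aligned bounding box).
#' @return a `domain_model`: standardization (`center`, `scale`), `loadings`
#'   (2 principal axes), `train_projection`, `hull` (vertex coordinates),
#'   `explained_variance` (fraction per retained component), `method`,
#'   `feature_names`.
#' @export
fit_domain <- function(X_train, method = c("hull", "bbox")) {
  method <- match.arg(method)
  X_train <- as.matrix(X_train)
  if (nrow(X_train) < 3)
    stop("at least 3 molecules are required", call. = FALSE)
  sds <- apply(X_train, 2, sd)
  if (any(sds == 0))
    stop("constant descriptor column(s) present; run filter_descriptors() ",
         "before fitting the domain", call. = FALSE)
  pca <- prcomp(X_train, center = TRUE, scale. = TRUE)
  if (length(pca$sdev) < 2 || pca$sdev[2] < 1e-10)
    stop("descriptor matrix has rank < 2; a 2-component chemical space ",
         "cannot be built", call. = FALSE)
  proj <- pca$x[, 1:2, drop = FALSE]
  colnames(proj) <- c("pc1", "pc2")
  hull_idx <- grDevices::chull(proj)
  structure(list(center = pca$center, scale = pca$scale,
                 loadings = pca$rotation[, 1:2, drop = FALSE],
                 train_projection = proj,
                 hull = proj[hull_idx, , drop = FALSE],
                 explained_variance =
                   (pca$sdev^2 / sum(pca$sdev^2))[1:2],
                 method = method, feature_names = colnames(X_train)),
            class = "domain_model")
}

#' @export
print.domain_model <- function(x, ...) {
  cat("PCA applicability domain (", x$method, "): ",
      nrow(x$train_projection), " training molecules, ",
      sprintf("%.1f%% + %.1f%%", 100 * x$explained_variance[1],
              100 * x$explained_variance[2]),
      " variance on PC1/PC2\n", sep = "")
  invisible(x)
}

# Boundary-inclusive membership test of points in a convex polygon given by
# its hull vertices (in hull order). Falls back to a bounding box when the
# hull is degenerate (fewer than 3 distinct vertices).
points_in_hull <- function(points, hull, tol = NULL) {
  if (is.null(tol))
    tol <- 1e-9 * max(1, diff(range(hull[, 1])), diff(range(hull[, 2])))
  nv <- nrow(hull)
  if (nv < 3) {
    inx <- points[, 1] >= min(hull[, 1]) - tol & points[, 1] <= max(hull[, 1]) + tol
    iny <- points[, 2] >= min(hull[, 2]) - tol & points[, 2] <= max(hull[, 2]) + tol
    return(inx & iny)
  }
  inside <- rep(TRUE, nrow(points))
  # polygon orientation from its signed area
  v2 <- rbind(hull[-1, , drop = FALSE], hull[1, , drop = FALSE])
  area2 <- sum(hull[, 1] * v2[, 2] - v2[, 1] * hull[, 2])
  orient <- if (area2 >= 0) 1 else -1
  for (e in seq_len(nv)) {
    a <- hull[e, ]; b <- v2[e, ]
    cross <- (b[1] - a[1]) * (points[, 2] - a[2]) -
             (b[2] - a[2]) * (points[, 1] - a[1])
    inside <- inside & (orient * cross >= -tol)
  }
  inside
}

#' Applicability-domain membership of new molecules
#'
#' Projects new molecules with the training standardization and loadings and
#' tests whether each projected point lies inside the training region
#' (convex hull or bounding box; the boundary counts as inside). Points
#' inside the region are chemistry the model was trained on, so predictions
#' there are considered more reliable.
#'
#' @param model a `domain_model` from [fit_domain()].
#' @param X_new descriptor matrix with the training feature schema.
#' @return data frame with `id`, projected `pc1`, `pc2`, and `in_domain`
#'   (`"inside"` / `"outside"`).
#' @export
in_domain <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  check_schema(model$feature_names, X_new)
  Z <- scale(X_new, center = model$center, scale = model$scale)
  proj <- Z %*% model$loadings
  ok <- if (model$method == "hull") {
    points_in_hull(proj, model$hull)
  } else {
    tp <- model$train_projection
    tol <- 1e-9 * max(1, diff(range(tp[, 1])), diff(range(tp[, 2])))
    proj[, 1] >= min(tp[, 1]) - tol & proj[, 1] <= max(tp[, 1]) + tol &
      proj[, 2] >= min(tp[, 2]) - tol & proj[, 2] <= max(tp[, 2]) + tol
  }
  data.frame(id = if (is.null(rownames(X_new))) seq_len(nrow(X_new))
                  else rownames(X_new),
             pc1 = proj[, 1], pc2 = proj[, 2],
             in_domain = ifelse(ok, "inside", "outside"),
             row.names = NULL, stringsAsFactors = FALSE)
}
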