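## Distance-to-tumour spatial statistics: Euclidean distance from each
## classified cell to the boundary of the nearest tumour region (0 inside),
## and between-subset comparison of the distance distributions.

## Minimum distance from points (px, py) to the closed polygonal ring `poly`
## (n x 2 matrix of vertices, open or closed; the closing edge is implied).
dist_points_to_ring <- function(px, py, poly) {
  if (nrow(poly) >= 2 &&
      all(poly[1, ] == poly[nrow(poly), ])) {
    poly <- poly[-nrow(poly), , drop = FALSE]
  }
  n <- nrow(poly)
  best <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    a <- poly[i, ]
    b <- poly[if (i == n) 1L else i + 1L, ]
    abx <- b[1] - a[1]; aby <- b[2] - a[2]
    len2 <- abx * abx + aby * aby
    if (len2 == 0) {
      d2 <- (px - a[1])^2 + (py - a[2])^2
    } else {
      t <- pmin(1, pmax(0, ((px - a[1]) * abx + (py - a[2]) * aby) / len2))
      d2 <- (px - (a[1] + t * abx))^2 + (py - (a[2] + t * aby))^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

points_in_polygon <- function(px, py, poly) {
  if (nrow(poly) >= 2 && all(poly[1, ] == poly[nrow(poly), ])) {
    poly <- poly[-nrow(poly), , drop = FALSE]
  }
  inside <- mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]),
                         cbind(px, py))
  ## in.out excludes boundary points inconsistently; a boundary point has
  ## ring distance 0 and is treated as inside by the caller anyway
  inside
}

#' Distance from cells to the nearest tumour region
#'
#' Euclidean point-to-boundary distance in micrometres, minimised over all
#' regions; points inside (or on the boundary of) any region get distance 0.
#'
#' @param x,y Cell coordinates in micrometres.
#' @param regions Non-empty list of simple polygons (two-column vertex
#'   matrices, micrometres; closing edge implied).
#' @return Numeric vector of distances, one per point.
#' @export
distance_to_nearest_tumour <- function(x, y, regions) {
  if (!length(regions)) stop("region set must be non-empty", call. = FALSE)
  d <- rep(Inf, length(x))
  inside_any <- rep(FALSE, length(x))
  for (poly in regions) {
    poly <- as.matrix(poly)
    d <- pmin(d, dist_points_to_ring(x, y, poly))
    inside_any <- inside_any | points_in_polygon(x, y, poly)
  }
  d[inside_any] <- 0
  d
}

#' Compare distance-to-tumour distributions between CAF subsets
#'
#' Summarises each subset's distances (n, median, mean, SD) and runs all
#' pairwise Welch tests with Benjamini-Hochberg correction across the pairs.
#'
#' @param records Data frame with columns `subset` and `distance` (one row
#'   per classified cell).
#' @return List with `summary` (one row per subset) and `pairwise` (one row
#'   per subset pair: `t`, `p`, `q`). Subsets without cells are dropped with
#'   a warning.
#' @export
subset_distance_comparison <- function(records) {
  stopifnot(all(c("subset", "distance") %in% colnames(records)))
  records$subset <- as.character(records$subset)
  counts <- table(records$subset)
  empty <- setdiff(unique(records$subset), names(counts)[counts > 0])
  if (length(empty)) {
    warning("omitting empty subset(s): ", paste(empty, collapse = ", "))
  }
  subsets <- names(counts)[counts > 0]
  if (length(subsets) < 2) {
    stop("need at least 2 subsets with cells to compare", call. = FALSE)
  }
  smry <- do.call(rbind, lapply(subsets, function(s) {
    d <- records$distance[records$subset == s]
    data.frame(subset = s, n = length(d), median = median(d),
               mean = mean(d), sd = sd(d))
  }))
  pairs <- utils::combn(subsets, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- records$distance[records$subset == pairs[1, i]]
    b <- records$distance[records$subset == pairs[2, i]]
    cg <- compare_groups(a, b)
    data.frame(subset_a = pairs[1, i], subset_b = pairs[2, i],
               t = cg$statistic, p = cg$p.value)
  }))
  pw$q <- p.adjust(pw$p, method = "BH")
  list(summary = smry, pairwise = pw)
}
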