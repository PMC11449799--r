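# SWC morphology I/O and morphometrics: Sholl profile, branch metrics,
# soma size.

#' Neuronal morphology (SWC node table)
#'
#' @param nodes A data.frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent` (standard 7-column SWC semantics: 1-based ids,
#'   `parent = -1` at the root).
#' @return A data.frame of class `morphology`, validated: exactly one root,
#'   no dangling parents, acyclic/connected (every parent precedes its
#'   children topologically), radii >= 0.
#' @export
morphology <- function(nodes) {
  req <- c("id", "type", "x", "y", "z", "radius", "parent")
  assert_that(all(req %in% names(nodes)), "nodes must have SWC columns")
  nodes <- nodes[, req]
  assert_that(!anyDuplicated(nodes$id), "duplicate node ids", "format_error")
  roots <- which(nodes$parent == -1L)
  if (length(roots) != 1L) {
    stop_twinephys(sprintf("expected exactly one root, found %d", length(roots)),
                   "format_error")
  }
  assert_that(all(nodes$radius >= 0), "radii must be >= 0", "format_error")
  non_root <- nodes$parent != -1L
  dangle <- !(nodes$parent[non_root] %in% nodes$id)
  if (any(dangle)) {
    bad <- which(non_root)[dangle][1]
    stop_twinephys(sprintf("node %d (row %d) has dangling parent %d",
                           nodes$id[bad], bad, nodes$parent[bad]),
                   "format_error")
  }
  # connectivity/acyclicity: iteratively peel nodes whose parent is resolved
  resolved <- nodes$parent == -1L
  repeat {
    newly <- !resolved & nodes$parent %in% nodes$id[resolved]
    if (!any(newly)) break
    resolved <- resolved | newly
  }
  if (!all(resolved)) {
    bad <- which(!resolved)[1]
    stop_twinephys(sprintf("cycle or disconnected component at node %d (row %d)",
                           nodes$id[bad], bad), "format_error")
  }
  structure(nodes, class = c("morphology", "data.frame"))
}

#' Read a morphology from an SWC file
#'
#' @param path Path to a 7-column SWC file (`#` comments allowed).
#' @return A [morphology()].
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(vapply(fields, length, integer(1)) != 7L)
  if (length(bad)) {
    stop_twinephys(sprintf("line %d: expected 7 fields", which(keep)[bad[1]]),
                   "format_error")
  }
  m <- do.call(rbind, lapply(fields, as.numeric))
  morphology(data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                        x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                        parent = as.integer(m[, 7])))
}

#' Write a morphology to an SWC file
#'
#' The round trip `read_swc(write_swc(m))` is the identity on the node table.
#'
#' @param morph A [morphology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(morph, path) {
  assert_that(inherits(morph, "morphology"), "input must be a morphology")
  lines <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                   morph$id, morph$type, morph$x, morph$y, morph$z,
                   morph$radius, morph$parent)
  writeLines(c("# SWC generated by twinephys", lines), path)
  invisible(path)
}

soma_center <- function(morph) {
  s <- morph$type == 1L
  if (any(s)) colMeans(morph[s, c("x", "y", "z")])
  else unlist(morph[morph$parent == -1L, c("x", "y", "z")])
}

# parent-child segment table (excluding soma-internal segments)
segment_table <- function(morph) {
  idx <- match(morph$parent, morph$id)
  child <- which(morph$parent != -1L)
  child <- child[!(morph$type[child] == 1L & morph$type[idx[child]] == 1L)]
  p <- idx[child]
  data.frame(x0 = morph$x[p], y0 = morph$y[p], z0 = morph$z[p],
             x1 = morph$x[child], y1 = morph$y[child], z1 = morph$z[child])
}

# number of crossings of the sphere |p - c| = r by one 3-D line segment;
# a tangency (double root) counts once.
segment_sphere_crossings <- function(seg, center, r) {
  a <- cbind(seg$x0 - center[1], seg$y0 - center[2], seg$z0 - center[3])
  b <- cbind(seg$x1 - seg$x0, seg$y1 - seg$y0, seg$z1 - seg$z0)
  A <- rowSums(b^2)
  B <- 2 * rowSums(a * b)
  C <- rowSums(a^2) - r^2
  counts <- integer(nrow(seg))
  disc <- B^2 - 4 * A * C
  for (i in seq_len(nrow(seg))) {
    if (A[i] == 0) next                          # degenerate zero-length segment
    if (disc[i] < 0) next
    sq <- sqrt(disc[i])
    t1 <- (-B[i] - sq) / (2 * A[i])
    t2 <- (-B[i] + sq) / (2 * A[i])
    if (disc[i] == 0) {
      counts[i] <- as.integer(t1 >= 0 && t1 <= 1)  # tangency counts once
    } else {
      counts[i] <- sum(c(t1, t2) >= 0 & c(t1, t2) <= 1)
    }
  }
  counts
}

#' Sholl intersection profile
#'
#' Counts, for each concentric sphere of radius `step, 2*step, ...` centered
#' on the soma, the number of times tree segments cross the sphere (a
#' segment crossing k times contributes k; tangency counts once). Spheres
#' are 3-D, matching 3-D reconstructions; set `project_2d = TRUE` for the
#' planar (xy-projection) variant.
#'
#' @param morph A [morphology()].
#' @param step Radial increment, um (default 10).
#' @param project_2d Count circle crossings in the xy plane instead.
#' @return A data.frame of class `sholl_profile` with columns `radius`,
#'   `intersections`; trailing all-zero radii are trimmed (a tree that never
#'   leaves the first shell gives zero rows).
#' @export
sholl <- function(morph, step = 10, project_2d = FALSE) {
  assert_that(inherits(morph, "morphology"), "input must be a morphology")
  assert_that(step > 0, "step must be > 0")
  center <- soma_center(morph)
  seg <- segment_table(morph)
  if (project_2d) {
    seg$z0 <- 0
    seg$z1 <- 0
    center[3] <- 0
  }
  if (!nrow(seg)) {
    return(structure(data.frame(radius = numeric(0), intersections = integer(0)),
                     class = c("sholl_profile", "data.frame")))
  }
  dmax <- sqrt(max((seg$x0 - center[1])^2 + (seg$y0 - center[2])^2 + (seg$z0 - center[3])^2,
                   (seg$x1 - center[1])^2 + (seg$y1 - center[2])^2 + (seg$z1 - center[3])^2))
  radii <- seq(step, by = step, length.out = max(1L, ceiling(dmax / step)))
  counts <- vapply(radii, function(r) sum(segment_sphere_crossings(seg, center, r)),
                   integer(1))
  nz <- which(counts > 0)
  keep <- if (length(nz)) seq_len(max(nz)) else integer(0)
  structure(data.frame(radius = radii[keep], intersections = counts[keep]),
            class = c("sholl_profile", "data.frame"))
}

#' Branch metrics: count, maximal branch length, total dendritic length
#'
#' A branch is an unbranched path between topological nodes (root,
#' branch points, tips). Lengths are summed 3-D Euclidean segment lengths.
#'
#' @param morph A [morphology()].
#' @return A list with `n_branches`, `max_branch_length` (um),
#'   `total_length` (um).
#' @export
branch_metrics <- function(morph) {
  assert_that(inherits(morph, "morphology"), "input must be a morphology")
  idx <- match(morph$parent, morph$id)
  child_rows <- which(morph$parent != -1L &
                        !(morph$type == 1L & morph$type[idx] == 1L))
  if (!length(child_rows)) {
    return(list(n_branches = 0L, max_branch_length = 0, total_length = 0))
  }
  p <- idx[child_rows]
  seg_len <- sqrt((morph$x[child_rows] - morph$x[p])^2 +
                    (morph$y[child_rows] - morph$y[p])^2 +
                    (morph$z[child_rows] - morph$z[p])^2)
  n_children <- tabulate(p, nbins = nrow(morph))
  root_row <- which(morph$parent == -1L)
  # a node ends a branch if it is a tip, a branch point, or the root
  is_junction <- n_children != 1L
  is_junction[root_row] <- TRUE
  # walk from each junction/tip child-end backwards to the previous junction
  branch_id <- integer(length(child_rows))
  names(seg_len) <- as.character(child_rows)
  bid <- 0L
  lengths <- numeric(0)
  for (k in seq_along(child_rows)) {
    node <- child_rows[k]
    if (!is_junction[node]) next      # interior of a branch
    bid <- bid + 1L
    len <- 0
    cur <- node
    repeat {
      ki <- match(cur, child_rows)
      len <- len + seg_len[ki]
      par_row <- idx[cur]
      if (is_junction[par_row]) break
      cur <- par_row
    }
    lengths[bid] <- len
  }
  list(n_branches = bid, max_branch_length = max(lengths),
       total_length = sum(seg_len))
}

#' Soma cross-sectional area
#'
#' If the soma is traced as a contour of three or more type-1 nodes, the
#' shoelace area of their xy outline is returned; otherwise the soma is
#' treated as a circle of the root radius (`pi * r^2`).
#'
#' @param morph A [morphology()].
#' @return Area, um^2.
#' @export
soma_size <- function(morph) {
  assert_that(inherits(morph, "morphology"), "input must be a morphology")
  s <- which(morph$type == 1L)
  if (length(s) >= 3L) {
    x <- morph$x[s]
    y <- morph$y[s]
    n <- length(x)
    j <- c(2:n, 1L)
    abs(sum(x * y[j] - x[j] * y)) / 2
  } else {
    r <- morph$radius[morph$parent == -1L]
    pi * r^2
  }
}
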