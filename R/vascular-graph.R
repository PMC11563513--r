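# Binary masks are modeled as centerline graphs: topology-preserving
# thinning, per-pixel calibers from the Euclidean distance transform, and
# a node/segment decomposition on which all downstream morphometrics
# (tortuosity, branching points, Murray deviation, symmetry) are defined.

shift_zero <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

# Neighborhood stack in Zhang-Suen order p2..p9 = N, NE, E, SE, S, SW, W, NW
# (x right = increasing col, y down = increasing row; "north" = row - 1).
zs_neighbors <- function(m) {
  list(shift_zero(m, -1L,  0L), shift_zero(m, -1L,  1L),
       shift_zero(m,  0L,  1L), shift_zero(m,  1L,  1L),
       shift_zero(m,  1L,  0L), shift_zero(m,  1L, -1L),
       shift_zero(m,  0L, -1L), shift_zero(m, -1L, -1L))
}

zs_pass <- function(m, first_subiter) {
  p <- zs_neighbors(m)
  B <- Reduce(`+`, p)
  A <- matrix(0L, nrow(m), ncol(m))
  for (k in 1:8) {
    nxt <- if (k == 8) 1 else k + 1
    A <- A + (!p[[k]] & p[[nxt]])
  }
  if (first_subiter) {
    cond <- !(p[[1]] & p[[3]] & p[[5]]) & !(p[[3]] & p[[5]] & p[[7]])
  } else {
    cond <- !(p[[1]] & p[[3]] & p[[7]]) & !(p[[1]] & p[[5]] & p[[7]])
  }
  del <- m & B >= 2 & B <= 6 & A == 1 & cond
  m & !del
}

#' Skeletonize a binary vessel mask
#'
#' Zhang-Suen thinning (8-connectivity) followed by a simple-point
#' cleanup pass that removes redundant pixels from residual 2 x 2 solid
#' blocks, so the skeleton is one pixel wide. Thinning only deletes
#' pixels, hence the skeleton is a subset of the mask, and deletions are
#' restricted to simple points, preserving the topology of each mask
#' component. An empty mask yields an empty skeleton.
#'
#' @param mask a [vessel_mask()].
#' @return A `skeleton`: list with `pixels` (n x 2 matrix of row, col),
#'   `radius_um` (filled by [radius_from_distance()]), `dims`, and
#'   `scale_um_per_px`.
#' @export
skeletonize <- function(mask) {
  m <- unclass(mask) == TRUE
  repeat {
    m1 <- zs_pass(m, TRUE)
    m2 <- zs_pass(m1, FALSE)
    if (identical(m2, m)) break
    m <- m2
  }
  # dissolve remaining 2x2 blocks pixel by pixel where deletion is safe
  two_by_two <- function(mm) {
    b <- mm & shift_zero(mm, 0L, 1L) & shift_zero(mm, 1L, 0L) &
      shift_zero(mm, 1L, 1L)
    which(b, arr.ind = TRUE)
  }
  blk <- two_by_two(m)
  guard <- 0L
  while (nrow(blk) > 0 && guard < 10000L) {
    changed <- FALSE
    for (i in seq_len(nrow(blk))) {
      for (dr in 0:1) for (dc in 0:1) {
        r <- blk[i, 1] + dr; c <- blk[i, 2] + dc
        if (r < 1 || c < 1 || r > nrow(m) || c > ncol(m) || !m[r, c]) next
        nb <- pixel_neighborhood(m, r, c)
        B <- sum(nb)
        A <- sum(!nb & nb[c(2:8, 1)])
        if (A == 1 && B >= 2 && B <= 7) {
          m[r, c] <- FALSE
          changed <- TRUE
        }
      }
    }
    blk <- two_by_two(m)
    guard <- guard + 1L
    if (!changed) break
  }
  m <- remove_staircase_redundancy(m)
  pix <- which(m, arr.ind = TRUE)
  colnames(pix) <- c("row", "col")
  structure(list(pixels = pix, radius_um = NULL, dims = dim(m),
                 scale_um_per_px = mask_scale(mask)),
            class = "skeleton")
}

# Zhang-Suen output retains redundant staircase pixels on diagonal runs;
# their neighbors all touch each other, so neighbor-count-based junction
# detection would chain them into spurious clusters. Delete any pixel
# with >= 2 neighbors whose skeleton neighbors form a single 8-connected
# component within the 3x3 ring (a simple point on a locally shortcut
# path), iterating to a fixed point.
remove_staircase_redundancy <- function(m) {
  off <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    pix <- which(m, arr.ind = TRUE)
    if (nrow(pix) == 0) break
    for (i in seq_len(nrow(pix))) {
      r <- pix[i, 1]; c <- pix[i, 2]
      if (!m[r, c]) next
      nb <- integer(0)
      for (k in 1:8) {
        rr <- r + off[k, 1]; cc <- c + off[k, 2]
        if (rr >= 1 && cc >= 1 && rr <= nrow(m) && cc <= ncol(m) &&
            m[rr, cc])
          nb <- c(nb, k)
      }
      if (length(nb) < 2) next
      # union-find over the neighbor cells' mutual 8-adjacency
      comp <- seq_along(nb)
      for (a in seq_along(nb)) for (b in seq_len(a - 1L)) {
        if (max(abs(off[nb[a], ] - off[nb[b], ])) <= 1) {
          ca <- comp[a]; cb <- comp[b]
          if (ca != cb) comp[comp == ca] <- cb
        }
      }
      if (length(unique(comp)) == 1L) {
        m[r, c] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# p2..p9 values around (r, c), zero-padded at the border.
pixel_neighborhood <- function(m, r, c) {
  off <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  rr <- r + off[, 1]; cc <- c + off[, 2]
  ok <- rr >= 1 & cc >= 1 & rr <= nrow(m) & cc <= ncol(m)
  v <- logical(8)
  v[ok] <- m[cbind(rr[ok], cc[ok])]
  v
}

#' @export
print.skeleton <- function(x, ...) {
  cat("<skeleton>", nrow(x$pixels), "px on a", x$dims[1], "x", x$dims[2],
      "grid\n")
  invisible(x)
}

#' Assign per-pixel radii from the distance transform
#'
#' The local vessel radius at each skeleton pixel is the Euclidean
#' distance from that pixel to the closest background (tissue) pixel,
#' computed with [EBImage::distmap()]. Because the raw distance is
#' quantized to pixel centers and the thinned skeleton can sit up to
#' half a pixel off the true centerline, the value is refined to
#' sub-pixel precision: the signed distance field (positive inside the
#' vessel, negative outside) forms a ridge along the centerline, and
#' the ridge apex is reconstructed from opposing-neighbor pairs by
#' intersecting unit-slope lines, then shifted by a fixed calibration
#' constant measured on rasterized tubes of known radius (see the
#' package vignette). Residual error is below half a pixel for tubes of
#' half-width two pixels and above.
#'
#' @param mask the [vessel_mask()] the skeleton was derived from.
#' @param skeleton a `skeleton` with `skeleton$pixels` all inside `mask`
#'   (anything else is an invariant breach and errors).
#' @return The skeleton with `radius_um` (and `radius_px`) filled in.
#' @export
radius_from_distance <- function(mask, skeleton) {
  m <- unclass(mask) == TRUE
  stopifnot(inherits(skeleton, "skeleton"),
            all(dim(m) == skeleton$dims))
  if (nrow(skeleton$pixels) == 0) {
    skeleton$radius_um <- numeric(0)
    skeleton$radius_px <- numeric(0)
    return(skeleton)
  }
  inside <- m[skeleton$pixels]
  if (!all(inside))
    stop("skeleton pixel outside mask: invariant breach (",
         sum(!inside), " pixels)")
  # signed distance field on the 2x bilinear-upsampled mask (distances in
  # upsampled pixels; half-pixel units of the original grid)
  mb <- upsample2_bilinear(m)
  sedt <- as.matrix(EBImage::distmap(mb * 1)) -
    as.matrix(EBImage::distmap((!mb) * 1))
  px <- skeleton$pixels
  nr <- 2L * skeleton$dims[1]; nc <- 2L * skeleton$dims[2]
  apex_at <- function(rb, cb) {
    val <- function(dr, dc) {
      r <- pmax(1L, pmin(nr, rb + dr))
      c <- pmax(1L, pmin(nc, cb + dc))
      sedt[cbind(r, c)]
    }
    e0 <- val(0L, 0L)
    # ridge apex from unit-slope line intersections on the four
    # opposing-neighbor axes; the cross-vessel axis attains the minimum
    axes <- cbind((val(-1L, 0L) + val(1L, 0L)) / 2 + 1,
                  (val(0L, -1L) + val(0L, 1L)) / 2 + 1,
                  (val(-1L, -1L) + val(1L, 1L)) / 2 + sqrt(2),
                  (val(-1L, 1L) + val(1L, -1L)) / 2 + sqrt(2))
    pmax(pmin(apply(axes, 1, min), e0 + 1), e0)
  }
  # each original pixel covers a 2x2 block in the upsampled grid; the
  # block pixel nearest the medial ridge carries the best estimate
  apex <- pmax(pmax(apex_at(2L * px[, "row"] - 1L, 2L * px[, "col"] - 1L),
                    apex_at(2L * px[, "row"] - 1L, 2L * px[, "col"])),
               pmax(apex_at(2L * px[, "row"], 2L * px[, "col"] - 1L),
                    apex_at(2L * px[, "row"], 2L * px[, "col"])))
  r_px <- edt_radius_calibrate(pmax(apex - 0.35, 0.4) / 2)
  skeleton$radius_px <- as.numeric(r_px)
  skeleton$radius_um <- as.numeric(r_px) * skeleton$scale_um_per_px
  skeleton
}

# Monotone recalibration of the apex radius estimate against rasterized
# tubes of known radius (0.6-10 px, angles 0-90 deg, random sub-pixel
# phases). The lookup inverts the measured response curve and is the
# identity at large radii.
edt_radius_calibrate <- function(est) {
  out <- approx(.radius_cal$est, .radius_cal$r, xout = est, rule = 2)$y
  big <- est > max(.radius_cal$est)
  out[big] <- est[big]
  out
}

.radius_cal <- list(
  est = c(0.438, 0.572, 0.771, 0.954, 1.390, 1.612, 1.708, 1.879, 1.973,
          2.335, 2.513, 2.651, 2.816, 3.388, 3.814, 4.795, 6.780, 9.762),
  r   = c(0.6, 0.8, 1.0, 1.2, 1.4, 1.6, 1.8, 2.0, 2.2,
          2.4, 2.6, 2.8, 3.0, 3.5, 4.0, 5.0, 7.0, 10.0))

#' Build a vessel graph from a skeleton
#'
#' Pixels with a number of 8-connected skeleton neighbors different from
#' two become node pixels (endpoints and junctions); 8-adjacent node
#' pixels are collapsed into a single node at their centroid (thinning
#' produces junction clusters). Maximal degree-2 paths between node
#' clusters become segments carrying the ordered centerline and per-point
#' radii. Pure cycles (components with no node pixel) are anchored at an
#' arbitrary pixel and kept as loop segments. Per segment, the arc length
#' is the measured centerline length, the chord is the Euclidean
#' endpoint distance, and the mean caliber is twice the mean radius; all
#' in micrometres.
#'
#' @param skeleton a `skeleton`, normally after [radius_from_distance()].
#' @return A `vessel_graph`: list with `nodes` (tibble: id, row, col,
#'   degree), `segments` (tibble: id, from, to, n_points, arc_um,
#'   chord_um, mean_caliber_um, and list-columns `points` (px) and
#'   `radius_um`), `scale_um_per_px`, `dims`.
#' @export
build_vessel_graph <- function(skeleton) {
  stopifnot(inherits(skeleton, "skeleton"))
  pix <- skeleton$pixels
  n <- nrow(pix)
  scale <- skeleton$scale_um_per_px
  rad <- skeleton$radius_um %||% rep(NA_real_, n)
  if (n == 0) return(empty_graph(skeleton))

  nr <- skeleton$dims[1]; nc <- skeleton$dims[2]
  enc <- (pix[, "col"] - 1L) * nr + pix[, "row"]
  lookup <- integer(nr * nc)
  lookup[enc] <- seq_len(n)
  offs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  nbmat <- matrix(0L, n, 8)
  for (k in 1:8) {
    rr <- pix[, "row"] + offs[k, 1]; cc <- pix[, "col"] + offs[k, 2]
    ok <- rr >= 1 & cc >= 1 & rr <= nr & cc <= nc
    e2 <- (cc[ok] - 1L) * nr + rr[ok]
    v <- integer(n)
    v[ok] <- lookup[e2]
    nbmat[, k] <- v
  }
  deg <- rowSums(nbmat > 0)
  is_node <- deg != 2

  # collapse 8-adjacent node pixels into clusters
  cluster <- integer(n)
  node_ids <- which(is_node)
  if (length(node_ids)) {
    edges <- NULL
    for (k in 1:8) {
      j <- nbmat[node_ids, k]
      keep <- j > 0 & is_node[pmax(j, 1L)]
      if (any(keep))
        edges <- rbind(edges, cbind(node_ids[keep], j[keep]))
    }
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(if (is.null(edges)) integer() else edges[, 1]),
                 to = as.character(if (is.null(edges)) integer() else edges[, 2])),
      directed = FALSE,
      vertices = data.frame(name = as.character(node_ids)))
    comp <- igraph::components(g)$membership
    cluster[node_ids] <- comp[as.character(node_ids)]
  }
  n_clusters <- if (length(node_ids)) max(cluster[node_ids]) else 0L

  neighbors_of <- function(i) {
    v <- nbmat[i, ]
    v[v > 0]
  }

  visited <- logical(n)     # marks internal (degree-2 non-node) pixels
  seg_list <- list()
  pair_seen <- character()

  add_segment <- function(path_ids, from_cluster, to_cluster) {
    pts <- cbind(x = pix[path_ids, "col"] - 0.5,
                 y = pix[path_ids, "row"] - 0.5)
    arc <- measure_arc_px(pts) * scale
    chord <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2)) * scale
    seg_list[[length(seg_list) + 1L]] <<- list(
      from = from_cluster, to = to_cluster,
      points = pts, radius_um = rad[path_ids],
      arc_um = arc, chord_um = chord,
      mean_caliber_um = 2 * mean(rad[path_ids]))
  }

  for (u in node_ids) {
    for (v in neighbors_of(u)) {
      if (is_node[v]) {
        if (cluster[v] == cluster[u]) next
        key <- paste(min(u, v), max(u, v))
        if (key %in% pair_seen) next
        pair_seen <- c(pair_seen, key)
        add_segment(c(u, v), cluster[u], cluster[v])
      } else {
        if (visited[v]) next
        path <- c(u, v)
        visited[v] <- TRUE
        prev <- u; cur <- v
        repeat {
          nbs <- neighbors_of(cur)
          nxt <- nbs[nbs != prev]
          if (length(nxt) == 0) break        # dead end (shouldn't occur)
          nxt <- nxt[1]
          path <- c(path, nxt)
          if (is_node[nxt]) break
          if (visited[nxt]) break            # guard against re-entry
          visited[nxt] <- TRUE
          prev <- cur; cur <- nxt
        }
        last <- path[length(path)]
        if (is_node[last])
          add_segment(path, cluster[u], cluster[last])
      }
    }
  }

  # pure cycles: components made only of degree-2 pixels
  leftover <- which(!visited & !is_node)
  for (a in leftover) {
    if (visited[a]) next
    n_clusters <- n_clusters + 1L
    cluster[a] <- n_clusters
    is_node[a] <- TRUE                       # anchor node
    nbs <- neighbors_of(a)
    if (length(nbs) == 0) next               # isolated pixel
    path <- c(a, nbs[1])
    visited[nbs[1]] <- TRUE
    prev <- a; cur <- nbs[1]
    repeat {
      nbs2 <- neighbors_of(cur)
      nxt <- nbs2[nbs2 != prev][1]
      if (is.na(nxt)) break
      path <- c(path, nxt)
      if (nxt == a) break
      visited[nxt] <- TRUE
      prev <- cur; cur <- nxt
    }
    add_segment(path, cluster[a], cluster[a])
  }

  # isolated single pixels become degree-0 nodes (handled via clusters)
  assemble_graph(seg_list, cluster, pix, is_node, scale, skeleton$dims)
}

empty_graph <- function(skeleton) {
  structure(list(
    nodes = tibble::tibble(id = integer(), row = numeric(), col = numeric(),
                           degree = integer()),
    segments = tibble::tibble(id = integer(), from = integer(),
                              to = integer(), n_points = integer(),
                              arc_um = numeric(), chord_um = numeric(),
                              mean_caliber_um = numeric(),
                              points = list(), radius_um = list()),
    scale_um_per_px = skeleton$scale_um_per_px,
    dims = skeleton$dims), class = "vessel_graph")
}

assemble_graph <- function(seg_list, cluster, pix, is_node, scale, dims) {
  used_clusters <- sort(unique(c(cluster[is_node & cluster > 0],
                                 vapply(seg_list, function(s)
                                   c(s$from, s$to), numeric(2)))))
  if (length(seg_list) == 0)
    used_clusters <- sort(unique(cluster[is_node & cluster > 0]))
  remap <- stats::setNames(seq_along(used_clusters), used_clusters)
  node_rows <- vapply(used_clusters, function(cl)
    mean(pix[cluster == cl & is_node, "row", drop = TRUE]), numeric(1))
  node_cols <- vapply(used_clusters, function(cl)
    mean(pix[cluster == cl & is_node, "col", drop = TRUE]), numeric(1))
  segs <- tibble::tibble(
    id = seq_along(seg_list),
    from = vapply(seg_list, function(s)
      unname(remap[as.character(s$from)]), numeric(1)),
    to = vapply(seg_list, function(s)
      unname(remap[as.character(s$to)]), numeric(1)),
    n_points = vapply(seg_list, function(s) nrow(s$points), numeric(1)),
    arc_um = vapply(seg_list, function(s) s$arc_um, numeric(1)),
    chord_um = vapply(seg_list, function(s) s$chord_um, numeric(1)),
    mean_caliber_um = vapply(seg_list, function(s) s$mean_caliber_um,
                             numeric(1)),
    points = lapply(seg_list, function(s) s$points),
    radius_um = lapply(seg_list, function(s) s$radius_um))
  nodes <- tibble::tibble(id = seq_along(used_clusters),
                          row = node_rows, col = node_cols,
                          degree = 0L)
  nodes$degree <- node_degrees(nodes, segs)
  structure(list(nodes = nodes, segments = segs,
                 scale_um_per_px = scale, dims = dims),
            class = "vessel_graph")
}

# degree lookup indexed by node id (positions beyond max id are zero)
deg_by_id <- function(segs, max_id) {
  if (max_id < 1) return(integer(0))
  as.integer(tabulate(c(segs$from, segs$to), nbins = max_id))
}

node_degrees <- function(nodes, segs) {
  if (nrow(nodes) == 0) return(integer(0))
  deg_by_id(segs, max(nodes$id))[nodes$id]
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat("<vessel_graph>", nrow(x$nodes), "nodes,", nrow(x$segments),
      "segments,", sum(x$nodes$degree == 3), "branching points\n")
  invisible(x)
}

#' Prune terminal spurs from a vessel graph
#'
#' Skeletonization leaves short terminal twigs at junctions that would
#' inflate branching-point counts. Terminal segments (at least one
#' endpoint of degree one) shorter than `min_length_um` are removed,
#' degrees are recomputed, and nodes left with degree two are merged so
#' their two incident segments become one; this repeats to a fixed point,
#' so the operation is idempotent at a fixed threshold. The default
#' 10 um is below capillary caliber and cannot remove a true branch.
#'
#' @param graph a `vessel_graph`.
#' @param min_length_um pruning threshold, um (0 leaves the graph
#'   unchanged).
#' @return The pruned `vessel_graph`.
#' @export
prune_spurs <- function(graph, min_length_um = 10) {
  stopifnot(inherits(graph, "vessel_graph"), min_length_um >= 0)
  if (min_length_um == 0) return(graph)
  repeat {
    changed <- FALSE
    # junction blobs can thin into tiny loops: a short self-loop, or two
    # short parallel paths between the same node pair. Drop the
    # redundant short path(s) so a single bifurcation is recovered.
    segs <- graph$segments
    drop <- segs$from == segs$to & segs$arc_um < min_length_um
    key <- paste(pmin(segs$from, segs$to), pmax(segs$from, segs$to))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k & segs$from != segs$to)
      if (length(idx) < 2) next
      idx <- idx[order(-segs$arc_um[idx])][-1]   # keep the longest
      drop[idx[segs$arc_um[idx] < min_length_um]] <- TRUE
    }
    if (any(drop)) {
      graph$segments <- segs[!drop, ]
      changed <- TRUE
    }
    degv <- deg_by_id(graph$segments, max(graph$nodes$id, 1L))
    graph$nodes$degree <- node_degrees(graph$nodes, graph$segments)
    term <- (degv[graph$segments$from] == 1 | degv[graph$segments$to] == 1) &
      graph$segments$arc_um < min_length_um &
      graph$segments$from != graph$segments$to
    if (any(term)) {
      graph$segments <- graph$segments[!term, ]
      changed <- TRUE
    }
    merged <- merge_degree2_nodes(graph)
    if (merged$changed) changed <- TRUE
    graph <- merged$graph
    # drop isolated nodes
    deg <- node_degrees(graph$nodes, graph$segments)
    keep <- deg > 0
    if (!all(keep) && nrow(graph$segments) > 0) {
      graph$nodes <- graph$nodes[keep, ]
      changed <- changed || any(!keep)
    }
    graph$nodes$degree <- node_degrees(graph$nodes, graph$segments)
    if (!changed) break
  }
  graph$segments$id <- seq_len(nrow(graph$segments))
  graph
}

merge_degree2_nodes <- function(graph) {
  changed <- FALSE
  repeat {
    deg <- node_degrees(graph$nodes, graph$segments)
    cand <- NULL
    for (nid in graph$nodes$id[deg == 2]) {
      inc <- which(graph$segments$from == nid | graph$segments$to == nid)
      if (length(inc) == 2 && inc[1] != inc[2]) { cand <- c(nid, inc); break }
    }
    if (is.null(cand)) break
    nid <- cand[1]; i1 <- cand[2]; i2 <- cand[3]
    s1 <- as.list(graph$segments[i1, ])
    s2 <- as.list(graph$segments[i2, ])
    p1 <- s1$points[[1]]; r1 <- s1$radius_um[[1]]
    p2 <- s2$points[[1]]; r2 <- s2$radius_um[[1]]
    if (s1$to != nid) { p1 <- p1[nrow(p1):1, , drop = FALSE]; r1 <- rev(r1) }
    if (s2$from != nid) { p2 <- p2[nrow(p2):1, , drop = FALSE]; r2 <- rev(r2) }
    from_new <- if (s1$to != nid) s1$to else s1$from
    to_new <- if (s2$from != nid) s2$from else s2$to
    pts <- rbind(p1, p2[-1, , drop = FALSE])
    rr <- c(r1, r2[-1])
    scale <- graph$scale_um_per_px
    newseg <- tibble::tibble(
      id = s1$id, from = from_new, to = to_new, n_points = nrow(pts),
      arc_um = measure_arc_px(pts) * scale,
      chord_um = sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2)) * scale,
      mean_caliber_um = 2 * mean(rr),
      points = list(pts), radius_um = list(rr))
    graph$segments <- rbind(graph$segments[-c(i1, i2), ], newseg)
    changed <- TRUE
  }
  list(graph = graph, changed = changed)
}

#' Split a vessel graph at a caliber threshold
#'
#' Partitions the segments into a large-vessel network (mean caliber
#' strictly above `threshold_um`) and a small-vessel network (at or below
#' it); every segment lands in exactly one subnetwork, so arc lengths are
#' conserved exactly. "Caliber" is the mean segment diameter (twice the
#' mean radius). Node degrees are recomputed within each subnetwork.
#'
#' @param graph a `vessel_graph` whose segments carry `mean_caliber_um`.
#' @param threshold_um caliber cut in um (20 by default).
#' @return List with components `large` and `small`, both `vessel_graph`s.
#' @export
split_by_caliber <- function(graph, threshold_um = 20) {
  stopifnot(inherits(graph, "vessel_graph"))
  big <- graph$segments$mean_caliber_um > threshold_um
  list(large = subgraph_from_segments(graph, which(big)),
       small = subgraph_from_segments(graph, which(!big)))
}

subgraph_from_segments <- function(graph, idx) {
  segs <- graph$segments[idx, ]
  keep_nodes <- graph$nodes$id %in% unique(c(segs$from, segs$to))
  nodes <- graph$nodes[keep_nodes, ]
  g <- structure(list(nodes = nodes, segments = segs,
                      scale_um_per_px = graph$scale_um_per_px,
                      dims = graph$dims), class = "vessel_graph")
  if (nrow(nodes)) g$nodes$degree <- node_degrees(nodes, segs)
  g
}

#' Bifurcation table of a vessel graph
#'
#' For every degree-3 node (branching point), identifies the parent as
#' the incident segment with the largest mean caliber (ties broken by
#' longer arc, then lower segment id — the deterministic rule this
#' package adopts, since parenthood is not defined by the degree rule
#' alone) and reports parent and daughter radii. Radii are taken as the
#' mean over the `near_frac` fraction of each segment's points closest to
#' the node, which avoids taper bias along long segments. Nodes of
#' degree four or more (crossing artifacts) are excluded.
#'
#' @param graph a `vessel_graph` with per-point radii.
#' @param near_frac fraction of points nearest the node used for the
#'   local radius (default 0.25).
#' @return Tibble with columns `node`, `parent_segment`,
#'   `parent_radius_um`, `d1_radius_um`, `d2_radius_um` (d1 >= d2).
#' @export
bifurcation_table <- function(graph, near_frac = 0.25) {
  stopifnot(inherits(graph, "vessel_graph"), near_frac > 0, near_frac <= 1)
  deg <- graph$nodes$degree
  out <- list()
  for (nid in graph$nodes$id[deg == 3]) {
    inc <- which(graph$segments$from == nid | graph$segments$to == nid)
    ends <- list()
    for (i in inc) {
      s <- graph$segments[i, ]
      at_from <- s$from == nid
      # a loop at the node contributes both of its ends
      reps <- if (s$from == nid && s$to == nid) c(TRUE, FALSE) else at_from
      for (af in reps) {
        r <- s$radius_um[[1]]
        if (!af) r <- rev(r)
        # skip the junction-overlap zone, where the union of the three
        # incident tubes inflates the distance transform: points within
        # the junction's own inscribed radius (+1 px) of the node
        scale <- graph$scale_um_per_px
        skip <- min(ceiling(r[1] / scale + 1), max(length(r) - 2L, 0L))
        r_use <- r[(skip + 1):length(r)]
        k <- max(1L, ceiling(near_frac * length(r_use)))
        near <- mean(r_use[seq_len(k)])
        ends[[length(ends) + 1L]] <- list(
          seg = s$id, near_radius = near,
          caliber = s$mean_caliber_um, arc = s$arc_um)
      }
    }
    if (length(ends) != 3) next
    cal <- vapply(ends, function(e) e$caliber, numeric(1))
    arc <- vapply(ends, function(e) e$arc, numeric(1))
    sid <- vapply(ends, function(e) e$seg, numeric(1))
    ord <- order(-cal, -arc, sid)
    parent <- ends[[ord[1]]]
    d <- sort(vapply(ends[ord[2:3]], function(e) e$near_radius, numeric(1)),
              decreasing = TRUE)
    out[[length(out) + 1L]] <- tibble::tibble(
      node = nid, parent_segment = parent$seg,
      parent_radius_um = parent$near_radius,
      d1_radius_um = d[1], d2_radius_um = d[2])
  }
  if (length(out)) do.call(rbind, out)
  else tibble::tibble(node = numeric(), parent_segment = numeric(),
                      parent_radius_um = numeric(),
                      d1_radius_um = numeric(), d2_radius_um = numeric())
}

#' Full mask-to-graph pipeline
#'
#' [skeletonize()], [radius_from_distance()], [build_vessel_graph()] and
#' [prune_spurs()] in one call.
#'
#' @param mask a [vessel_mask()].
#' @param prune_um spur-pruning threshold, um.
#' @return A pruned `vessel_graph`.
#' @export
mask_to_graph <- function(mask, prune_um = 10) {
  sk <- skeletonize(mask)
  sk <- radius_from_distance(mask, sk)
  g <- build_vessel_graph(sk)
  prune_spurs(g, prune_um)
}
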