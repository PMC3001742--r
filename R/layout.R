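# Fruchterman-Reingold force-directed layout in 2D and 3D, with
# degree-proportional node radii and sign-colored edges, plus exporters.

#' Fruchterman-Reingold layout of a signed bipartite network
#'
#' Force-directed layout in 2 or 3 dimensions: attraction `d^2 / kappa`
#' along edges, repulsion `kappa^2 / d` between all node pairs, with
#' `kappa = C * (volume / n)^(1/dims)` (unit volume) and the maximum
#' per-node displacement cooled linearly to zero over the iteration budget.
#' Shared high-degree genes are pulled toward the centre of the layout;
#' disease-specific genes are pushed to the periphery. Deterministic given
#' `seed` (random initial placement from the seeded stream).
#'
#' @param net a `signed_bipartite` network with >= 1 node.
#' @param dims 2 or 3.
#' @param iterations number of iterations (default 500).
#' @param seed optional seed.
#' @param C optimal-distance constant (default 0.9).
#' @param t0 initial temperature: maximum displacement per iteration, in
#'   box units (default 0.1).
#' @param rescale if `TRUE` (default) final coordinates are rescaled to the
#'   unit square/cube per axis; `FALSE` returns raw coordinates (useful for
#'   inspecting force-balance distances).
#' @param r_min,r_max node radius range; radius is the affine map
#'   `r_min + (r_max - r_min) * degree / max(degree)`.
#' @return An object of class `fr_layout`: `coords` (matrix, one row per
#'   node, rownames = node ids), `node_radius`, `edge_color` (`"yellow"` =
#'   up, `"blue"` = down, named by `disease|gene`), `dims`, `iterations`,
#'   `seed`, `kappa`.
#' @export
fr_layout <- function(net, dims = 2, iterations = 500, seed = NULL,
                      C = 0.9, t0 = 0.1, rescale = TRUE,
                      r_min = 0.005, r_max = 0.05) {
  stopifnot(dims %in% c(2, 3), iterations >= 1, r_max > r_min, r_min > 0)
  ids <- c(net$diseases, net$genes)
  n <- length(ids)
  if (n < 1) stop("network has no nodes", call. = FALSE)

  pos <- with_seed(seed, {
    if (n == 1) {
      matrix(0.5, 1, dims)  # no forces act; centre of the box
    } else {
      idx <- setNames(seq_len(n), ids)
      fr_layout_cpp(n, unname(idx[net$edges$disease]),
                    unname(idx[net$edges$gene]),
                    as.integer(dims), as.integer(iterations), C, t0)
    }
  })
  if (rescale) {
    for (c in seq_len(dims)) {
      rng <- range(pos[, c])
      pos[, c] <- if (diff(rng) > 0) (pos[, c] - rng[1]) / diff(rng) else 0.5
    }
  }
  rownames(pos) <- ids
  colnames(pos) <- c("x", "y", "z")[seq_len(dims)]

  deg <- c(degree_table(net)$disease_degree, degree_table(net)$gene_degree)[ids]
  dmax <- max(deg, 1)
  radius <- r_min + (r_max - r_min) * deg / dmax

  ecol <- ifelse(net$edges$sign == "up", "yellow", "blue")
  names(ecol) <- paste(net$edges$disease, net$edges$gene, sep = "|")

  structure(list(coords = pos, node_radius = radius, edge_color = ecol,
                 dims = dims, iterations = iterations, seed = seed,
                 kappa = C * (1 / n)^(1 / dims)),
            class = "fr_layout")
}

#' @export
print.fr_layout <- function(x, ...) {
  cat(sprintf("%dD Fruchterman-Reingold layout: %d nodes, %d iterations\n",
              x$dims, nrow(x$coords), x$iterations))
  invisible(x)
}

#' Centre-periphery score of a layout
#'
#' Spearman rank correlation between gene degree and the gene's distance
#' from the centroid of the disease nodes. Negative values mean shared
#' (high-degree) genes sit nearer the centre and disease-specific genes at
#' the periphery — the behaviour expected of force-directed layouts of
#' these networks.
#'
#' @param layout an `fr_layout`.
#' @param net the network it was computed from (>= 3 genes, >= 2 distinct
#'   gene degrees).
#' @return The rank correlation (in `[-1, 1]`).
#' @export
centre_periphery_score <- function(layout, net) {
  if (length(net$genes) < 3)
    stop("need at least 3 genes", call. = FALSE)
  gd <- degree_table(net)$gene_degree
  if (length(unique(gd)) < 2)
    stop("gene degrees are constant: score undefined", call. = FALSE)
  centroid <- colMeans(layout$coords[net$diseases, , drop = FALSE])
  gpos <- layout$coords[net$genes, , drop = FALSE]
  dist <- sqrt(rowSums(sweep(gpos, 2, centroid)^2))
  if (var(dist) == 0)
    stop("gene distances are constant: score undefined", call. = FALSE)
  cor(as.numeric(gd[net$genes]), dist, method = "spearman")
}

# FR energy proxy: sum of edge attractive potentials d^3/(3 kappa) and
# pairwise repulsive potentials -kappa^2 log(d).
fr_energy <- function(coords, net, kappa) {
  ids <- rownames(coords)
  D <- as.matrix(stats::dist(coords))
  D[D < 1e-9] <- 1e-9
  rep_e <- -kappa^2 * sum(log(D[upper.tri(D)]))
  ii <- match(net$edges$disease, ids)
  jj <- match(net$edges$gene, ids)
  d <- sqrt(rowSums((coords[ii, , drop = FALSE] -
                       coords[jj, , drop = FALSE])^2))
  att_e <- sum(d^3) / (3 * kappa)
  rep_e + att_e
}

#' Export a layout for external viewers
#'
#' `pajek_net`: a Pajek `.net` (+ `.clu` partition) embedding per-vertex
#' x y z coordinates (2D layouts are written with z = 0.5 and a `%` comment
#' line flagging `dims=2`). `csv`: a node table
#' (`node_id,class,degree,x,y,z,radius`) at `path` and an edge table
#' (`disease,gene,sign,color`) at `path` with an `_edges` suffix. Both
#' round-trip through [read_pajek()] / [read_edge_list()].
#'
#' @param net a `signed_bipartite` network.
#' @param layout the `fr_layout` for it.
#' @param path output path.
#' @param format `"pajek_net"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_layout <- function(net, layout, path, format = c("pajek_net", "csv")) {
  if (!is.character(format) || !all(format %in% c("pajek_net", "csv")))
    stop("unknown format: ", paste(setdiff(format, c("pajek_net", "csv")),
                                   collapse = ", "), call. = FALSE)
  format <- match.arg(format)
  co <- layout$coords
  if (layout$dims == 2) co <- cbind(co, z = 0.5)

  if (format == "pajek_net") {
    comment <- c(sprintf("dims=%d", layout$dims),
                 sprintf("iterations=%d", layout$iterations))
    write_pajek(net, path, coords = co, comment = comment)
  } else {
    ids <- c(net$diseases, net$genes)
    deg <- c(degree_table(net)$disease_degree,
             degree_table(net)$gene_degree)[ids]
    nodes <- data.frame(
      node_id = ids,
      class = rep(c("disease", "gene"),
                  c(length(net$diseases), length(net$genes))),
      degree = as.integer(deg),
      x = co[ids, 1], y = co[ids, 2], z = co[ids, 3],
      radius = as.numeric(layout$node_radius[ids]))
    write.table(nodes, path, sep = ",", row.names = FALSE, quote = FALSE)
    edges <- cbind(net$edges,
                   color = unname(layout$edge_color[
                     paste(net$edges$disease, net$edges$gene, sep = "|")]))
    epath <- sub("(\\.[A-Za-z]+)?$", "_edges\\1", path)
    if (identical(epath, path)) epath <- paste0(path, "_edges")
    write.table(edges, epath, sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Plot the down-regulation curve with its envelope
#'
#' Observed curve (solid, points) with the lower/upper Monte-Carlo envelope
#' bounds (dashed); points outside the envelope are highlighted.
#'
#' @param x a `curve_envelope`.
#' @param ... passed to `plot`.
#' @return `x`, invisibly.
#' @importFrom graphics lines points legend
#' @export
plot.curve_envelope <- function(x, ...) {
  e <- x$envelope
  plot(e$degree, e$observed, type = "b", pch = 19, ylim = c(0, 1),
       xlab = "Gene degree", ylab = "Proportion of down-regulated edges",
       main = sprintf("Observed curve vs. %.1f%% null envelope",
                      100 * x$level), ...)
  lines(e$degree, e$lower, lty = 2)
  lines(e$degree, e$upper, lty = 2)
  if (any(e$outside))
    points(e$degree[e$outside], e$observed[e$outside], pch = 1, cex = 2,
           col = "red")
  legend("topleft", lty = c(1, 2), pch = c(19, NA),
         legend = c("observed", "envelope"), bty = "n")
  invisible(x)
}

#' Plot a layout (2D projection)
#'
#' Nodes at their layout coordinates (x, y), radii proportional to degree,
#' diseases as squares, genes as circles; edges colored yellow (up) / blue
#' (down). 3D layouts are projected onto the x-y plane.
#'
#' @param x an `fr_layout`.
#' @param net the network it was computed from.
#' @param ... passed to `plot`.
#' @return `x`, invisibly.
#' @importFrom graphics segments symbols
#' @export
plot.fr_layout <- function(x, net, ...) {
  co <- x$coords
  plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "x", ylab = "y",
       asp = 1, ...)
  key <- paste(net$edges$disease, net$edges$gene, sep = "|")
  segments(co[net$edges$disease, 1], co[net$edges$disease, 2],
           co[net$edges$gene, 1], co[net$edges$gene, 2],
           col = ifelse(x$edge_color[key] == "yellow", "gold", "blue"))
  symbols(co[net$genes, 1], co[net$genes, 2],
          circles = x$node_radius[net$genes], inches = FALSE, add = TRUE,
          bg = "black")
  symbols(co[net$diseases, 1], co[net$diseases, 2],
          squares = 2 * x$node_radius[net$diseases], inches = FALSE,
          add = TRUE, bg = "white")
  invisible(x)
}
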