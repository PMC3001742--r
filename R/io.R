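# Readers and writers: Pajek .net (+ .clu partition sidecar) and delimited
# edge lists.
#
# Pajek has no native edge sign, so regulation is carried as the integer
# edge value: 1 = up, 2 = down. The disease/gene partition is carried as
# class 1 = disease, 2 = gene, either in a "*Partition" block appended to
# the .net file or in a companion .clu file. Coordinates (normalized to
# [0,1] per axis) are written with 6 decimal places.

PAJEK_SIGN_TO_VALUE <- c(up = 1L, down = 2L)

clu_path_for <- function(path) {
  if (grepl("\\.net$", path, ignore.case = TRUE))
    sub("\\.net$", ".clu", path, ignore.case = TRUE)
  else paste0(path, ".clu")
}

#' Write a network as Pajek .net (+ .clu partition)
#'
#' Vertices are written diseases first, then genes, 1-based, with quoted
#' labels; edges carry sign as value 1 (up) / 2 (down). The node class
#' (1 = disease, 2 = gene) goes to a companion `.clu` file (default), or an
#' inline `*Partition` block.
#'
#' @param net a `signed_bipartite` network.
#' @param path output `.net` path.
#' @param coords optional numeric matrix of per-vertex coordinates (2 or 3
#'   columns, values in `[0,1]`), with rownames naming the nodes. Two-column
#'   input is written with z = 0.5 (Pajek plane convention).
#' @param partition `"clu"` (sidecar file next to `path`) or `"inline"`.
#' @param comment optional character lines written first, `%`-prefixed.
#' @return `path`, invisibly.
#' @export
write_pajek <- function(net, path, coords = NULL,
                        partition = c("clu", "inline"), comment = NULL) {
  partition <- match.arg(partition)
  validate_signed_bipartite(net)
  ids <- c(net$diseases, net$genes)
  n <- length(ids)

  vlines <- sprintf("%d \"%s\"", seq_len(n), ids)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (is.null(rownames(coords)) || !all(ids %in% rownames(coords)))
      stop("`coords` must have rownames covering every node", call. = FALSE)
    coords <- coords[ids, , drop = FALSE]
    if (!ncol(coords) %in% c(2L, 3L))
      stop("`coords` must have 2 or 3 columns", call. = FALSE)
    z <- if (ncol(coords) == 3L) coords[, 3] else rep(0.5, n)
    vlines <- sprintf("%s %.6f %.6f %.6f", vlines, coords[, 1], coords[, 2], z)
  }

  idx <- setNames(seq_len(n), ids)
  e <- net$edges
  elines <- sprintf("%d %d %d", idx[e$disease], idx[e$gene],
                    PAJEK_SIGN_TO_VALUE[e$sign])

  out <- c(if (!is.null(comment)) paste0("% ", comment),
           sprintf("*Vertices %d", n), vlines, "*Edges", elines)
  cls <- rep(1:2, c(length(net$diseases), length(net$genes)))
  if (partition == "inline") {
    out <- c(out, sprintf("*Partition class %d", n), sprintf("%d", cls))
    writeLines(out, path)
  } else {
    writeLines(out, path)
    writeLines(c(sprintf("*Vertices %d", n), sprintf("%d", cls)),
               clu_path_for(path))
  }
  invisible(path)
}

#' Read a Pajek .net network (with partition)
#'
#' Requires a `*Vertices` and an `*Edges` section; the disease/gene classes
#' come from an inline `*Partition` block or the companion `.clu` file.
#' `%`-prefixed comment lines are ignored. Edge values 1/2 decode to
#' up/down regulation.
#'
#' @param path `.net` file path.
#' @param clu optional explicit `.clu` path (default: `path` with `.clu`
#'   extension, if it exists).
#' @return A `signed_bipartite` network. If the file carries vertex
#'   coordinates, they are attached as `attr(net, "coords")` (matrix, one
#'   row per node).
#' @export
read_pajek <- function(path, clu = NULL) {
  lines <- readLines(path)
  strip <- trimws(lines)
  keep <- !grepl("^%", strip) & nzchar(strip)
  lineno <- which(keep)
  strip <- strip[keep]

  hdr <- grepl("^\\*", strip)
  vsec <- grep("^\\*vertices", strip, ignore.case = TRUE)
  esec <- grep("^\\*edges", strip, ignore.case = TRUE)
  psec <- grep("^\\*partition", strip, ignore.case = TRUE)
  if (length(vsec) != 1 || length(esec) != 1)
    stop("Pajek file needs one *Vertices and one *Edges section", call. = FALSE)

  nv <- as.integer(sub("^\\*vertices\\s+(\\d+).*$", "\\1", strip[vsec],
                       ignore.case = TRUE))
  sec_starts <- sort(c(which(hdr), length(strip) + 1L))
  sec_end <- function(i) sec_starts[which(sec_starts == i) + 1L] - 1L

  # vertices
  vrows <- if (vsec + 1 <= sec_end(vsec)) (vsec + 1):sec_end(vsec) else integer(0)
  labels <- character(nv)
  coords <- matrix(NA_real_, nv, 3)
  num <- "[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?"
  vre <- paste0("^(\\d+)\\s+\"([^\"]*)\"(?:\\s+(", num, ")\\s+(", num,
                ")(?:\\s+(", num, "))?)?\\s*$")
  for (i in vrows) {
    m <- regmatches(strip[i], regexec(vre, strip[i]))[[1]]
    if (length(m) == 0)
      stop(sprintf("cannot parse vertex line %d: %s", lineno[i], strip[i]),
           call. = FALSE)
    id <- as.integer(m[2])
    if (id < 1 || id > nv)
      stop(sprintf("vertex index %d out of range at line %d", id, lineno[i]),
           call. = FALSE)
    labels[id] <- m[3]
    if (nzchar(m[4])) {
      coords[id, 1] <- as.numeric(m[4])
      coords[id, 2] <- as.numeric(m[5])
      coords[id, 3] <- if (nzchar(m[6])) as.numeric(m[6]) else 0.5
    }
  }

  # edges
  erows <- if (esec + 1 <= sec_end(esec)) (esec + 1):sec_end(esec) else integer(0)
  ei <- ej <- ev <- integer(length(erows))
  for (k in seq_along(erows)) {
    i <- erows[k]
    parts <- strsplit(strip[i], "\\s+")[[1]]
    if (length(parts) < 3 || anyNA(suppressWarnings(as.integer(parts[1:3]))))
      stop(sprintf("cannot parse edge line %d: %s", lineno[i], strip[i]),
           call. = FALSE)
    v <- as.integer(parts[1:3])
    if (v[1] < 1 || v[1] > nv || v[2] < 1 || v[2] > nv)
      stop(sprintf("edge references undefined vertex at line %d: %s",
                   lineno[i], strip[i]), call. = FALSE)
    if (!v[3] %in% PAJEK_SIGN_TO_VALUE)
      stop(sprintf("unknown edge value %d at line %d (expected 1=up, 2=down)",
                   v[3], lineno[i]), call. = FALSE)
    ei[k] <- v[1]; ej[k] <- v[2]; ev[k] <- v[3]
  }

  # partition: inline block, else sidecar .clu
  cls <- NULL
  if (length(psec) == 1) {
    prows <- if (psec + 1 <= sec_end(psec)) (psec + 1):sec_end(psec) else integer(0)
    cls <- as.integer(strip[prows])
  } else {
    clu <- clu %||% clu_path_for(path)
    if (!file.exists(clu))
      stop("no node class information: expected a *Partition block or a ",
           "partition file at ", clu,
           " (class 1 = disease, 2 = gene)", call. = FALSE)
    cl <- trimws(readLines(clu))
    cl <- cl[nzchar(cl) & !grepl("^%", cl)]
    cl <- cl[!grepl("^\\*", cl)]
    cls <- as.integer(cl)
  }
  if (length(cls) != nv || !all(cls %in% 1:2))
    stop("partition must assign class 1 (disease) or 2 (gene) to each of the ",
         nv, " vertices", call. = FALSE)

  is_dis <- cls == 1L
  sign_of <- names(PAJEK_SIGN_TO_VALUE)[ev]
  # edges must run disease -> gene (either orientation in the file)
  d_end <- ifelse(is_dis[ei], ei, ej)
  g_end <- ifelse(is_dis[ei], ej, ei)
  if (any(is_dis[d_end] == FALSE) || any(is_dis[g_end]))
    stop("edge joining two vertices of the same class", call. = FALSE)

  edges <- data.frame(disease = labels[d_end], gene = labels[g_end],
                      sign = sign_of, stringsAsFactors = FALSE)
  net <- build_network(edges, diseases = labels[is_dis], genes = labels[!is_dis])
  if (any(!is.na(coords[, 1]))) {
    rownames(coords) <- labels
    colnames(coords) <- c("x", "y", "z")
    attr(net, "coords") <- coords[c(net$diseases, net$genes), , drop = FALSE]
  }
  net
}

#' Write a delimited edge list
#'
#' Three columns `disease,gene,sign` with a header row.
#'
#' @param net a `signed_bipartite` network.
#' @param path output path.
#' @param sep field separator (`","` or `"\t"`).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, sep = ",") {
  write.table(net$edges, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a delimited edge list
#'
#' Expects a header; columns `disease`, `gene`, `sign` by name, or the first
#' three columns. Separator auto-detected (tab if the header contains one,
#' else comma) unless given.
#'
#' @param path input path.
#' @param sep optional separator.
#' @return A `signed_bipartite` network.
#' @export
read_edge_list <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  build_network(df)
}
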