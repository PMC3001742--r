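# Signed bipartite disease-gene networks.
#
# The central object: two node classes (diseases, genes) and signed edges,
# one per (disease, gene) pair, where the sign records whether the gene is
# up- or down-regulated in that disease.

SIGN_LEVELS <- c("up", "down")

# Low-level constructor; assumes inputs already validated.
new_signed_bipartite <- function(diseases, genes, edges) {
  edges$disease <- as.character(edges$disease)
  edges$gene <- as.character(edges$gene)
  edges$sign <- as.character(edges$sign)
  rownames(edges) <- NULL
  structure(
    list(diseases = as.character(diseases),
         genes = as.character(genes),
         edges = edges[, c("disease", "gene", "sign")]),
    class = "signed_bipartite"
  )
}

#' Build a signed bipartite disease-gene network
#'
#' Constructs the network from (disease, gene, sign) triples. Edges join a
#' disease to a gene only; the sign is `"up"` or `"down"` (whether the gene
#' is up- or down-regulated in that disease). Node ordering follows first
#' appearance in the triples.
#'
#' @param edges a data.frame (or coercible) with columns `disease`, `gene`,
#'   `sign` (the first three columns are used if unnamed).
#' @param diseases,genes optional character vectors of node identifiers; any
#'   identifiers appearing in `edges` are appended in order of first
#'   appearance. Use these to declare isolated (degree-0) nodes.
#' @return An object of class `signed_bipartite`: a list with character
#'   vectors `diseases` and `genes` and a data.frame `edges`.
#' @details Duplicate (disease, gene) pairs are an error, whether the signs
#'   conflict or repeat: the study design admits a single regulation relation
#'   per pair. An identifier may not appear in both node classes.
#' @examples
#' net <- build_network(data.frame(
#'   disease = c("D1", "D1", "D2", "D2"),
#'   gene    = c("g1", "g2", "g2", "g3"),
#'   sign    = c("up", "down", "down", "up")))
#' net
#' @export
build_network <- function(edges, diseases = character(), genes = character()) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0 &&
      !all(c("disease", "gene", "sign") %in% names(edges))) {
    if (ncol(edges) < 3)
      stop("`edges` needs columns disease, gene, sign", call. = FALSE)
    names(edges)[1:3] <- c("disease", "gene", "sign")
  }
  if (nrow(edges) == 0)
    edges <- data.frame(disease = character(), gene = character(),
                        sign = character(), stringsAsFactors = FALSE)
  edges$disease <- as.character(edges$disease)
  edges$gene <- as.character(edges$gene)
  edges$sign <- as.character(edges$sign)

  if (any(!nzchar(edges$disease)) || any(!nzchar(edges$gene)) ||
      anyNA(edges$disease) || anyNA(edges$gene))
    stop("node identifiers must be non-empty strings", call. = FALSE)
  bad_sign <- !(edges$sign %in% SIGN_LEVELS)
  if (any(bad_sign))
    stop("edge signs must be \"up\" or \"down\"; found: ",
         paste(unique(edges$sign[bad_sign]), collapse = ", "), call. = FALSE)

  diseases <- unique(c(as.character(diseases), edges$disease))
  genes <- unique(c(as.character(genes), edges$gene))

  both <- intersect(diseases, genes)
  if (length(both) > 0)
    stop("identifier(s) appear in both node classes: ",
         paste(both, collapse = ", "), call. = FALSE)

  pair <- paste(edges$disease, edges$gene, sep = "\r")
  if (anyDuplicated(pair)) {
    d <- pair[duplicated(pair)][1]
    ids <- strsplit(d, "\r", fixed = TRUE)[[1]]
    signs <- edges$sign[pair == d]
    kind <- if (length(unique(signs)) > 1) "conflicting signs" else "repeated edge"
    stop(sprintf("duplicate (disease, gene) pair (%s, %s): %s",
                 ids[1], ids[2], kind), call. = FALSE)
  }

  validate_signed_bipartite(new_signed_bipartite(diseases, genes, edges))
}

# Full invariant check; returns the network invisibly-validated.
validate_signed_bipartite <- function(net) {
  stopifnot(inherits(net, "signed_bipartite"))
  e <- net$edges
  if (anyDuplicated(net$diseases) || anyDuplicated(net$genes) ||
      length(intersect(net$diseases, net$genes)) > 0)
    stop("node identifiers must be unique across both classes", call. = FALSE)
  if (!all(e$disease %in% net$diseases))
    stop("edge references unknown disease", call. = FALSE)
  if (!all(e$gene %in% net$genes))
    stop("edge references unknown gene", call. = FALSE)
  if (!all(e$sign %in% SIGN_LEVELS))
    stop("invalid edge sign", call. = FALSE)
  if (anyDuplicated(paste(e$disease, e$gene, sep = "\r")))
    stop("duplicate (disease, gene) pair", call. = FALSE)
  net
}

#' Number of edges of a network
#' @param net a `signed_bipartite` network.
#' @return Integer edge count.
#' @export
n_edges <- function(net) nrow(net$edges)

#' @export
print.signed_bipartite <- function(x, ...) {
  e <- x$edges
  cat(sprintf("Signed bipartite network: %d diseases, %d genes, %d edges (%d up, %d down)\n",
              length(x$diseases), length(x$genes), nrow(e),
              sum(e$sign == "up"), sum(e$sign == "down")))
  invisible(x)
}

#' Degree accounting for a signed bipartite network
#'
#' Edge-incidence counts per node and the gene degree distribution. Genes of
#' degree 0 (declared but unconnected) appear in `gene_degree` but are
#' excluded from `gene_degree_distribution`, which describes the connected
#' (differentially regulated) genes the analyses consume.
#'
#' @param net a `signed_bipartite` network.
#' @return A list of class `degree_table`: named integer vectors
#'   `gene_degree` and `disease_degree`, and `gene_degree_distribution`
#'   (named counts, names = degree).
#' @export
degree_table <- function(net) {
  gd <- setNames(integer(length(net$genes)), net$genes)
  dd <- setNames(integer(length(net$diseases)), net$diseases)
  if (nrow(net$edges) > 0) {
    tg <- table(net$edges$gene)
    td <- table(net$edges$disease)
    gd[names(tg)] <- as.integer(tg)
    dd[names(td)] <- as.integer(td)
  }
  pos <- gd[gd > 0]
  dist <- if (length(pos) > 0) {
    tb <- table(pos)
    setNames(as.integer(tb), names(tb))
  } else setNames(integer(0), character(0))
  structure(list(gene_degree = gd, disease_degree = dd,
                 gene_degree_distribution = dist),
            class = "degree_table")
}

#' @export
print.degree_table <- function(x, ...) {
  cat("Degree table\n")
  cat("  disease degrees:",
      paste(sprintf("%s=%d", names(x$disease_degree), x$disease_degree),
            collapse = " "), "\n")
  cat("  gene degree distribution:",
      paste(sprintf("k=%s: %d", names(x$gene_degree_distribution),
                    x$gene_degree_distribution), collapse = ", "), "\n")
  invisible(x)
}

# Canonical edge ordering, used for comparisons (not for storage).
sorted_edges <- function(net) {
  e <- net$edges
  e[order(e$disease, e$gene), , drop = FALSE]
}

#' Test two networks for equality up to edge order
#' @param a,b `signed_bipartite` networks.
#' @return Logical.
#' @export
same_network <- function(a, b) {
  ea <- sorted_edges(a); eb <- sorted_edges(b)
  setequal(a$diseases, b$diseases) && setequal(a$genes, b$genes) &&
    nrow(ea) == nrow(eb) &&
    all(ea$disease == eb$disease) && all(ea$gene == eb$gene) &&
    all(ea$sign == eb$sign)
}
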