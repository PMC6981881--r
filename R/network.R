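#' Assemble the miRNA-gene-lincRNA regulatory network
#'
#' One directed \code{represses} edge per (miRNA, target) prediction and one
#' undirected \code{coexpressed} edge (weight = r) per retained
#' (lincRNA, gene) pair.  Duplicate edges are collapsed; self-edges are
#' impossible by construction because node namespaces are typed.
#'
#' @param focalGene id of the focal gene.
#' @param mirnaTargets data.frame with columns \code{mirna}, \code{target}
#'   (e.g. derived from \code{\link{scanTranscripts}} output).
#' @param lincrnaPairs data.frame with columns \code{lncrna_id},
#'   \code{gene_id}, \code{r} (output of \code{\link{transCandidates}}).
#' @return a \linkS4class{RegulatoryNetwork}.
#' @export
buildNetwork <- function(focalGene, mirnaTargets = NULL, lincrnaPairs = NULL) {
    edges <- data.frame(from = character(), to = character(),
                        type = character(), weight = numeric(),
                        stringsAsFactors = FALSE)
    if (!is.null(mirnaTargets) && nrow(mirnaTargets)) {
        e <- unique(data.frame(from = mirnaTargets$mirna,
                               to = mirnaTargets$target,
                               type = "represses", weight = NA_real_,
                               stringsAsFactors = FALSE))
        edges <- rbind(edges, e)
    }
    if (!is.null(lincrnaPairs) && nrow(lincrnaPairs)) {
        a <- pmin(lincrnaPairs$lncrna_id, lincrnaPairs$gene_id)
        b <- pmax(lincrnaPairs$lncrna_id, lincrnaPairs$gene_id)
        e <- data.frame(from = a, to = b, type = "coexpressed",
                        weight = lincrnaPairs$r, stringsAsFactors = FALSE)
        e <- e[!duplicated(e[, c("from", "to", "type")]), , drop = FALSE]
        edges <- rbind(edges, e)
    }
    if (!nrow(edges)) {
        warning("no input edges: returning an empty network")
        g <- igraph::make_empty_graph(directed = TRUE)
        return(new("RegulatoryNetwork", graph = g))
    }
    type <- character(0)
    mirs <- unique(mirnaTargets$mirna)
    lincs <- unique(lincrnaPairs$lncrna_id)
    nodes <- unique(c(edges$from, edges$to))
    nodeType <- ifelse(nodes %in% mirs, "miRNA",
                       ifelse(nodes %in% lincs, "lincRNA", "mRNA"))
    g <- igraph::graph_from_data_frame(
        edges, directed = TRUE,
        vertices = data.frame(name = nodes, type = nodeType,
                              stringsAsFactors = FALSE))
    igraph::E(g)$directed <- edges$type == "represses"
    new("RegulatoryNetwork", graph = g)
}

#' @rdname accessors
#' @export
setMethod("networkGraph", "RegulatoryNetwork", function(x) x@graph)

#' @rdname accessors
#' @export
setMethod("nodeTable", "RegulatoryNetwork", function(x) {
    g <- x@graph
    if (!igraph::vcount(g))
        return(data.frame(name = character(), type = character(),
                          stringsAsFactors = FALSE))
    data.frame(name = igraph::V(g)$name, type = igraph::V(g)$type,
               stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("edgeTable", "RegulatoryNetwork", function(x) {
    g <- x@graph
    if (!igraph::ecount(g))
        return(data.frame(from = character(), to = character(),
                          type = character(), weight = numeric(),
                          stringsAsFactors = FALSE))
    e <- igraph::as_data_frame(g, what = "edges")
    data.frame(from = e$from, to = e$to, type = e$type,
               weight = e$weight, stringsAsFactors = FALSE)
})

setMethod("show", "RegulatoryNetwork", function(object) {
    g <- object@graph
    cat(sprintf("RegulatoryNetwork: %d nodes, %d edges\n",
                igraph::vcount(g), igraph::ecount(g)))
    if (igraph::vcount(g)) {
        tt <- table(igraph::V(g)$type)
        cat("  nodes:", paste(sprintf("%s %s", tt, names(tt)),
                              collapse = ", "), "\n")
    }
    if (igraph::ecount(g)) {
        te <- table(igraph::E(g)$type)
        cat("  edges:", paste(sprintf("%s %s", te, names(te)),
                              collapse = ", "), "\n")
    }
})

#' Rebuild a network from its exported node and edge tables
#'
#' Inverse of \code{\link{nodeTable}}/\code{\link{edgeTable}}; rebuilding
#' from an export reproduces an isomorphic graph.
#'
#' @param nodes data.frame (\code{name}, \code{type}).
#' @param edges data.frame (\code{from}, \code{to}, \code{type},
#'   \code{weight}).
#' @return a \linkS4class{RegulatoryNetwork}.
#' @export
networkFromTables <- function(nodes, edges) {
    if (!nrow(nodes)) {
        return(new("RegulatoryNetwork",
                   graph = igraph::make_empty_graph(directed = TRUE)))
    }
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = nodes)
    igraph::E(g)$directed <- edges$type == "represses"
    new("RegulatoryNetwork", graph = g)
}

#' Write a network as GraphML
#'
#' @param net a \linkS4class{RegulatoryNetwork}.
#' @param path output file.
#' @export
writeGraphML <- function(net, path) {
    igraph::write_graph(networkGraph(net), path, format = "graphml")
    invisible(path)
}

#' Candidate competing endogenous RNAs of a focal gene
#'
#' Genes targeted by the focal gene's miRNA(s), excluding the focal gene
#' itself, flagged \code{same_cluster_as_focal} when their expression
#' cluster label equals the focal gene's ("similar expression pattern" is
#' operationalized as same-cluster membership at the configured cut).
#'
#' @param focalGene focal gene id (must carry a cluster label).
#' @param mirnaTargets data.frame (\code{mirna}, \code{target}).
#' @param clusterLabels named vector of cluster labels from
#'   \code{\link{clusterProfiles}}.
#' @param annotation optional data.frame (\code{gene_id}, \code{label})
#'   of free-text functional annotations.
#' @return data.frame with \code{gene_id}, \code{shared_mirna},
#'   \code{same_cluster_as_focal}, \code{annotation_label}.
#' @export
cernaCandidates <- function(focalGene, mirnaTargets, clusterLabels,
                            annotation = NULL) {
    if (!focalGene %in% names(clusterLabels))
        stop(sprintf("focal gene '%s' has no cluster label", focalGene))
    focalCluster <- clusterLabels[[focalGene]]
    sharedMirs <- unique(mirnaTargets$mirna[mirnaTargets$target == focalGene])
    cand <- mirnaTargets[mirnaTargets$mirna %in% sharedMirs &
                         mirnaTargets$target != focalGene, , drop = FALSE]
    cand <- cand[!duplicated(cand[, c("mirna", "target")]), , drop = FALSE]
    same <- vapply(cand$target, function(gid) {
        gid %in% names(clusterLabels) &&
            identical(clusterLabels[[gid]], focalCluster)
    }, logical(1))
    lab <- rep(NA_character_, nrow(cand))
    if (!is.null(annotation)) {
        m <- match(cand$target, annotation$gene_id)
        lab <- annotation$label[m]
    }
    out <- data.frame(gene_id = cand$target, shared_mirna = cand$mirna,
                      same_cluster_as_focal = same, annotation_label = lab,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}
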