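#' Write an annotated regulatory network as GraphML
#'
#' Emits standards-conformant GraphML with typed edge attributes (sign,
#' delay, frequency, p_tail, goi) and a node attribute marking genes of
#' interest, so the network can be loaded into any graph tool. The output is
#' round-trip safe via [read_graphml()].
#'
#' @param grn an `annotated_grn` or `causal_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(grn, path) {
  stopifnot(inherits(grn, "causal_graph"))
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- list(
    c(id = "d_goi", `for` = "node", attr.name = "is_goi", attr.type = "boolean"),
    c(id = "d_sign", `for` = "edge", attr.name = "sign", attr.type = "string"),
    c(id = "d_delay", `for` = "edge", attr.name = "delay", attr.type = "int"),
    c(id = "d_freq", `for` = "edge", attr.name = "frequency", attr.type = "double"),
    c(id = "d_count", `for` = "edge", attr.name = "count", attr.type = "int"),
    c(id = "d_ptail", `for` = "edge", attr.name = "p_tail", attr.type = "double"),
    c(id = "d_srcgoi", `for` = "edge", attr.name = "goi", attr.type = "string"))
  for (k in keys) {
    node <- xml2::xml_add_child(doc, "key")
    for (nm in names(k)) xml2::xml_set_attr(node, nm, k[[nm]])
  }
  g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")
  goi <- grn$goi %||% character(0)
  for (v in sort(grn$genes)) {
    nd <- xml2::xml_add_child(g, "node", id = v)
    d <- xml2::xml_add_child(nd, "data", key = "d_goi")
    xml2::xml_set_text(d, tolower(as.character(v %in% goi)))
  }
  e <- grn$edges
  if (nrow(e) > 0) {
    ord <- order(e$cause, e$target, e$sign)   # canonical attribute ordering
    e <- e[ord, , drop = FALSE]
    for (q in seq_len(nrow(e))) {
      ed <- xml2::xml_add_child(g, "edge", source = e$cause[q],
                                target = e$target[q])
      put <- function(key, val) {
        if (is.null(val) || length(val) == 0 || is.na(val)) return()
        d <- xml2::xml_add_child(ed, "data", key = key)
        xml2::xml_set_text(d, as.character(val))
      }
      put("d_sign", e$sign[q])
      put("d_delay", e$delay[q])
      put("d_freq", if ("frequency" %in% names(e)) e$frequency[q] else NULL)
      put("d_count", if ("count" %in% names(e)) e$count[q] else NULL)
      put("d_ptail", if ("p_tail" %in% names(e)) e$p_tail[q] else NULL)
      put("d_srcgoi", if ("goi" %in% names(e)) e$goi[q] else NULL)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a GraphML file written by [write_graphml()]
#'
#' @param path GraphML file path.
#' @return An `annotated_grn`.
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//node")
  genes <- xml2::xml_attr(nodes, "id")
  goi <- genes[vapply(nodes, function(nd) {
    d <- xml2::xml_find_first(nd, ".//data[@key='d_goi']")
    !inherits(d, "xml_missing") && identical(xml2::xml_text(d), "true")
  }, TRUE)]
  eds <- xml2::xml_find_all(doc, ".//edge")
  get_data <- function(ed, key) {
    d <- xml2::xml_find_first(ed, sprintf(".//data[@key='%s']", key))
    if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
  }
  edges <- data.frame(
    cause = xml2::xml_attr(eds, "source"),
    target = xml2::xml_attr(eds, "target"),
    sign = vapply(eds, get_data, "", key = "d_sign"),
    delay = as.integer(vapply(eds, get_data, "", key = "d_delay")),
    count = as.integer(vapply(eds, get_data, "", key = "d_count")),
    frequency = as.numeric(vapply(eds, get_data, "", key = "d_freq")),
    p_tail = as.numeric(vapply(eds, get_data, "", key = "d_ptail")),
    goi = vapply(eds, get_data, "", key = "d_srcgoi"),
    stringsAsFactors = FALSE)
  g <- causal_graph(edges, genes)
  class(g) <- c("annotated_grn", class(g))
  g$goi <- goi
  g
}

#' Write a Cytoscape-style edge table
#'
#' TSV with columns source, target, interaction (activates/represses),
#' delay, frequency; directly loadable as a Cytoscape edge table.
#'
#' @param grn an `annotated_grn` or `causal_graph`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cytoscape_table <- function(grn, path) {
  stopifnot(inherits(grn, "causal_graph"))
  e <- grn$edges
  df <- data.frame(
    source = e$cause, target = e$target,
    interaction = ifelse(e$sign == "positive", "activates", "represses"),
    delay = e$delay,
    frequency = if ("frequency" %in% names(e)) e$frequency else NA_real_,
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the raw per-edge table
#'
#' @param grn `causal_graph` or `annotated_grn`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(grn, path) {
  stopifnot(inherits(grn, "causal_graph"))
  write.table(grn$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge per-gene networks into one consolidated network
#'
#' Node and edge union; duplicate (cause, target, sign) edges are collapsed,
#' keeping the maximum frequency/count and concatenating the source
#' gene-of-interest lists. Edges that disagree in sign for the same (cause,
#' target) are kept as distinct signed edges so per-gene evidence is never
#' destroyed.
#'
#' @param grns list of `annotated_grn`/`causal_graph` objects.
#' @return Merged `annotated_grn`.
#' @export
merge_grns <- function(grns) {
  stopifnot(is.list(grns))
  if (length(grns) == 0) {
    g <- causal_graph(data.frame(cause = character(0), target = character(0),
                                 sign = character(0), delay = integer(0),
                                 stringsAsFactors = FALSE), character(0))
    class(g) <- c("annotated_grn", class(g))
    g$goi <- character(0)
    return(g)
  }
  for (g in grns) stopifnot(inherits(g, "causal_graph"))
  genes <- sort(unique(unlist(lapply(grns, `[[`, "genes"))))
  goi <- sort(unique(unlist(lapply(grns, function(g) g$goi %||% character(0)))))
  all_e <- do.call(rbind, lapply(grns, function(g) {
    e <- g$edges
    for (col in c("count", "frequency", "p_tail"))
      if (!(col %in% names(e))) e[[col]] <- NA_real_
    if (!("goi" %in% names(e))) e$goi <- NA_character_
    e[, c("cause", "target", "sign", "delay", "count", "frequency",
          "p_tail", "goi")]
  }))
  if (nrow(all_e) == 0) {
    g <- causal_graph(all_e, genes)
  } else {
    key <- paste(all_e$cause, all_e$target, all_e$sign, sep = "\r")
    merged <- do.call(rbind, lapply(split(all_e, key), function(d) {
      best <- if (all(is.na(d$frequency))) 1 else which.max(d$frequency)
      srcs <- sort(unique(unlist(strsplit(d$goi[!is.na(d$goi)], ","))))
      data.frame(cause = d$cause[1], target = d$target[1], sign = d$sign[1],
                 delay = d$delay[best],
                 count = suppressWarnings(max(d$count, na.rm = TRUE)),
                 frequency = suppressWarnings(max(d$frequency, na.rm = TRUE)),
                 p_tail = suppressWarnings(min(d$p_tail, na.rm = TRUE)),
                 goi = paste(srcs, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    merged$count[!is.finite(merged$count)] <- NA_integer_
    merged$frequency[!is.finite(merged$frequency)] <- NA_real_
    merged$p_tail[!is.finite(merged$p_tail)] <- NA_real_
    rownames(merged) <- NULL
    merged <- merged[order(merged$cause, merged$target, merged$sign), ,
                     drop = FALSE]
    rownames(merged) <- NULL
    g <- causal_graph(merged, genes)
  }
  class(g) <- c("annotated_grn", class(g))
  g$goi <- goi
  g
}
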