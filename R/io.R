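# Network and record interchange: a native JSON/YAML document, the GeNIe
# XDSL dialect (chance nodes with discrete states only), and CSV record
# tables with blank cells for missing values.

network_to_list <- function(net) {
  list(
    variables = lapply(names(net$variables), function(v)
      list(name = v, states = as.list(net$variables[[v]]))),
    arcs = lapply(seq_len(nrow(net$arcs)), function(i)
      list(parent = net$arcs$parent[i], child = net$arcs$child[i])),
    cpts = lapply(net$cpts, function(cpt) {
      grid <- if (length(cpt$parents) == 0) data.frame(row.names = 1) else
        expand.grid(cpt$states[cpt$parents], stringsAsFactors = FALSE,
                    KEEP.OUT.ATTRS = FALSE)
      rows <- lapply(seq_len(nrow(grid)), function(i) {
        config <- if (length(cpt$parents) == 0) character(0) else
          stats::setNames(as.character(grid[i, cpt$parents]), cpt$parents)
        list(given = as.list(unname(config)), p = as.list(cpt_row(cpt, config)))
      })
      list(child = cpt$child, parents = as.list(cpt$parents), rows = rows)
    }))
}

network_from_list <- function(doc, context = "network document") {
  need <- c("variables", "arcs", "cpts")
  miss <- setdiff(need, names(doc))
  if (length(miss) > 0)
    stop_parse(sprintf("%s lacks section(s): %s", context, paste(miss, collapse = ", ")))
  variables <- stats::setNames(
    lapply(doc$variables, function(v) as.character(unlist(v$states))),
    vapply(doc$variables, function(v) as.character(v$name), character(1)))
  arcs <- data.frame(
    parent = vapply(doc$arcs, function(a) as.character(a$parent), character(1)),
    child = vapply(doc$arcs, function(a) as.character(a$child), character(1)))
  cpts <- lapply(doc$cpts, function(c0) {
    child <- as.character(c0$child)
    parents <- as.character(unlist(c0$parents))
    if (is.null(c0$rows))
      stop_parse(sprintf("%s: CPT for '%s' has no rows", context, child))
    rows <- do.call(rbind, lapply(c0$rows, function(r) {
      given <- as.character(unlist(r$given))
      p <- as.numeric(unlist(r$p))
      df <- as.data.frame(as.list(stats::setNames(given, parents)),
                          stringsAsFactors = FALSE)
      if (length(parents) == 0) df <- data.frame(row.names = 1)
      cbind(df, stats::setNames(as.data.frame(as.list(p)),
                                paste0("p_", variables[[child]])))
    }))
    cpt_from_rows(child, parents, rows,
                  prob_cols = paste0("p_", variables[[child]]),
                  states = variables[c(child, parents)])
  })
  bn_network(variables, arcs, cpts)
}

# XDSL stores each CPT flat with the node's own states varying fastest and
# the first parent slowest
xdsl_prob_order <- function(cpt) {
  k <- length(cpt$parents)
  if (k == 0) return(as.numeric(cpt$prob))
  as.numeric(aperm(cpt$prob, c(1, seq(k + 1, 2))))
}

network_to_xdsl <- function(net, id = "network") {
  doc <- xml2::xml_new_root("smile", version = "1.0", id = id)
  nodes <- xml2::xml_add_child(doc, "nodes")
  order <- topo_order(net)
  for (v in order) {
    cpt <- net$cpts[[v]]
    node <- xml2::xml_add_child(nodes, "cpt", id = v)
    for (s in net$variables[[v]])
      xml2::xml_add_child(node, "state", id = s)
    if (length(cpt$parents) > 0)
      xml2::xml_add_child(node, "parents", paste(cpt$parents, collapse = " "))
    xml2::xml_add_child(node, "probabilities",
                        paste(format(xdsl_prob_order(cpt), digits = 10,
                                     scientific = FALSE, trim = TRUE),
                              collapse = " "))
  }
  doc
}

network_from_xdsl <- function(doc, context = "XDSL file") {
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "smile")
    stop_parse(sprintf("%s: root element is <%s>, expected <smile>", context,
                       xml2::xml_name(root)))
  nodes <- xml2::xml_find_all(root, "./nodes/*")
  if (length(nodes) == 0)
    stop_parse(sprintf("%s: no nodes found", context))
  bad <- nodes[xml2::xml_name(nodes) != "cpt"]
  if (length(bad) > 0)
    stop_parse(sprintf(
      "%s: unsupported node type(s) %s; only chance (<cpt>) nodes with discrete states are supported",
      context, paste(unique(xml2::xml_name(bad)), collapse = ", ")))
  variables <- list()
  arcs <- data.frame(parent = character(), child = character())
  cpts <- list()
  for (node in nodes) {
    v <- xml2::xml_attr(node, "id")
    states <- xml2::xml_attr(xml2::xml_find_all(node, "./state"), "id")
    if (length(states) < 2)
      stop_parse(sprintf("%s: node '%s' needs at least two <state> elements", context, v))
    variables[[v]] <- states
    parents_node <- xml2::xml_find_first(node, "./parents")
    parents <- if (inherits(parents_node, "xml_missing")) character(0) else
      strsplit(trimws(xml2::xml_text(parents_node)), "\\s+")[[1]]
    probs_node <- xml2::xml_find_first(node, "./probabilities")
    if (inherits(probs_node, "xml_missing"))
      stop_parse(sprintf("%s: node '%s' has no <probabilities>", context, v))
    p <- as.numeric(strsplit(trimws(xml2::xml_text(probs_node)), "\\s+")[[1]])
    unknown <- setdiff(parents, names(variables))
    if (length(unknown) > 0)
      stop_parse(sprintf("%s: node '%s' references undeclared parent(s) %s (parents must precede children)",
                         context, v, paste(unknown, collapse = ", ")))
    sizes <- c(length(states), vapply(variables[parents], length, integer(1)))
    if (length(p) != prod(sizes))
      stop_parse(sprintf("%s: node '%s' has %d probabilities, expected %d",
                         context, v, length(p), prod(sizes)))
    k <- length(parents)
    arr <- array(p, dim = if (k == 0) sizes else c(sizes[1], sizes[seq(k + 1, 2)]))
    if (k > 0) arr <- aperm(arr, c(1, seq(k + 1, 2)))
    cpts[[v]] <- bn_cpt(v, parents, arr, c(variables[v], variables[parents]))
    if (k > 0)
      arcs <- rbind(arcs, data.frame(parent = parents, child = v))
  }
  bn_network(variables, arcs, cpts)
}

guess_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
         json = "json", yaml = "yaml", yml = "yaml", xdsl = "xdsl",
         stop_validation(sprintf(
           "cannot infer network format from '%s'; pass format explicitly", path)))
}

#' Write a network to disk
#'
#' @param net A validated [bn_network()] with CPTs.
#' @param path Output file.
#' @param format `"json"`, `"yaml"`, or `"xdsl"` (GeNIe interchange);
#'   inferred from the file extension by default. Round trips preserve
#'   structure and CPT values to at least 6 decimals.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = guess_format(path)) {
  validate_network(net)
  format <- match.arg(format, c("json", "yaml", "xdsl"))
  switch(format,
         json = jsonlite::write_json(network_to_list(net), path,
                                     auto_unbox = TRUE, digits = NA, pretty = TRUE),
         yaml = yaml::write_yaml(network_to_list(net), path,
                                 precision = 12L),
         xdsl = xml2::write_xml(network_to_xdsl(net), path))
  invisible(path)
}

#' Read a network from disk
#'
#' @param path Network file (native JSON/YAML or GeNIe XDSL).
#' @param format Format override; inferred from the extension by default.
#' @return A validated [bn_network()].
#' @export
read_network <- function(path, format = guess_format(path)) {
  if (!file.exists(path))
    stop_validation(sprintf("network file '%s' does not exist", path))
  format <- match.arg(format, c("json", "yaml", "xdsl"))
  switch(format,
         json = network_from_list(jsonlite::read_json(path), path),
         yaml = network_from_list(yaml::read_yaml(path), path),
         xdsl = network_from_xdsl(xml2::read_xml(path), path))
}

#' Write dichotomized records as CSV
#'
#' Missing cells are written as empty fields.
#'
#' @param records data.frame of state labels (optionally with `id`).
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read dichotomized records from CSV
#'
#' Empty fields become `NA` (missing).
#'
#' @param path CSV with one state column per variable.
#' @return data.frame of state labels.
#' @export
read_records <- function(path) {
  if (!file.exists(path))
    stop_validation(sprintf("record file '%s' does not exist", path))
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}
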