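#' Total persistence duration of each state
#'
#' Each time point contributes one sampling interval to the state it is
#' in, so `duration(z) = dt * #\{i : Q[i] = z\}` and durations sum to
#' `|Q| * dt` (the total sampled time).
#'
#' @param astd An `hfpne_astd`.
#' @param dt Sampling interval of the underlying trace.
#' @return Named numeric vector, one entry per state id.
#' @export
state_durations <- function(astd, dt) {
  stopifnot(length(astd$Q) > 0L, dt > 0)
  counts <- tabulate(astd$Q, nbins = length(astd$nodes))
  stats::setNames(counts * dt, as.character(seq_along(astd$nodes)))
}

#' Out-degree of each state, on a natural-log scale
#'
#' The out-degree counts how often (mode `"traversals"`, default) or
#' along how many distinct edges (mode `"distinct"`) a state is exited.
#' Node sizes in diagrams use `ln(count)`; a count of zero (a terminal
#' state, which a sustained oscillation never has) maps to `NA` and is
#' drawn at the minimum size.
#'
#' @param astd An `hfpne_astd`.
#' @param mode `"traversals"` or `"distinct"`.
#' @return Data frame with `state`, `count`, `ln` columns.
#' @export
out_degree_scale <- function(astd, mode = c("traversals", "distinct")) {
  mode <- match.arg(mode)
  n <- length(astd$nodes)
  count <- integer(n)
  if (nrow(astd$edges)) {
    agg <- if (mode == "traversals")
      tapply(astd$edges$count, astd$edges$src, sum)
    else table(astd$edges$src)
    count[as.integer(names(agg))] <- as.integer(agg)
  }
  data.frame(state = seq_len(n), count = count,
             ln = ifelse(count >= 1L, log(count), NA_real_))
}

#' Total concentration difference of a place per state
#'
#' Sums the adjacent-time concentration differences
#' `M(p)[x_i] - M(p)[x_(i-1)]` over index pairs whose *both* endpoints
#' lie in the given state (boundary pairs, where the previous point is in
#' a different state, belong to no state).  On a single-state trace this
#' telescopes to final minus initial value.
#'
#' @param trace The `hfpne_trace` the ASTD was built from (same time
#'   axis: `|Q| = nrow(trace)`).
#' @param astd An `hfpne_astd`.
#' @param place A place id (numeric column of `trace`).
#' @return Named numeric vector, one entry per state id, in the trace's
#'   concentration units.
#' @export
total_concentration_difference <- function(trace, astd, place) {
  if (!place %in% names(trace))
    stop("unknown place '", place, "'", call. = FALSE)
  if (nrow(trace) != length(astd$Q))
    stop("trace and ASTD do not share a time axis (", nrow(trace),
         " vs ", length(astd$Q), " points)", call. = FALSE)
  v <- trace[[place]]
  if (!is.numeric(v))
    stop("place '", place, "' holds generic marks; concentration ",
         "differences are defined for numeric places", call. = FALSE)
  n <- length(astd$nodes)
  out <- stats::setNames(numeric(n), as.character(seq_len(n)))
  if (length(v) < 2L) return(out)
  i <- 2:length(v)
  same <- astd$Q[i] == astd$Q[i - 1L]
  if (any(same)) {
    d <- (v[i] - v[i - 1L])[same]
    z <- astd$Q[i][same]
    agg <- tapply(d, z, sum)
    out[names(agg)] <- as.numeric(agg)
  }
  out
}

#' Compare two ASTDs by structural state
#'
#' Matches states across two diagrams (e.g. wild type vs a mutant built
#' over the same element-id namespace) by canonical key and reports the
#' shared and model-specific states, with per-side state ids and visit
#' counts for the shared ones.
#'
#' @param a,b `hfpne_astd` objects.
#' @return List with `shared` (data frame: `key`, `sid_a`, `sid_b`,
#'   `visits_a`, `visits_b`), `only_a`, `only_b` (key vectors) and
#'   `n_shared`.
#' @export
compare_astds <- function(a, b) {
  shared_keys <- intersect(a$keys, b$keys)
  if (length(shared_keys) == 0L)
    warning("no shared states: do the two ASTDs share an element-id ",
            "namespace?")
  va <- tabulate(a$Q, nbins = length(a$nodes))
  vb <- tabulate(b$Q, nbins = length(b$nodes))
  shared <- data.frame(
    key = shared_keys,
    sid_a = match(shared_keys, a$keys),
    sid_b = match(shared_keys, b$keys))
  shared$visits_a <- va[shared$sid_a]
  shared$visits_b <- vb[shared$sid_b]
  list(shared = shared,
       only_a = setdiff(a$keys, b$keys),
       only_b = setdiff(b$keys, a$keys),
       n_shared = length(shared_keys))
}

# Diverging blue-white-red scale; red marks the largest positive value.
diverging_color <- function(v) {
  v[!is.finite(v)] <- 0
  m <- max(abs(v), 1e-12)
  ramp <- grDevices::colorRamp(c("#2166AC", "#FFFFFF", "#B2182B"))
  rgb <- ramp((v / m + 1) / 2)
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
}

#' Export an ASTD as DOT or GraphML
#'
#' Writes a deterministic graph file in which node size encodes state
#' duration (or ln out-degree) and node colour encodes the total
#' concentration difference of a chosen place on a diverging scale (red =
#' largest positive difference).
#'
#' @param astd An `hfpne_astd`.
#' @param path Output file.
#' @param format `"dot"` or `"graphml"`.
#' @param size Named/plain numeric vector of node sizes (e.g. from
#'   [state_durations()] or the `ln` column of [out_degree_scale()]);
#'   `NA` entries get the minimum size.
#' @param color Numeric vector per state (e.g. from
#'   [total_concentration_difference()]); mapped to a diverging scale.
#' @return `path`, invisibly.
#' @export
export_graph <- function(astd, path, format = c("dot", "graphml"),
                         size = NULL, color = NULL) {
  format <- match.arg(format)
  n <- length(astd$nodes)
  if (is.null(size)) size <- rep(1, n)
  size <- as.numeric(size)
  lo <- if (all(is.na(size))) 1 else min(size, na.rm = TRUE)
  size[is.na(size)] <- lo
  rng <- range(size)
  norm <- if (diff(rng) == 0) rep(0.5, n) else (size - rng[1]) / diff(rng)
  width <- 0.3 + 1.2 * norm
  col <- if (is.null(color)) rep("#FFFFFF", n) else diverging_color(as.numeric(color))
  if (format == "dot") {
    lines <- c("digraph astd {", "  node [shape=circle, style=filled];")
    for (i in seq_len(n))
      lines <- c(lines, sprintf(
        '  z%d [label="z%d", width=%.4f, fixedsize=true, fillcolor="%s"];',
        i, i, width[[i]], col[[i]]))
    for (j in seq_len(nrow(astd$edges)))
      lines <- c(lines, sprintf('  z%d -> z%d [label="%d"];',
                                astd$edges$src[[j]], astd$edges$dst[[j]],
                                astd$edges$count[[j]]))
    lines <- c(lines, "}")
    writeLines(lines, path)
  } else {
    doc <- xml2::xml_new_root(
      "graphml",
      xmlns = "http://graphml.graphdrawing.org/xmlns",
      "xmlns:xsi" = "http://www.w3.org/2001/XMLSchema-instance",
      "xsi:schemaLocation" = paste(
        "http://graphml.graphdrawing.org/xmlns",
        "http://graphml.graphdrawing.org/xmlns/1.0/graphml.xsd"))
    for (k in list(c("d_size", "node", "size", "double"),
                   c("d_color", "node", "color", "string"),
                   c("d_count", "edge", "count", "int"))) {
      key <- xml2::xml_add_child(doc, "key")
      xml2::xml_set_attrs(key, c(id = k[1], `for` = k[2],
                                 attr.name = k[3], attr.type = k[4]))
    }
    g <- xml2::xml_add_child(doc, "graph", id = "astd",
                             edgedefault = "directed")
    for (i in seq_len(n)) {
      nd <- xml2::xml_add_child(g, "node", id = paste0("z", i))
      d1 <- xml2::xml_add_child(nd, "data", key = "d_size")
      xml2::xml_set_text(d1, format(width[[i]], digits = 6))
      d2 <- xml2::xml_add_child(nd, "data", key = "d_color")
      xml2::xml_set_text(d2, col[[i]])
    }
    for (j in seq_len(nrow(astd$edges))) {
      ed <- xml2::xml_add_child(g, "edge",
                                source = paste0("z", astd$edges$src[[j]]),
                                target = paste0("z", astd$edges$dst[[j]]))
      dc <- xml2::xml_add_child(ed, "data", key = "d_count")
      xml2::xml_set_text(dc, as.character(astd$edges$count[[j]]))
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}
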