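#' Canonical key of a temporal subnet
#'
#' Two subnets are the same structural state exactly when their place,
#' transition and arc id sets are equal.  The key is the sorted id sets
#' concatenated into one string, so it is independent of element insertion
#' order and identical across runs and serialisations.
#'
#' @param subnet An `hfpne_subnet`.
#' @return A single string.
#' @export
canonical_key <- function(subnet) {
  paste0("P:", paste(sort(subnet$places), collapse = ","),
         "|T:", paste(sort(subnet$transitions), collapse = ","),
         "|A:", paste(sort(subnet$arcs), collapse = ","))
}

#' Build the active state transition diagram (ASTD)
#'
#' Deduplicates a time-ordered stream of temporal subnets into a directed
#' graph G = (N, E).  State ids are assigned consecutively from 1 in
#' order of first appearance; whenever the current subnet differs from
#' the previous one, a directed edge previous -> current is recorded.
#' Consecutive identical subnets emit no edge (no self-loops), and the
#' first state has no incoming edge.  Edges are stored deduplicated by
#' (src, dst) with a traversal count, so both the set reading and the
#' multiset reading of the edge list are recoverable.  The full visited
#' sequence Q (one state id per time point) is retained.
#'
#' @param subnets Nonempty time-ordered list of `hfpne_subnet` (from
#'   [extract_all()]).
#' @return An `hfpne_astd`: `nodes` (state id -> representative subnet),
#'   `edges` (data frame `src`, `dst`, `count`), `Q` (integer vector),
#'   `keys` (canonical key per state id).
#' @export
build_astd <- function(subnets) {
  if (length(subnets) == 0L)
    stop("build_astd() needs a nonempty subnet stream", call. = FALSE)
  state_map <- new.env(parent = emptyenv(), hash = TRUE)
  n_tp <- length(subnets)
  Q <- integer(n_tp)
  nodes <- list()
  keys <- character(0)
  ekey <- new.env(parent = emptyenv(), hash = TRUE)  # "src>dst" -> count

  k0 <- canonical_key(subnets[[1L]])
  assign(k0, 1L, envir = state_map)
  nodes[[1L]] <- subnets[[1L]]
  keys[[1L]] <- k0
  Q[[1L]] <- 1L
  prev_key <- k0
  prev_sid <- 1L
  sid <- 1L

  for (i in seq_len(n_tp)[-1L]) {
    k <- canonical_key(subnets[[i]])
    if (k != prev_key) {
      cur_sid <- if (exists(k, envir = state_map, inherits = FALSE))
        get(k, envir = state_map) else NA_integer_
      if (is.na(cur_sid)) {
        sid <- sid + 1L
        cur_sid <- sid
        assign(k, cur_sid, envir = state_map)
        nodes[[cur_sid]] <- subnets[[i]]
        keys[[cur_sid]] <- k
      } else {
        # accumulate the occurrence times on the representative subnet
        nodes[[cur_sid]]$times <- c(nodes[[cur_sid]]$times,
                                    subnets[[i]]$times)
      }
      ek <- paste0(prev_sid, ">", cur_sid)
      n <- if (exists(ek, envir = ekey, inherits = FALSE))
        get(ek, envir = ekey) else 0L
      assign(ek, n + 1L, envir = ekey)
      prev_sid <- cur_sid
      prev_key <- k
    } else {
      nodes[[prev_sid]]$times <- c(nodes[[prev_sid]]$times,
                                   subnets[[i]]$times)
    }
    Q[[i]] <- prev_sid
  }

  eks <- ls(ekey)
  edges <- if (length(eks)) {
    parts <- strsplit(eks, ">", fixed = TRUE)
    df <- data.frame(src = as.integer(vapply(parts, `[[`, "", 1L)),
                     dst = as.integer(vapply(parts, `[[`, "", 2L)),
                     count = vapply(eks, function(k) get(k, envir = ekey),
                                    0L, USE.NAMES = FALSE))
    df[order(df$src, df$dst), , drop = FALSE]
  } else data.frame(src = integer(0), dst = integer(0), count = integer(0))
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, Q = Q, keys = keys,
                 net_id = subnets[[1L]]$net_id),
            class = "hfpne_astd")
}

#' @export
print.hfpne_astd <- function(x, ...) {
  cat("<hfpne_astd> of '", x$net_id, "': ", length(x$nodes),
      " states, ", nrow(x$edges), " directed edges (",
      sum(x$edges$count), " traversals), |Q| = ", length(x$Q), "\n",
      sep = "")
  invisible(x)
}

#' Write / read an ASTD as JSON
#'
#' Nodes carry their canonical element lists; edges carry traversal
#' counts; the visited sequence Q is stored in full.  Output is
#' deterministic.
#'
#' @param astd An `hfpne_astd`.
#' @param path File path.
#' @return `path` (write) or an `hfpne_astd` (read).
#' @export
write_astd <- function(astd, path) {
  doc <- list(
    format = "hfpne-astd", version = 1L, net_id = astd$net_id,
    nodes = lapply(seq_along(astd$nodes), function(i) {
      z <- astd$nodes[[i]]
      list(sid = i, places = z$places, transitions = z$transitions,
           arcs = z$arcs)
    }),
    edges = lapply(seq_len(nrow(astd$edges)), function(i)
      list(src = astd$edges$src[[i]], dst = astd$edges$dst[[i]],
           count = astd$edges$count[[i]])),
    Q = astd$Q)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_astd
#' @export
read_astd <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "hfpne-astd"))
    stop("'", path, "' is not an hfpne-astd file", call. = FALSE)
  nodes <- lapply(doc$nodes, function(nd)
    structure(list(net_id = doc$net_id, times = numeric(0),
                   places = as.character(unlist(nd$places)),
                   transitions = as.character(unlist(nd$transitions)),
                   arcs = as.character(unlist(nd$arcs))),
              class = "hfpne_subnet"))
  edges <- if (length(doc$edges))
    data.frame(src = vapply(doc$edges, function(e) as.integer(e$src), 0L),
               dst = vapply(doc$edges, function(e) as.integer(e$dst), 0L),
               count = vapply(doc$edges, function(e) as.integer(e$count), 0L))
  else data.frame(src = integer(0), dst = integer(0), count = integer(0))
  structure(list(nodes = nodes, edges = edges,
                 Q = as.integer(unlist(doc$Q)),
                 keys = vapply(nodes, canonical_key, ""),
                 net_id = doc$net_id),
            class = "hfpne_astd")
}
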