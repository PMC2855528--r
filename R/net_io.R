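#' Write a net description file
#'
#' Serializes an [hfpne_net()] to a versioned YAML document listing
#' places, transitions and arcs in a deterministic order (declaration
#' order), so that identical nets write byte-identical files.
#'
#' @param net An [hfpne_net()].
#' @param path Output path (`.yaml` by convention).
#' @return `path`, invisibly.
#' @export
write_net <- function(net, path) {
  doc <- list(
    format = "hfpne-net",
    version = 1L,
    id = net$id,
    places = unname(lapply(net$places, function(p)
      list(id = p$id, name = p$name, kind = p$kind,
           initial = p$initial, variable = p$variable))),
    transitions = unname(lapply(net$transitions, function(t) {
      out <- list(id = t$id, name = t$name, kind = t$kind,
                  priority = t$priority)
      if (!is.null(t$delay)) out$delay <- t$delay$text
      out
    })),
    arcs = unname(lapply(net$arcs, function(a) {
      out <- list(id = a$id, from = a$from, to = a$to, label = a$label)
      if (!is.null(a$activity)) out$activity <- a$activity$text
      if (!is.null(a$update)) out$update <- a$update$text
      out
    })))
  yaml::write_yaml(doc, path, precision = 17L)
  invisible(path)
}

#' Read a net description file
#'
#' @param path Path to a YAML file written by [write_net()] (or authored
#'   by hand to the same schema).
#' @return An [hfpne_net()].
#' @export
read_net <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$format, "hfpne-net"))
    stop("'", path, "' is not an hfpne-net file", call. = FALSE)
  places <- lapply(doc$places, function(p)
    place(p$id, p$kind, initial = p$initial,
          name = if (is.null(p$name)) p$id else p$name,
          variable = if (is.null(p$variable)) p$id else p$variable))
  transitions <- lapply(doc$transitions, function(t)
    transition(t$id, t$kind,
               delay = if (t$kind == "continuous") NULL
                       else if (is.null(t$delay)) "0" else t$delay,
               priority = if (is.null(t$priority)) NA_integer_ else t$priority,
               name = if (is.null(t$name)) t$id else t$name))
  arcs <- lapply(doc$arcs, function(a)
    arc(a$from, a$to, a$label, activity = a$activity, update = a$update,
        id = a$id))
  hfpne_net(places, transitions, arcs,
            id = if (is.null(doc$id)) "net" else doc$id)
}
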