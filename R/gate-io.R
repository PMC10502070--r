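# Reading and writing gate-system specification files.
#
# The on-disk form is a plain structured-text document with sections
# `domains`, `strands`, `gate` and (optionally) `kinetics`; YAML is the
# default rendering and JSON is supported via the .json extension.

#' Read a gate system from a specification file
#'
#' @param path a `.yaml`/`.yml` or `.json` gate-specification file with
#'   sections `domains` (name/role/length records), `strands`
#'   (name/domains/label records), `gate` (template, incumbent, footprint,
#'   inputs) and optional `kinetics` overrides.
#' @return a validated `dsd_gate` (see [build_gate_system()]).
#' @export
read_gate_system <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  spec <- if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  build_gate_system(spec, name = spec$name %||% basename(path))
}

#' Write a gate system to a specification file
#'
#' The written file reloads through [read_gate_system()] into a gate equal
#' to the original on every field.
#'
#' @param gate a `dsd_gate`.
#' @param path output path; a `.json` extension selects JSON, anything
#'   else YAML.
#' @return `path`, invisibly.
#' @export
write_gate_system <- function(gate, path) {
  stopifnot(inherits(gate, "dsd_gate"))
  spec <- gate_to_spec(gate)
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(spec, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(spec, path)
  }
  invisible(path)
}

gate_to_spec <- function(gate) {
  list(
    name = gate$name,
    domains = lapply(seq_len(nrow(gate$domains)), function(i)
      list(name = gate$domains$name[i], role = gate$domains$role[i],
           length = gate$domains$length[i])),
    strands = lapply(gate$strands, function(s)
      list(name = s$name, domains = as.list(s$domains), label = s$label)),
    gate = list(template = gate$template$name,
                incumbent = gate$incumbent$name,
                footprint = as.list(as.integer(gate$footprint)),
                inputs = lapply(gate$inputs, `[[`, "name")),
    kinetics = if (length(gate$kinetics) > 0L) gate$kinetics else NULL
  ) |> Filter(f = Negate(is.null))
}
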