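#' dsdgates: domain-level DNA strand-displacement logic gates
#'
#' Tools to model toehold-mediated DNA strand displacement at the domain
#' level: build gate systems (a quencher-labelled template strand holding a
#' fluorophore-labelled incumbent, plus three named input strands), decide
#' whether a given input combination releases the reporter, compute truth
#' tables, run exact stochastic kinetics for a fluorescence-style readout,
#' and design orthogonal nucleotide sequences for the domains.
#'
#' @section Built-in gates:
#' [paper_gate()] returns the three-input OR, AND and MAJORITY gates built
#' on a four-domain template (`E F H G` with reporter `fh`, or the blunt
#' duplex `ABCD:abcd`).
#'
#' @keywords internal
#' @useDynLib dsdgates, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# -- domain name algebra -------------------------------------------------

#' Complement of a domain name, domain table row, or strand
#'
#' Complementary domains are named by case swap (`F` pairs with `f`);
#' the complement of a strand is the antiparallel strand, i.e. the reversed
#' list of domain complements. `complement()` is an involution.
#'
#' @param x a character vector of domain names, or a [strand()].
#' @param ... unused.
#' @return an object of the same kind as `x`.
#' @examples
#' complement("F")
#' complement(strand("ABCD", c("A", "B", "C", "D")))
#' @export
complement <- function(x, ...) UseMethod("complement")

#' @export
complement.character <- function(x, ...) {
  bad <- x[!is_valid_domain_name(x)]
  if (length(bad) > 0L) {
    stop("invalid domain name(s): ", paste(bad, collapse = ", "),
         " (names must be non-empty, letters only, all one case)",
         call. = FALSE)
  }
  ifelse(x == tolower(x), toupper(x), tolower(x))
}

#' @export
complement.dsd_strand <- function(x, ...) {
  doms <- rev(complement(x$domains))
  strand(paste0(doms, collapse = ""), doms, label = "none")
}

is_valid_domain_name <- function(x) {
  nzchar(x) & grepl("^[A-Za-z]+$", x) &
    (x == tolower(x) | x == toupper(x)) & (tolower(x) != toupper(x))
}

# -- strands -------------------------------------------------------------

#' Construct a DNA strand
#'
#' A strand is an ordered (5'->3') list of domain names plus an optional
#' terminal label: the FAM fluorophore, the BHQ1 quencher, or none.
#'
#' @param name strand identifier (conventionally the concatenated domain
#'   names, e.g. `"efh"`).
#' @param domains character vector of domain names, 5'->3', non-empty.
#' @param label one of `"none"`, `"fluorophore_FAM"`, `"quencher_BHQ1"`.
#' @return an object of class `dsd_strand`.
#' @export
strand <- function(name, domains, label = "none") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("strand name must be a single non-empty string", call. = FALSE)
  if (length(domains) == 0L)
    stop("strand '", name, "' has an empty domain list", call. = FALSE)
  bad <- domains[!is_valid_domain_name(domains)]
  if (length(bad) > 0L)
    stop("strand '", name, "' has invalid domain name(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  label <- match.arg(label, c("none", "fluorophore_FAM", "quencher_BHQ1"))
  structure(list(name = name, domains = as.character(domains),
                 label = label),
            class = "dsd_strand")
}

#' @export
print.dsd_strand <- function(x, ...) {
  lab <- switch(x$label, none = "", fluorophore_FAM = " [FAM]",
                quencher_BHQ1 = " [BHQ1]")
  cat(sprintf("<strand %s: 5'-%s-3'%s>\n", x$name,
              paste(x$domains, collapse = "-"), lab))
  invisible(x)
}

same_composition <- function(a, b) identical(a$domains, b$domains)

# -- gate systems --------------------------------------------------------

#' Build and validate a gate system
#'
#' A gate system is a quencher-labelled template strand, a
#' fluorophore-labelled incumbent (the reporter) initially hybridised to a
#' contiguous run of template domains (the footprint), and exactly three
#' named input strands, each complementary to a contiguous run of template
#' domains. The input order defines INPUT1/INPUT2/INPUT3 and hence the
#' truth-table state order.
#'
#' @param spec a list with components:
#'   \describe{
#'     \item{domains}{a data frame (or list of lists) with columns/fields
#'       `name`, `role` (`"toehold"` or `"recognition"`), `length`
#'       (nucleotides). Only one member of each complement pair needs to be
#'       listed; the partner is derived.}
#'     \item{strands}{a list of [strand()] objects or of lists with fields
#'       `name`, `domains`, optional `label`.}
#'     \item{gate}{a list with fields `template`, `incumbent` (strand
#'       names), optional `footprint` (`c(lo, hi)`, 1-based inclusive;
#'       derived from the incumbent if absent), and `inputs` (three strand
#'       names).}
#'     \item{kinetics}{optional: overrides for [rate_parameters()] fields,
#'       carried along with the gate.}
#'   }
#' @param name optional gate name (used in printing and file output).
#' @return an object of class `dsd_gate` with components `name`, `domains`
#'   (data frame over both cases), `strands` (list), `template`,
#'   `incumbent` (strands), `footprint` (integer `c(lo, hi)`), `inputs`
#'   (list of three strands), `kinetics` (list, possibly empty).
#' @seealso [paper_gate()], [read_gate_system()], [write_gate_system()]
#' @export
build_gate_system <- function(spec, name = spec$name %||% "gate") {
  if (is.null(spec$domains)) stop("spec has no 'domains' section", call. = FALSE)
  if (is.null(spec$strands)) stop("spec has no 'strands' section", call. = FALSE)
  if (is.null(spec$gate)) stop("spec has no 'gate' section", call. = FALSE)

  domains <- as_domain_table(spec$domains)
  strands <- lapply(spec$strands, as_strand)

  # every domain referenced by a strand must be declared (either case)
  referenced <- unique(unlist(lapply(strands, `[[`, "domains")))
  known <- c(domains$name, complement(domains$name))
  missing <- setdiff(referenced, known)
  if (length(missing) > 0L)
    stop("strand(s) reference undeclared domain(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  domains <- expand_domain_table(domains)

  # duplicate strand names are tolerated only for identical composition
  # (the MAJORITY design reuses the reporter's composition as an input)
  nms <- vapply(strands, `[[`, "", "name")
  for (nm in unique(nms[duplicated(nms)])) {
    grp <- strands[nms == nm]
    if (!all(vapply(grp[-1], same_composition, NA, grp[[1]])))
      stop("duplicate strand name '", nm,
           "' with differing domain composition", call. = FALSE)
  }

  g <- spec$gate
  template <- pick_strand(strands, g$template, "template")
  incumbent <- pick_strand(strands, g$incumbent, "incumbent")
  if (anyDuplicated(template$domains) > 0L)
    stop("template '", template$name, "' has duplicated domains", call. = FALSE)
  if (template$label != "quencher_BHQ1")
    stop("template '", template$name, "' must carry the BHQ1 quencher",
         call. = FALSE)
  if (incumbent$label != "fluorophore_FAM")
    stop("incumbent '", incumbent$name, "' must carry the FAM fluorophore",
         call. = FALSE)

  n <- length(template$domains)
  run <- strand_run_or_fail(incumbent, template)
  if (!is.null(g$footprint)) {
    fp <- as.integer(g$footprint)
    if (length(fp) != 2L || any(is.na(fp)) || fp[1] > fp[2] ||
        fp[1] < 1L || fp[2] > n)
      stop("footprint must be c(lo, hi) within 1..", n, call. = FALSE)
    if (!identical(fp, run))
      stop("incumbent '", incumbent$name, "' covers positions ",
           run[1], "..", run[2], ", not the declared footprint ",
           fp[1], "..", fp[2], call. = FALSE)
  }
  footprint <- run

  if (length(g$inputs) != 3L)
    stop("a gate needs exactly 3 inputs, got ", length(g$inputs),
         call. = FALSE)
  inputs <- lapply(g$inputs, pick_strand, strands = strands, what = "input",
                   prefer_unlabelled = TRUE)
  for (inp in inputs) strand_run_or_fail(inp, template)

  structure(list(name = name, domains = domains, strands = strands,
                 template = template, incumbent = incumbent,
                 footprint = footprint, inputs = inputs,
                 kinetics = spec$kinetics %||% list()),
            class = "dsd_gate")
}

#' @export
print.dsd_gate <- function(x, ...) {
  n <- length(x$template$domains)
  cat(sprintf("<gate '%s': template %s (%d domains), reporter %s on %d..%d>\n",
              x$name, x$template$name, n, x$incumbent$name,
              x$footprint[1], x$footprint[2]))
  for (i in seq_along(x$inputs))
    cat(sprintf("  INPUT%d: %s (5'-%s-3')\n", i, x$inputs[[i]]$name,
                paste(x$inputs[[i]]$domains, collapse = "-")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_strand <- function(s) {
  if (inherits(s, "dsd_strand")) return(s)
  strand(s$name, unlist(s$domains), label = s$label %||% "none")
}

as_domain_table <- function(d) {
  if (is.data.frame(d)) {
    df <- d
  } else {
    df <- data.frame(
      name = vapply(d, `[[`, "", "name"),
      role = vapply(d, `[[`, "", "role"),
      length = vapply(d, function(x) as.integer(x$length), 0L),
      stringsAsFactors = FALSE)
  }
  if (!all(c("name", "role", "length") %in% names(df)))
    stop("domain table needs columns name, role, length", call. = FALSE)
  df$length <- as.integer(df$length)
  bad <- df$name[!is_valid_domain_name(df$name)]
  if (length(bad) > 0L)
    stop("invalid domain name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$name) > 0L)
    stop("duplicate domain name(s): ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "),
         call. = FALSE)
  if (!all(df$role %in% c("toehold", "recognition")))
    stop("domain role must be 'toehold' or 'recognition'", call. = FALSE)
  if (any(df$length <= 0L))
    stop("domain length must be a positive nucleotide count", call. = FALSE)
  # a domain and its listed complement must agree on role and length
  comp <- complement(df$name)
  both <- df$name[comp %in% df$name]
  for (nm in both) {
    i <- match(nm, df$name); j <- match(complement(nm), df$name)
    if (df$role[i] != df$role[j] || df$length[i] != df$length[j])
      stop("domains ", nm, " and ", complement(nm),
           " disagree on role or length", call. = FALSE)
  }
  df
}

# add the case-swapped partner of every listed domain
expand_domain_table <- function(df) {
  comp <- complement(df$name)
  add <- !(comp %in% df$name)
  out <- rbind(df, data.frame(name = comp[add], role = df$role[add],
                              length = df$length[add],
                              stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

pick_strand <- function(strands, name, what, prefer_unlabelled = FALSE) {
  if (is.null(name)) stop("gate section misses its ", what, call. = FALSE)
  if (inherits(name, "dsd_strand")) return(name)
  hits <- strands[vapply(strands, `[[`, "", "name") == name]
  if (length(hits) == 0L)
    stop(what, " strand '", name, "' is not declared", call. = FALSE)
  if (prefer_unlabelled && length(hits) > 1L) {
    plain <- hits[vapply(hits, `[[`, "", "label") == "none"]
    if (length(plain) > 0L) return(plain[[1]])
  }
  hits[[1]]
}

#' Map a strand onto the template it invades
#'
#' The run of template positions whose domains are the complements of the
#' strand's domains. The run must be contiguous; the strand's domain order
#' is interpreted at the domain-set level (orientation is carried by
#' [complement()], not by re-ordering names).
#'
#' @param x a [strand()].
#' @param template the template strand (or a `dsd_gate`, whose template is
#'   used).
#' @return integer `c(lo, hi)`, 1-based inclusive template positions.
#' @export
strand_run <- function(x, template) {
  if (inherits(template, "dsd_gate")) template <- template$template
  strand_run_or_fail(x, template)
}

strand_run_or_fail <- function(x, template) {
  pos <- match(complement(x$domains), template$domains)
  if (anyNA(pos))
    stop("strand '", x$name, "' does not map onto template '",
         template$name, "' (domain ",
         paste(x$domains[is.na(pos)], collapse = ", "),
         " has no template partner)", call. = FALSE)
  pos <- sort(pos)
  if (anyDuplicated(pos) > 0L ||
      !identical(pos, seq.int(pos[1], pos[length(pos)])))
    stop("strand '", x$name,
         "' does not cover a contiguous run of template domains",
         call. = FALSE)
  c(pos[1], pos[length(pos)])
}

# -- built-in gate library ----------------------------------------------

#' The built-in three-input logic gates
#'
#' The three gate designs shipped with the package:
#' \describe{
#'   \item{OR}{template `E-F-H-G` (BHQ1), reporter `fh` on the middle two
#'     domains, leaving toeholds `E` and `G` exposed; inputs `efh`, `fhg`,
#'     `efhg`. Any single input can anchor at an exposed toehold and
#'     displace the reporter.}
#'   \item{AND}{blunt duplex `ABCD:abcd` (BHQ1/FAM) with no exposed
#'     toehold; inputs `ab`, `cd`, `bc`. Displacement requires the full
#'     cooperative hand-over-hand chain, so only all three inputs
#'     release the reporter.}
#'   \item{MAJORITY}{template `E-F-H-G`, reporter `fh`; inputs `ef`, `hg`,
#'     `fh`. Any two inputs suffice (two toehold-anchored invasions, or one
#'     anchored invasion extended by the overlap-joining `fh` input); one
#'     does not.}
#' }
#'
#' Toehold domains default to 6 nt and recognition domains to 15 nt; the
#' flanking/terminal domains (`E`, `G`, `A`, `D`) are the toeholds.
#'
#' @param name `"OR"`, `"AND"` or `"MAJORITY"`.
#' @return a validated `dsd_gate`.
#' @examples
#' paper_gate("OR")
#' truth_table(paper_gate("MAJORITY"))
#' @export
paper_gate <- function(name) {
  valid <- c("OR", "AND", "MAJORITY")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    stop("unknown gate; valid names: ", paste(valid, collapse = ", "),
         call. = FALSE)
  build_gate_system(builtin_gate_spec(name), name = name)
}

builtin_gate_spec <- function(name) {
  dom <- function(names, roles, len = ifelse(roles == "toehold", 6L, 15L))
    data.frame(name = names, role = roles, length = len,
               stringsAsFactors = FALSE)
  if (name == "AND") {
    list(
      domains = dom(c("A", "B", "C", "D"),
                    c("toehold", "recognition", "recognition", "toehold")),
      strands = list(
        strand("ABCD", c("A", "B", "C", "D"), "quencher_BHQ1"),
        strand("abcd", c("a", "b", "c", "d"), "fluorophore_FAM"),
        strand("ab", c("a", "b")),
        strand("cd", c("c", "d")),
        strand("bc", c("b", "c"))),
      gate = list(template = "ABCD", incumbent = "abcd",
                  footprint = c(1L, 4L), inputs = c("ab", "cd", "bc")))
  } else {
    inputs <- if (name == "OR") list(
      strand("efh", c("e", "f", "h")),
      strand("fhg", c("f", "h", "g")),
      strand("efhg", c("e", "f", "h", "g"))
    ) else list(
      strand("ef", c("e", "f")),
      strand("hg", c("h", "g")),
      strand("fh", c("f", "h")))
    list(
      domains = dom(c("E", "F", "H", "G"),
                    c("toehold", "recognition", "recognition", "toehold")),
      strands = c(list(
        strand("EFHG", c("E", "F", "H", "G"), "quencher_BHQ1"),
        strand("fh", c("f", "h"), "fluorophore_FAM")), inputs),
      gate = list(template = "EFHG", incumbent = "fh",
                  footprint = c(2L, 3L),
                  inputs = vapply(inputs, `[[`, "", "name")))
  }
}
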