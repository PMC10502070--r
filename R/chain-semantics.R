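# The logical execution layer: displacement-chain reachability.
#
# An input strand can start a displacement chain either at a strong anchor
# (an exposed toehold it complements) or at a weak anchor (terminal
# fraying at template position 1 or n). A present input whose template run
# overlaps an anchored chain's coverage joins that chain (hand-over-hand
# displacement: the junction left by the previous invader is an internal
# toehold). The reporter is released iff a single chain covers its whole
# footprint, or the strong-anchored chains jointly do; disconnected weak
# (fray-seeded) chains never cooperate, which is what keeps a blunt duplex
# closed unless the invader chain is continuous.

# the paper's fixed abscissa order for the eight input states
STATE_ORDER <- matrix(c(0L, 0L, 0L,
                        1L, 0L, 0L,
                        0L, 1L, 0L,
                        0L, 0L, 1L,
                        1L, 1L, 0L,
                        1L, 0L, 1L,
                        0L, 1L, 1L,
                        1L, 1L, 1L),
                      ncol = 3L, byrow = TRUE,
                      dimnames = list(NULL, c("input1", "input2", "input3")))

#' Exposed toeholds of a gate
#'
#' Template positions not covered by the incumbent footprint, i.e. the
#' single-stranded domains where an invader can anchor strongly.
#'
#' @param gate a `dsd_gate`.
#' @return sorted integer vector of template positions (possibly empty,
#'   as for the blunt AND duplex).
#' @export
exposed_toeholds <- function(gate) {
  stopifnot(inherits(gate, "dsd_gate"))
  n <- length(gate$template$domains)
  setdiff(seq_len(n), seq.int(gate$footprint[1], gate$footprint[2]))
}

#' Anchor sites of an invader strand on a gate
#'
#' Strong anchors are exposed template positions the invader complements;
#' weak anchors are template terminal positions (1 or n) it complements,
#' reachable only through end fraying even while paired.
#'
#' @param invader a [strand()] whose domains complement a contiguous
#'   template run.
#' @param gate a `dsd_gate`.
#' @return a data frame with columns `position` (integer) and `kind`
#'   (`"strong_toehold"` or `"weak_fray"`), ordered by position; zero rows
#'   if the strand has no anchor (e.g. the MAJORITY `fh` input alone).
#' @export
anchor_sites <- function(invader, gate) {
  stopifnot(inherits(gate, "dsd_gate"))
  run <- strand_run(invader, gate$template)
  n <- length(gate$template$domains)
  exposed <- exposed_toeholds(gate)
  pos <- seq.int(run[1], run[2])
  kind <- ifelse(pos %in% exposed, "strong_toehold",
                 ifelse(pos %in% c(1L, n), "weak_fray", NA_character_))
  keep <- !is.na(kind)
  data.frame(position = pos[keep], kind = kind[keep],
             stringsAsFactors = FALSE)
}

# resolve a "set of inputs" to sorted indices into gate$inputs
resolve_inputs <- function(gate, present) {
  if (is.null(present) || length(present) == 0L) return(integer(0))
  if (inherits(present, "dsd_strand")) present <- list(present)
  if (is.list(present) && all(vapply(present, inherits, NA, "dsd_strand"))) {
    idx <- vapply(present, function(s) {
      for (i in seq_along(gate$inputs))
        if (identical(gate$inputs[[i]]$domains, s$domains) &&
            gate$inputs[[i]]$name == s$name) return(i)
      stop("strand '", s$name, "' is not an input of gate '", gate$name,
           "'", call. = FALSE)
    }, 0L)
  } else if (is.character(present)) {
    nms <- vapply(gate$inputs, `[[`, "", "name")
    idx <- match(present, nms)
    if (anyNA(idx))
      stop("unknown input(s): ", paste(present[is.na(idx)], collapse = ", "),
           call. = FALSE)
  } else {
    idx <- as.integer(present)
    if (anyNA(idx) || any(idx < 1L | idx > length(gate$inputs)))
      stop("input indices must lie in 1..", length(gate$inputs),
           call. = FALSE)
  }
  sort(unique(idx))
}

#' Grow displacement chains to fixpoint
#'
#' Seeds a chain at every anchor site of every present input, then
#' repeatedly joins any present input whose template run overlaps a
#' chain's coverage in at least one position, extending the coverage over
#' the joined run, until nothing changes. The result is independent of
#' the order in which inputs are considered.
#'
#' @param gate a `dsd_gate`.
#' @param present the present input strands: a list of strands, a
#'   character vector of input names, or integer indices into
#'   `gate$inputs`.
#' @param trace emit a `message()` per chain event (anchor / join).
#' @return an object of class `dsd_chain_set`: a list with `chains` (each
#'   chain has `anchor_kind`, `anchor_position`, `members` — input names —
#'   and `coverage = c(lo, hi)`) and `strong_coverage`, the union of
#'   strong-chain coverages as a position vector.
#' @export
extend_chains <- function(gate, present, trace = FALSE) {
  stopifnot(inherits(gate, "dsd_gate"))
  idx <- resolve_inputs(gate, present)
  empty <- structure(list(chains = list(), strong_coverage = integer(0)),
                     class = "dsd_chain_set")
  if (length(idx) == 0L) return(empty)

  runs <- lapply(gate$inputs, strand_run, template = gate$template)
  overlap <- function(a, b) max(a[1], b[1]) <= min(a[2], b[2])

  # connected components of the run-overlap graph over present inputs;
  # joining to fixpoint is exactly reachability in this graph
  comp <- seq_along(idx)
  repeat {
    changed <- FALSE
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (comp[a] != comp[b] && overlap(runs[[idx[a]]], runs[[idx[b]]])) {
        comp[comp == comp[b]] <- comp[a]
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  chains <- list()
  seen <- character(0)
  for (a in seq_along(idx)) {
    i <- idx[a]
    anchors <- anchor_sites(gate$inputs[[i]], gate)
    if (nrow(anchors) == 0L) next
    members <- idx[comp == comp[a]]
    cov <- range(unlist(lapply(runs[members], function(r) r[1]:r[2])))
    for (k in seq_len(nrow(anchors))) {
      kind <- anchors$kind[k]
      key <- paste(kind, paste(members, collapse = ","),
                   cov[1], cov[2], sep = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      if (trace)
        message(sprintf("anchor %s@%d -> chain {%s} covering %d..%d",
                        gate$inputs[[i]]$name, anchors$position[k],
                        paste(vapply(gate$inputs[members], `[[`, "", "name"),
                              collapse = ","), cov[1], cov[2]))
      chains[[length(chains) + 1L]] <- list(
        anchor_kind = kind,
        anchor_position = anchors$position[k],
        members = vapply(gate$inputs[members], `[[`, "", "name"),
        member_idx = members,
        coverage = c(cov[1], cov[2]))
    }
  }
  # deterministic presentation: by anchor position, then anchor kind
  ord <- order(vapply(chains, `[[`, 0L, "anchor_position"),
               vapply(chains, `[[`, "", "anchor_kind"))
  chains <- chains[ord]
  strong <- chains[vapply(chains, `[[`, "", "anchor_kind") ==
                     "strong_toehold"]
  strong_cov <- sort(unique(unlist(
    lapply(strong, function(ch) ch$coverage[1]:ch$coverage[2]))))
  structure(list(chains = chains,
                 strong_coverage = as.integer(strong_cov %||% integer(0))),
            class = "dsd_chain_set")
}

#' @export
print.dsd_chain_set <- function(x, ...) {
  if (length(x$chains) == 0L) {
    cat("<chain set: empty>\n")
    return(invisible(x))
  }
  cat(sprintf("<chain set: %d chain(s)>\n", length(x$chains)))
  for (ch in x$chains)
    cat(sprintf("  %s@%d {%s} covers %d..%d\n", ch$anchor_kind,
                ch$anchor_position, paste(ch$members, collapse = ","),
                ch$coverage[1], ch$coverage[2]))
  invisible(x)
}

#' Decide reporter release from a chain set
#'
#' Release (bit 1) iff some single chain's coverage contains the whole
#' incumbent footprint, or the union of strong-anchored chains' coverages
#' does. A union of disconnected weak chains does not release: two
#' independent fray events cannot sustain a continuous migration front.
#'
#' @param gate a `dsd_gate`.
#' @param chains a `dsd_chain_set` from [extend_chains()] on the same gate.
#' @return integer bit, 0 or 1.
#' @export
release_decision <- function(gate, chains) {
  stopifnot(inherits(gate, "dsd_gate"), inherits(chains, "dsd_chain_set"))
  fp <- seq.int(gate$footprint[1], gate$footprint[2])
  for (ch in chains$chains)
    if (all(fp >= ch$coverage[1] & fp <= ch$coverage[2])) return(1L)
  if (all(fp %in% chains$strong_coverage)) return(1L)
  0L
}

#' Evaluate a gate on one input state
#'
#' @param gate a `dsd_gate`.
#' @param state an input triple: `c(1, 0, 1)`, the string `"101"`, or the
#'   paper-style string `"(1 0 1)"`; order is (INPUT1, INPUT2, INPUT3).
#' @return integer bit: 1 if the reporter is released, else 0.
#' @examples
#' evaluate_gate(paper_gate("AND"), "111")
#' evaluate_gate(paper_gate("MAJORITY"), c(1, 0, 1))
#' @export
evaluate_gate <- function(gate, state) {
  bits <- parse_state(state)
  release_decision(gate, extend_chains(gate, which(bits == 1L)))
}

#' Truth table of a gate (logical engine)
#'
#' Evaluates all eight input combinations in the fixed state order
#' (0 0 0)(1 0 0)(0 1 0)(0 0 1)(1 1 0)(1 0 1)(0 1 1)(1 1 1).
#'
#' @param gate a `dsd_gate`.
#' @return a `dsd_truth_table`: a data frame with columns `input1`,
#'   `input2`, `input3`, `output` and 8 rows in the fixed order.
#' @export
truth_table <- function(gate) {
  out <- vapply(seq_len(nrow(STATE_ORDER)), function(r)
    evaluate_gate(gate, STATE_ORDER[r, ]), 0L)
  new_truth_table(out)
}

new_truth_table <- function(output, signal = NULL) {
  tt <- as.data.frame(STATE_ORDER)
  tt$output <- as.integer(output)
  if (!is.null(signal)) tt$signal <- signal
  class(tt) <- c("dsd_truth_table", "data.frame")
  tt
}

#' @export
print.dsd_truth_table <- function(x, ...) {
  cat("state      output", if ("signal" %in% names(x)) "  signal_au", "\n",
      sep = "")
  for (r in seq_len(nrow(x))) {
    cat(sprintf("(%d %d %d)    %d", x$input1[r], x$input2[r], x$input3[r],
                x$output[r]))
    if ("signal" %in% names(x)) cat(sprintf("       %6.1f", x$signal[r]))
    cat("\n")
  }
  invisible(x)
}

#' Write / read a truth table as CSV
#'
#' Column order `input1,input2,input3,output(,signal)`; the eight rows are
#' kept in the fixed state order, so the files round-trip losslessly.
#'
#' @param tt a `dsd_truth_table`.
#' @param path CSV path.
#' @return `write_truth_table()`: `path`, invisibly; `read_truth_table()`:
#'   a `dsd_truth_table`.
#' @export
write_truth_table <- function(tt, path) {
  stopifnot(inherits(tt, "dsd_truth_table"))
  utils::write.csv(as.data.frame(tt), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("input1", "input2", "input3", "output")
  if (!all(need %in% names(df)) || nrow(df) != 8L)
    stop("not a truth-table CSV: ", path, call. = FALSE)
  if (!identical(as.matrix(df[, 1:3]), unname(STATE_ORDER)) &&
      !all(as.matrix(df[, 1:3]) == STATE_ORDER))
    stop("truth-table CSV rows are not in the fixed state order",
         call. = FALSE)
  new_truth_table(df$output, signal = df$signal)
}

#' Parse and format input states
#'
#' `parse_state()` accepts a bit vector `c(1,0,1)`, a compact string
#' `"101"`, or the paper-style `"(1 0 1)"`. `format_state()` renders the
#' canonical paper form.
#'
#' @param state the state in any accepted form.
#' @return `parse_state()`: integer vector of three bits;
#'   `format_state()`: a string like `"(1 0 1)"`.
#' @export
parse_state <- function(state) {
  if (is.character(state) && length(state) == 1L) {
    digits <- strsplit(gsub("[^01]", "", state), "")[[1]]
    state <- suppressWarnings(as.integer(digits))
  }
  state <- suppressWarnings(as.integer(state))
  if (length(state) != 3L || anyNA(state) || !all(state %in% c(0L, 1L)))
    stop("state must be three bits, e.g. \"101\" or \"(1 0 1)\"",
         call. = FALSE)
  state
}

#' @rdname parse_state
#' @export
format_state <- function(state) {
  paste0("(", paste(parse_state(state), collapse = " "), ")")
}
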