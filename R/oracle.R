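# Brute-force verification oracle.
#
# Breadth-first search over per-position binding states of one template
# molecule under elementary moves: binding at a free position of the
# invader's run, terminal-fray binding at template position 1 or n,
# binding onto a position held by an overlapping fellow invader (internal
# toehold), and single-position branch-migration steps in either
# direction (for invaders and for the incumbent alike). A strand that has
# lost every position has unbound; strand copies are in excess, so
# rebinding is always available. The search is exhaustive, so it serves
# as an independent check on the chain-reachability engine.

#' Brute-force displacement oracle
#'
#' Explores the reachable binding states of a gate exhaustively and
#' reports whether the incumbent can be fully displaced, under the same
#' anchoring discipline as the chain rules: release is recognised in a
#' state where the incumbent holds nothing and either a single
#' run-overlap-connected group of invaders holds the whole footprint, or
#' groups able to anchor at exposed toeholds jointly hold it. Without
#' that discipline two disconnected end-fray fronts would open the blunt
#' AND duplex, which the cooperative design forbids.
#'
#' @param gate a `dsd_gate` with at most 8 template domains.
#' @param present the present input strands (see [extend_chains()]).
#' @param max_states state budget; exceeding it raises an error marked
#'   inconclusive rather than returning a silent 0.
#' @return integer bit, 0 or 1.
#' @examples
#' oracle_enumerate(paper_gate("OR"), "efhg")
#' @export
oracle_enumerate <- function(gate, present, max_states = 200000L) {
  stopifnot(inherits(gate, "dsd_gate"))
  n <- length(gate$template$domains)
  if (n > 8L)
    stop("oracle supports at most 8 template domains, got ", n,
         call. = FALSE)
  idx <- resolve_inputs(gate, present)
  if (length(idx) > 6L)
    stop("oracle supports at most 6 invader species", call. = FALSE)
  fp <- seq.int(gate$footprint[1], gate$footprint[2])
  exposed <- exposed_toeholds(gate)
  runs <- lapply(gate$inputs[idx], strand_run, template = gate$template)
  k <- length(idx)

  # species s has strong-capable anchoring if its run meets an exposed
  # position; used to classify invader groups in the release check
  strong_capable <- vapply(runs, function(r) any(exposed >= r[1] &
                                                   exposed <= r[2]), NA)

  released <- function(occ) {
    if (any(occ == -1L)) return(FALSE)
    held <- lapply(seq_len(k), function(s) which(occ == s))
    active <- which(lengths(held) > 0L)
    if (length(active) == 0L) return(length(fp) == 0L)
    # run-overlap components over the species bound in this state
    comp <- seq_along(active)
    for (a in seq_along(active)) for (b in seq_along(active)) {
      ra <- runs[[active[a]]]; rb <- runs[[active[b]]]
      if (comp[a] != comp[b] && max(ra[1], rb[1]) <= min(ra[2], rb[2]))
        comp[comp == comp[b]] <- comp[a]
    }
    strong_held <- integer(0)
    for (cid in unique(comp)) {
      members <- active[comp == cid]
      hh <- unlist(held[members])
      if (all(fp %in% hh)) return(TRUE)
      if (any(strong_capable[members]))
        strong_held <- c(strong_held, hh)
    }
    all(fp %in% strong_held)
  }

  moves <- function(occ) {
    out <- list()
    add <- function(o) out[[length(out) + 1L]] <<- o
    for (s in seq_len(k)) {
      r <- runs[[s]]
      # binding of a fresh copy
      for (p in r[1]:r[2]) {
        o <- occ[p]
        if (o == s) next
        free_pos <- o == 0L
        terminal <- p == 1L || p == n
        onto_invader <- o > 0L
        if (free_pos || terminal || onto_invader) {
          occ2 <- occ; occ2[p] <- s; add(occ2)
        }
      }
      # single-position branch migration at block edges
      hh <- which(occ == s)
      if (length(hh) > 0L) {
        blocks <- split(hh, cumsum(c(1L, diff(hh) != 1L)))
        for (b in blocks) {
          for (t in c(min(b) - 1L, max(b) + 1L)) {
            if (t >= r[1] && t <= r[2] && occ[t] != s) {
              occ2 <- occ; occ2[t] <- s; add(occ2)
            }
          }
        }
      }
    }
    # the incumbent can migrate back over its footprint
    hh <- which(occ == -1L)
    if (length(hh) > 0L) {
      blocks <- split(hh, cumsum(c(1L, diff(hh) != 1L)))
      for (b in blocks) {
        for (t in c(min(b) - 1L, max(b) + 1L)) {
          if (t >= fp[1] && t <= fp[length(fp)] && occ[t] != -1L) {
            occ2 <- occ; occ2[t] <- -1L; add(occ2)
          }
        }
      }
    }
    out
  }

  init <- integer(n)
  init[fp] <- -1L
  visited <- new.env(hash = TRUE, parent = emptyenv())
  queue <- list(init)
  assign(paste(init, collapse = ","), TRUE, envir = visited)
  n_seen <- 1L
  head <- 1L
  while (head <= length(queue)) {
    occ <- queue[[head]]
    head <- head + 1L
    if (released(occ)) return(1L)
    for (occ2 in moves(occ)) {
      key <- paste(occ2, collapse = ",")
      if (!exists(key, envir = visited, inherits = FALSE)) {
        n_seen <- n_seen + 1L
        if (n_seen > max_states)
          stop("oracle inconclusive: state budget (", max_states,
               ") exceeded", call. = FALSE)
        assign(key, TRUE, envir = visited)
        queue[[length(queue) + 1L]] <- occ2
      }
    }
  }
  0L
}
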