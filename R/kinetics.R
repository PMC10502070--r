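# Kinetic layer: compile a gate + input combination into a stochastic
# mass-action network whose channels mirror the logical moves (strong
# anchoring, fray anchoring, overlap joining, dissociation of a lone
# anchored strand, reporter release), then sample it exactly and read the
# endpoint out as a fluorescence-style signal.
#
# Branch migration inside a chain is coarse-grained away: a complex is
# identified by which input species are bound to it and whether the
# reporter is still attached.

#' Rate parameters of the kinetic layer
#'
#' Rates are stochastic mass-action constants in arbitrary time units.
#' The defaults separate the fast toehold-mediated channels from the slow
#' terminal-fray channel by three orders of magnitude, the qualitative
#' hierarchy of strand-displacement kinetics.
#'
#' @param k_strong strong-toehold anchoring, per molecule pair.
#' @param k_join overlap chain-joining (internal toehold), per pair.
#' @param k_release reporter release once its footprint is displaceable.
#' @param k_fray terminal-fray anchoring; must stay below `k_strong`.
#' @param k_unbind1 dissociation of a strand that is alone in its chain
#'   (holding little more than its anchor).
#' @return a named list of class `dsd_rates`.
#' @export
rate_parameters <- function(k_strong = 1, k_join = 1, k_release = 10,
                            k_fray = 1e-3, k_unbind1 = 0.1) {
  r <- list(k_strong = k_strong, k_join = k_join, k_release = k_release,
            k_fray = k_fray, k_unbind1 = k_unbind1)
  if (any(vapply(r, function(x) !is.numeric(x) || length(x) != 1L ||
                   is.na(x) || x < 0, NA)))
    stop("all rates must be single non-negative numbers", call. = FALSE)
  if (r$k_fray >= r$k_strong)
    stop("k_fray must be smaller than k_strong", call. = FALSE)
  structure(r, class = "dsd_rates")
}

# merge rate overrides (e.g. a gate file's `kinetics` section) onto defaults
merge_rates <- function(base, overrides) {
  for (nm in intersect(names(overrides), names(base))) {
    base[[nm]] <- overrides[[nm]]
  }
  do.call(rate_parameters, unclass(base))
}

#' Compile a gate and input state into a reaction network
#'
#' Species are the reachable complex configurations (which inputs are
#' bound; reporter attached or released) plus the free strands. Channels:
#' an input with a strong anchor binds at `k_strong`; an input whose run
#' overlaps an anchored chain on the complex joins at `k_join`; an input
#' with only a terminal-fray anchor binds at `k_fray`; an input alone in
#' its chain falls off at `k_unbind1`; a complex whose bound set satisfies
#' the release rule emits the reporter at `k_release` (after which the
#' complex is inert). Initial counts follow the 1:1 stoichiometry of
#' inputs to annealed duplex.
#'
#' @param gate a `dsd_gate`.
#' @param state input bit-triple (any form accepted by [parse_state()]).
#' @param rates a [rate_parameters()] object.
#' @param copies molecule count of the annealed duplex and of each
#'   present input.
#' @param max_species cap on network size.
#' @return an object of class `dsd_network`: species names, initial
#'   counts, reaction list (`reactants`, `products`, `rate`, `kind`), and
#'   a strand-content matrix used for conservation checks and readout.
#' @export
compile_reactions <- function(gate, state, rates = rate_parameters(),
                              copies = 100L, max_species = 512L) {
  stopifnot(inherits(gate, "dsd_gate"))
  if (!inherits(rates, "dsd_rates")) rates <- do.call(rate_parameters, rates)
  copies <- as.integer(copies)
  if (is.na(copies) || copies < 1L) stop("copies must be >= 1", call. = FALSE)
  bits <- parse_state(state)
  present <- which(bits == 1L)

  runs <- lapply(gate$inputs, strand_run, template = gate$template)
  anch <- lapply(gate$inputs, anchor_sites, gate = gate)
  has_strong <- vapply(anch, function(a) any(a$kind == "strong_toehold"), NA)
  has_fray <- vapply(anch, function(a) any(a$kind == "weak_fray"), NA)
  overlap <- function(a, b) max(a[1], b[1]) <= min(a[2], b[2])

  # run-overlap components of a bound set; a component is anchored if any
  # member can anchor by itself
  components <- function(B) {
    if (length(B) == 0L) return(list())
    comp <- seq_along(B)
    for (a in seq_along(B)) for (b in seq_along(B))
      if (comp[a] != comp[b] && overlap(runs[[B[a]]], runs[[B[b]]]))
        comp[comp == comp[b]] <- comp[a]
    lapply(unique(comp), function(cid) B[comp == cid])
  }
  bind_channel <- function(B, s) {
    # NULL if s cannot bind to a complex with bound set B
    if (has_strong[s]) return(list(rate = rates$k_strong,
                                   kind = "strong_anchor"))
    joinable <- any(vapply(components(B), function(cc) {
      anchored <- any(has_strong[cc] | has_fray[cc])
      cov <- range(unlist(lapply(runs[cc], function(r) r[1]:r[2])))
      anchored && overlap(cov, runs[[s]])
    }, NA))
    if (joinable) return(list(rate = rates$k_join, kind = "join"))
    if (has_fray[s]) return(list(rate = rates$k_fray, kind = "fray_anchor"))
    NULL
  }

  set_key <- function(B) paste0("s", paste(B, collapse = "."))
  cplx_name <- function(B, inc) {
    mem <- if (length(B) == 0L) "empty"
      else paste(vapply(gate$inputs[B], `[[`, "", "name"), collapse = "+")
    paste0("cplx{", mem, if (inc) "|rep}" else "}")
  }
  free_name <- function(s) paste0("free_in", s, "_", gate$inputs[[s]]$name)

  # enumerate reachable bound sets (incumbent attached) from the empty set
  sets <- list(integer(0))
  keys <- set_key(integer(0))
  head <- 1L
  edges <- list() # list of (from_key, to_key, rate, kind, s)
  while (head <= length(sets)) {
    B <- sets[[head]]; head <- head + 1L
    for (s in setdiff(present, B)) {
      ch <- bind_channel(B, s)
      if (is.null(ch)) next
      B2 <- sort(c(B, s))
      if (!(set_key(B2) %in% keys)) {
        sets[[length(sets) + 1L]] <- B2
        keys <- c(keys, set_key(B2))
        if (length(sets) > max_species)
          stop("network exceeds ", max_species,
               " species; reduce the input set or use the logical engine",
               call. = FALSE)
      }
      edges[[length(edges) + 1L]] <-
        list(from = set_key(B), to = set_key(B2), rate = ch$rate,
             kind = ch$kind, s = s)
    }
    # dissociation of strands alone in their chain
    for (cc in components(B)) {
      if (length(cc) == 1L && (has_strong[cc] || has_fray[cc])) {
        B2 <- setdiff(B, cc)
        edges[[length(edges) + 1L]] <-
          list(from = set_key(B), to = set_key(B2),
               rate = rates$k_unbind1, kind = "unbind1", s = cc)
      }
    }
  }

  releasing <- vapply(sets, function(B)
    release_decision(gate, extend_chains(gate, B)) == 1L, NA)

  species <- c(vapply(sets, cplx_name, "", inc = TRUE),
               vapply(sets[releasing], cplx_name, "", inc = FALSE),
               vapply(present, free_name, ""),
               "free_reporter")
  sp_id <- seq_along(species)
  names(sp_id) <- species
  cplx_inc_id <- sp_id[vapply(sets, cplx_name, "", inc = TRUE)]
  names(cplx_inc_id) <- keys
  cplx_rel_id <- sp_id[vapply(sets[releasing], cplx_name, "", inc = FALSE)]
  names(cplx_rel_id) <- keys[releasing]
  free_id <- if (length(present) > 0L) sp_id[vapply(present, free_name, "")]
             else integer(0)
  names(free_id) <- as.character(present)

  reactions <- list()
  add_rx <- function(reactants, products, rate, kind) {
    reactions[[length(reactions) + 1L]] <<-
      list(reactants = reactants, products = products, rate = rate,
           kind = kind)
  }
  for (e in edges) {
    fr <- unname(cplx_inc_id[e$from]); to <- unname(cplx_inc_id[e$to])
    fs <- unname(free_id[as.character(e$s)])
    if (e$kind == "unbind1") add_rx(fr, c(to, fs), e$rate, e$kind)
    else add_rx(c(fr, fs), to, e$rate, e$kind)
  }
  for (i in which(releasing)) {
    add_rx(unname(cplx_inc_id[keys[i]]),
           c(unname(cplx_rel_id[keys[i]]), sp_id[["free_reporter"]]),
           rates$k_release, "release")
  }

  # strand content per species (template, reporter, input1..3)
  strand_ids <- c("template", "reporter", paste0("input", seq_along(gate$inputs)))
  content <- matrix(0L, nrow = length(strand_ids), ncol = length(species),
                    dimnames = list(strand_ids, species))
  for (i in seq_along(sets)) {
    cid <- cplx_inc_id[keys[i]]
    content["template", cid] <- 1L
    content["reporter", cid] <- 1L
    for (s in sets[[i]]) content[paste0("input", s), cid] <- 1L
    if (releasing[i]) {
      rid <- cplx_rel_id[keys[i]]
      content["template", rid] <- 1L
      for (s in sets[[i]]) content[paste0("input", s), rid] <- 1L
    }
  }
  for (s in present) content[paste0("input", s), free_id[as.character(s)]] <- 1L
  content["reporter", "free_reporter"] <- 1L

  init <- integer(length(species))
  names(init) <- species
  init[cplx_inc_id[set_key(integer(0))]] <- copies
  for (s in present) init[free_id[as.character(s)]] <- copies

  structure(list(gate_name = gate$name, state = bits, species = species,
                 init = init, reactions = reactions, content = content,
                 rates = rates, copies = copies),
            class = "dsd_network")
}

#' @export
print.dsd_network <- function(x, ...) {
  cat(sprintf("<reaction network: gate '%s', state %s, %d species, %d reactions>\n",
              x$gate_name, format_state(x$state), length(x$species),
              length(x$reactions)))
  invisible(x)
}

#' Check strand-count conservation of a network
#'
#' Every reaction must conserve the total copy number of each strand
#' species (template, reporter, each input).
#'
#' @param network a `dsd_network`.
#' @return `TRUE` invisibly; stops with the offending reaction otherwise.
#' @export
check_conservation <- function(network) {
  stopifnot(inherits(network, "dsd_network"))
  for (j in seq_along(network$reactions)) {
    rx <- network$reactions[[j]]
    delta <- rowSums(network$content[, rx$products, drop = FALSE]) -
      rowSums(network$content[, rx$reactants, drop = FALSE])
    if (any(delta != 0L))
      stop("reaction ", j, " (", rx$kind, ") does not conserve strand ",
           paste(rownames(network$content)[delta != 0L], collapse = ", "),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Exact stochastic simulation of a compiled network
#'
#' Gillespie's direct method; statistically exact sampling of the jump
#' process. Identical `(network, t_end, seed)` give identical
#' trajectories.
#'
#' @param network a `dsd_network` from [compile_reactions()].
#' @param t_end simulated duration (arbitrary time units).
#' @param seed integer seed for the run's random number stream; the
#'   caller's RNG state is left untouched.
#' @param record if `TRUE` (default) every jump is recorded and returned;
#'   if `FALSE` only the final state is kept (used for endpoint readouts).
#' @param max_events hard guard against runaway simulations.
#' @return an object of class `dsd_trajectory`: `times`, `counts` (matrix
#'   jumps x species; a single final row when `record = FALSE`),
#'   `final`, `t_final`, `n_events`, `seed` and the originating `network`.
#' @export
simulate_network <- function(network, t_end = 1e4, seed = 1L,
                             record = TRUE, max_events = 5e7) {
  stopifnot(inherits(network, "dsd_network"))
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be > 0",
                                             call. = FALSE)
  sp_index <- seq_along(network$species)
  names(sp_index) <- network$species
  n_rx <- length(network$reactions)
  reactants <- lapply(network$reactions, function(rx)
    as.integer(rx$reactants) - 1L)
  stoich <- matrix(0L, nrow = length(network$species),
                   ncol = max(n_rx, 1L))
  for (j in seq_len(n_rx)) {
    rx <- network$reactions[[j]]
    for (i in rx$reactants) stoich[i, j] <- stoich[i, j] - 1L
    for (i in rx$products) stoich[i, j] <- stoich[i, j] + 1L
  }
  rates <- vapply(network$reactions, `[[`, 0, "rate")

  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  res <- if (n_rx == 0L) {
    list(final = as.numeric(network$init), t_final = t_end, n_events = 0,
         times = 0, counts = matrix(as.numeric(network$init), nrow = 1L))
  } else {
    ssa_core(unname(network$init), reactants, stoich, rates,
             as.numeric(t_end), as.numeric(max_events), isTRUE(record))
  }
  counts <- if (!is.null(res$counts)) res$counts
            else matrix(res$final, nrow = 1L)
  colnames(counts) <- network$species
  structure(list(times = if (!is.null(res$times)) as.numeric(res$times)
                         else res$t_final,
                 counts = counts,
                 final = stats::setNames(as.numeric(res$final),
                                         network$species),
                 t_final = res$t_final, n_events = res$n_events,
                 seed = as.integer(seed), network = network),
            class = "dsd_trajectory")
}

#' @export
print.dsd_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %s events over t = 0..%.4g (seed %d)>\n",
              format(x$n_events, big.mark = ","), x$t_final, x$seed))
  invisible(x)
}

#' Write a trajectory as long-format TSV
#'
#' One row per (time, species, count) triple.
#'
#' @param trajectory a `dsd_trajectory` recorded with `record = TRUE`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "dsd_trajectory"))
  long <- data.frame(
    time = rep(trajectory$times, times = ncol(trajectory$counts)),
    species = rep(colnames(trajectory$counts),
                  each = nrow(trajectory$counts)),
    count = as.vector(trajectory$counts))
  utils::write.table(long[order(long$time, long$species), ], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fluorescence-style readout of a trajectory endpoint
#'
#' The free fraction is the share of reporter strands not co-complexed
#' with the quencher-labelled template at the end of the run; the signal
#' is `free_fraction * F_max`. Signals strictly above the boundary
#' binarize to 1; a signal exactly on the boundary is reported as 0 with
#' a warning (the boundary rule only defines "above" and "below").
#'
#' @param trajectory a `dsd_trajectory`.
#' @param F_max full-scale signal in arbitrary units.
#' @param boundary binarization threshold in the same units.
#' @return an object of class `dsd_readout`: `free_fraction`,
#'   `signal_au`, `bit`.
#' @export
readout <- function(trajectory, F_max = 150, boundary = 50) {
  stopifnot(inherits(trajectory, "dsd_trajectory"))
  if (!(F_max > boundary && boundary > 0))
    stop("need F_max > boundary > 0", call. = FALSE)
  content <- trajectory$network$content
  total <- sum(content["reporter", ] * trajectory$final)
  free <- trajectory$final[["free_reporter"]]
  ff <- if (total > 0) free / total else 0
  signal <- ff * F_max
  if (signal == boundary)
    warning("signal sits exactly on the boundary; reporting bit 0",
            call. = FALSE)
  structure(list(free_fraction = ff, signal_au = signal,
                 bit = as.integer(signal > boundary)),
            class = "dsd_readout")
}

#' @export
print.dsd_readout <- function(x, ...) {
  cat(sprintf("<readout: free fraction %.3f, signal %.1f au, bit %d>\n",
              x$free_fraction, x$signal_au, x$bit))
  invisible(x)
}

#' Kinetic truth table
#'
#' Runs the stochastic engine for each of the eight input states and a
#' set of seeds; each row reports the median endpoint signal over seeds
#' and its binarization.
#'
#' @param gate a `dsd_gate` (its `kinetics` file section, if any, is
#'   applied on top of `rates`).
#' @param rates a [rate_parameters()] object.
#' @param copies duplex / input copy number (1:1 stoichiometry).
#' @param t_end simulated duration per run.
#' @param seeds integer vector of seeds (one run per seed and state).
#' @param F_max,boundary readout scale and threshold, see [readout()].
#' @return a `dsd_truth_table` with a `signal` column (median over
#'   seeds); attributes `per_seed_signal` (8 x n_seeds matrix) and
#'   `seeds`.
#' @export
kinetic_truth_table <- function(gate, rates = rate_parameters(),
                                copies = 100L, t_end = 1e4, seeds = 1:10,
                                F_max = 150, boundary = 50) {
  stopifnot(inherits(gate, "dsd_gate"), length(seeds) >= 1L)
  rates <- merge_rates(rates, gate$kinetics)
  sig <- matrix(NA_real_, nrow = nrow(STATE_ORDER), ncol = length(seeds))
  for (r in seq_len(nrow(STATE_ORDER))) {
    net <- compile_reactions(gate, STATE_ORDER[r, ], rates, copies)
    for (j in seq_along(seeds)) {
      traj <- simulate_network(net, t_end = t_end, seed = seeds[j],
                               record = FALSE)
      sig[r, j] <- readout(traj, F_max, boundary)$signal_au
    }
  }
  med <- apply(sig, 1L, stats::median)
  tt <- new_truth_table(as.integer(med > boundary), signal = med)
  attr(tt, "per_seed_signal") <- sig
  attr(tt, "seeds") <- as.integer(seeds)
  attr(tt, "boundary") <- boundary
  tt
}
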