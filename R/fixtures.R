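# Synthetic gate generator: structural analogues of the three built-in
# designs plus fully random valid systems, used as the test surface for
# the engines and the oracle.

#' Generate a synthetic gate system
#'
#' \describe{
#'   \item{`"OR-like"`}{reporter on the interior run `2..n-1`, toeholds
#'     exposed at both ends; inputs analogous to `efh`/`fhg`/`efhg`
#'     (each single input displaces). Needs `n_domains >= 3`.}
#'   \item{`"AND-like"`}{blunt full-footprint duplex with inputs tiling
#'     the template in two halves plus a strand bridging the junction
#'     (all three needed). Needs `n_domains >= 4`.}
#'   \item{`"MAJORITY-like"`}{reporter on `2..n-1`; inputs are the two
#'     toehold-anchored halves plus a copy of the reporter's composition
#'     (any two suffice). Needs `n_domains >= 4`.}
#'   \item{`"random-valid"`}{random contiguous footprint and three random
#'     contiguous input runs; structurally valid but with an arbitrary
#'     truth table. Needs `n_domains <= 8` (oracle bounds).}
#' }
#'
#' Template domains are named `A`, `B`, ... in order; terminal and
#' exposed domains are 6-nt toeholds, interior covered domains 15-nt
#' recognition domains.
#'
#' @param kind one of `"OR-like"`, `"AND-like"`, `"MAJORITY-like"`,
#'   `"random-valid"`.
#' @param n_domains template length in domains (2..8; see per-kind
#'   minima above).
#' @param seed integer; identical `(kind, n_domains, seed)` give an
#'   identical gate.
#' @return a validated `dsd_gate`.
#' @examples
#' truth_table(generate_fixture("OR-like", 5, seed = 1))
#' @export
generate_fixture <- function(kind = c("OR-like", "AND-like",
                                      "MAJORITY-like", "random-valid"),
                             n_domains = 4L, seed = 1L) {
  kind <- match.arg(kind)
  n <- as.integer(n_domains)
  if (is.na(n) || n < 2L || n > 8L)
    stop("n_domains must lie in 2..8", call. = FALSE)
  min_n <- switch(kind, "OR-like" = 3L, "AND-like" = 4L,
                  "MAJORITY-like" = 4L, "random-valid" = 2L)
  if (n < min_n)
    stop(kind, " fixtures need at least ", min_n, " domains",
         call. = FALSE)

  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  m <- n %/% 2L
  if (kind == "random-valid") {
    rand_run <- function() {
      a <- sample.int(n, 1L)
      c(a, a + sample.int(n - a + 1L, 1L) - 1L)
    }
    fp <- rand_run()
    runs <- replicate(3L, rand_run(), simplify = FALSE)
  } else {
    fp <- switch(kind,
                 "OR-like" = c(2L, n - 1L),
                 "AND-like" = c(1L, n),
                 "MAJORITY-like" = c(2L, n - 1L))
    runs <- switch(kind,
                   "OR-like" = list(c(1L, n - 1L), c(2L, n), c(1L, n)),
                   "AND-like" = list(c(1L, m), c(m + 1L, n), c(m, m + 1L)),
                   "MAJORITY-like" = list(c(1L, m), c(m + 1L, n),
                                          c(2L, n - 1L)))
  }

  upper <- LETTERS[seq_len(n)]
  role <- ifelse(seq_len(n) < fp[1] | seq_len(n) > fp[2] |
                   seq_len(n) %in% c(1L, n), "toehold", "recognition")
  run_strand <- function(r, label = "none") {
    doms <- tolower(upper[r[1]:r[2]])
    strand(paste(doms, collapse = ""), doms, label)
  }
  template <- strand(paste(upper, collapse = ""), upper, "quencher_BHQ1")
  incumbent <- run_strand(fp, "fluorophore_FAM")
  inputs <- lapply(runs, run_strand)

  build_gate_system(
    list(domains = data.frame(name = upper, role = role,
                              length = ifelse(role == "toehold", 6L, 15L),
                              stringsAsFactors = FALSE),
         strands = c(list(template, incumbent), inputs),
         gate = list(template = template$name, incumbent = incumbent$name,
                     footprint = fp, inputs = inputs)),
    name = sprintf("%s_n%d_s%d", kind, n, as.integer(seed)))
}
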