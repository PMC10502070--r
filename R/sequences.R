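# Nucleotide-level layer: assign concrete ACGT sequences to domains,
# screen them for cross-hybridisation, and move strand sets through
# FASTA. Domain-level semantics never depend on this layer; it exists so
# designed gates can be ordered and checked.

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

kmers <- function(x, k) {
  if (nchar(x) < k) return(character(0))
  unique(substring(x, seq_len(nchar(x) - k + 1L),
                   seq_len(nchar(x) - k + 1L) + k - 1L))
}

max_homopolymer <- function(x) {
  r <- rle(strsplit(x, "")[[1]])
  max(r$lengths)
}

gc_fraction <- function(x) {
  chars <- strsplit(x, "")[[1]]
  mean(chars %in% c("G", "C"))
}

#' Assign nucleotide sequences to the domains of a gate
#'
#' Samples a random ACGT sequence for each canonical (upper-case) domain
#' and derives the lower-case partner as its reverse complement. Accepted
#' sequences satisfy: GC fraction within `gc_range`, no homopolymer run
#' longer than 4, and (for domains at least `screen_k` long) no length-k
#' word shared, in either orientation, with any previously assigned
#' domain — so the produced sets pass [validate_orthogonality()] at the
#' same word length by construction.
#'
#' @param gate a `dsd_gate` whose domain table carries lengths.
#' @param seed integer; same `(gate, seed)` gives the same assignment.
#' @param gc_range closed interval of admissible GC fractions.
#' @param screen_k word length of the cross-talk screen.
#' @param max_tries rejection-sampling budget per domain.
#' @return a named character vector of class `dsd_seq_assignment`
#'   mapping every domain name (both cases) to its sequence.
#' @export
assign_sequences <- function(gate, seed, gc_range = c(0.3, 0.7),
                             screen_k = 6L, max_tries = 10000L) {
  stopifnot(inherits(gate, "dsd_gate"))
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  canon <- unique(toupper(gate$domains$name))
  lens <- gate$domains$length[match(canon, toupper(gate$domains$name))]
  assignment <- character(0)
  banned <- character(0) # k-mers of accepted sequences, both orientations
  for (i in seq_along(canon)) {
    len <- lens[i]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                    collapse = "")
      gc <- gc_fraction(cand)
      if (gc < gc_range[1] || gc > gc_range[2]) next
      if (max_homopolymer(cand) > 4L) next
      words <- c(kmers(cand, screen_k), kmers(revcomp(cand), screen_k))
      if (length(intersect(words, banned)) > 0L) next
      ok <- TRUE
      break
    }
    if (!ok)
      stop("cannot satisfy sequence constraints for domain '", canon[i],
           "' (length ", len, ", GC in [", gc_range[1], ", ", gc_range[2],
           "])", call. = FALSE)
    assignment[canon[i]] <- cand
    assignment[tolower(canon[i])] <- revcomp(cand)
    banned <- c(banned, kmers(cand, screen_k), kmers(revcomp(cand), screen_k))
  }
  structure(assignment, class = "dsd_seq_assignment",
            gc_range = gc_range, screen_k = as.integer(screen_k))
}

#' Sequence of a strand under an assignment
#'
#' 5'->3' concatenation of the strand's domain sequences.
#'
#' @param x a [strand()].
#' @param assignment a `dsd_seq_assignment`.
#' @return a single character string.
#' @export
strand_sequence <- function(x, assignment) {
  miss <- setdiff(x$domains, names(assignment))
  if (length(miss) > 0L)
    stop("no sequence assigned for domain(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  paste(assignment[x$domains], collapse = "")
}

#' Screen an assignment for cross-hybridisation
#'
#' Reports every pair of non-complementary domains that shares a
#' length-`k` word with the reverse complement of the other (i.e. could
#' form a spurious k-base-pair duplex). An empty report is a pass.
#'
#' @param assignment a `dsd_seq_assignment` (any named character vector
#'   of domain sequences works).
#' @param k word length, at least 4.
#' @return a data frame with columns `domain_a`, `domain_b`,
#'   `shared_word`, one row per offending word.
#' @export
validate_orthogonality <- function(assignment, k = 6L) {
  k <- as.integer(k)
  if (is.na(k) || k < 4L) stop("k must be >= 4", call. = FALSE)
  nms <- names(assignment)
  out <- data.frame(domain_a = character(0), domain_b = character(0),
                    shared_word = character(0), stringsAsFactors = FALSE)
  if (length(nms) < 2L) return(out)
  for (a in seq_len(length(nms) - 1L)) for (b in (a + 1L):length(nms)) {
    if (complement(nms[a]) == nms[b]) next
    shared <- intersect(kmers(assignment[[a]], k),
                        kmers(revcomp(assignment[[b]]), k))
    if (length(shared) > 0L)
      out <- rbind(out, data.frame(domain_a = nms[a], domain_b = nms[b],
                                   shared_word = shared,
                                   stringsAsFactors = FALSE))
  }
  out
}

#' @describeIn validate_orthogonality write the report as TSV
#'   (columns `domain_a`, `domain_b`, `shared_word`).
#' @param report a report from `validate_orthogonality()`.
#' @param path output TSV path.
#' @export
write_orthogonality_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' FASTA export / import of a gate's strand set
#'
#' `write_gate_fasta()` emits one record per strand (template, incumbent,
#' then inputs), named by the strand name. `read_gate_fasta()`
#' reconstructs a sequence assignment from such a file by cutting each
#' record at the strand's domain boundaries, and validates it: records
#' must exist for every strand, contain only ACGT, have the exact
#' expected length, agree wherever a domain occurs more than once, and
#' satisfy reverse-complement pairing between complementary domains.
#'
#' @param gate a `dsd_gate`.
#' @param assignment a `dsd_seq_assignment` for writing.
#' @param path FASTA path.
#' @return `write_gate_fasta()`: `path`, invisibly; `read_gate_fasta()`:
#'   a `dsd_seq_assignment`.
#' @export
write_gate_fasta <- function(gate, assignment, path) {
  stopifnot(inherits(gate, "dsd_gate"))
  strands <- gate_strand_set(gate)
  seqs <- vapply(strands, strand_sequence, "", assignment = assignment)
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- vapply(strands, `[[`, "", "name")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# template, incumbent, inputs — in that order, without duplicating an
# input that is the very same object as the incumbent
gate_strand_set <- function(gate) {
  c(list(gate$template, gate$incumbent), gate$inputs)
}

#' @rdname write_gate_fasta
#' @export
read_gate_fasta <- function(gate, path) {
  stopifnot(inherits(gate, "dsd_gate"))
  set <- Biostrings::readDNAStringSet(path)
  recs <- as.character(set)
  names(recs) <- sub("\\s.*$", "", names(set))
  lens <- stats::setNames(gate$domains$length, gate$domains$name)

  assignment <- character(0)
  for (s in gate_strand_set(gate)) {
    hit <- recs[names(recs) == s$name]
    if (length(hit) == 0L)
      stop("FASTA record missing for strand '", s$name, "'", call. = FALSE)
    if (length(unique(hit)) > 1L)
      stop("FASTA records named '", s$name, "' disagree", call. = FALSE)
    seq <- toupper(hit[[1]])
    if (grepl("[^ACGT]", seq))
      stop("record '", s$name, "' contains non-ACGT characters",
           call. = FALSE)
    expected <- sum(lens[s$domains])
    if (nchar(seq) != expected)
      stop("record '", s$name, "' has length ", nchar(seq),
           ", expected ", expected, call. = FALSE)
    stops <- cumsum(lens[s$domains])
    starts <- c(1L, utils::head(stops, -1L) + 1L)
    for (d in seq_along(s$domains)) {
      dom <- s$domains[d]
      piece <- substring(seq, starts[d], stops[d])
      if (dom %in% names(assignment) && assignment[[dom]] != piece)
        stop("domain '", dom, "' has conflicting sequences across records",
             call. = FALSE)
      assignment[dom] <- piece
    }
  }
  # fill unseen complements, then check pairing
  for (nm in names(assignment)) {
    partner <- complement(nm)
    if (is.na(assignment[partner]))
      assignment[partner] <- revcomp(assignment[[nm]])
  }
  for (nm in names(assignment)) {
    partner <- complement(nm)
    if (assignment[[partner]] != revcomp(assignment[[nm]]))
      stop("domains '", nm, "' and '", partner,
           "' are not reverse complements in ", basename(path),
           call. = FALSE)
  }
  structure(assignment[order(toupper(names(assignment)),
                             names(assignment))],
            class = "dsd_seq_assignment")
}
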