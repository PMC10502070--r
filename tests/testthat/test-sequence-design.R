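test_that("sequence assignment is deterministic in (gate, seed)", {
  gate <- paper_gate("OR")
  a <- assign_sequences(gate, seed = 5)
  b <- assign_sequences(gate, seed = 5)
  expect_identical(as.character(a), as.character(b))
  c <- assign_sequences(gate, seed = 6)
  expect_false(identical(as.character(a), as.character(c)))
})

test_that("assignments satisfy pairing, length, GC and homopolymer rules", {
  for (g in c("OR", "AND")) {
    gate <- paper_gate(g)
    a <- assign_sequences(gate, seed = 3)
    lens <- stats::setNames(gate$domains$length, gate$domains$name)
    for (nm in names(a)) {
      expect_identical(nchar(a[[nm]]), as.integer(lens[[nm]]))
      expect_identical(a[[complement(nm)]],
                       dsdgates:::revcomp(a[[nm]]))
      gc <- dsdgates:::gc_fraction(a[[nm]])
      expect_true(gc >= 0.3 && gc <= 0.7)
      expect_lte(dsdgates:::max_homopolymer(a[[nm]]), 4L)
    }
  }
})

test_that("strand sequences concatenate their domain sequences 5'->3'", {
  gate <- paper_gate("OR")
  a <- assign_sequences(gate, seed = 2)
  efh <- gate$inputs[[1]]
  expect_identical(strand_sequence(efh, a),
                   paste0(a[["e"]], a[["f"]], a[["h"]]))
  expect_error(strand_sequence(strand("q", "q"), a), "no sequence")
})

test_that("unsatisfiable constraints fail naming the domain", {
  # GC fraction in [0.60, 0.65] admits no integer GC count at 6 nt
  expect_error(assign_sequences(paper_gate("OR"), seed = 1,
                                gc_range = c(0.60, 0.65), max_tries = 50),
               "domain 'E'")
})

test_that("the orthogonality screen flags planted cross-talk", {
  planted <- c(E = "ACGTAGGCTA", e = dsdgates:::revcomp("ACGTAGGCTA"),
               G = dsdgates:::revcomp("TTACGTAGGC"),
               g = "TTACGTAGGC")
  rep <- validate_orthogonality(planted, k = 6)
  expect_gt(nrow(rep), 0L)
  expect_true(any(rep$domain_a == "E" & rep$domain_b == "G"))

  single <- c(X = "ACGTACGTAA", x = dsdgates:::revcomp("ACGTACGTAA"))
  expect_identical(nrow(validate_orthogonality(single, k = 6)), 0L)

  expect_error(validate_orthogonality(planted, k = 3), "k must be")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_orthogonality_report(rep, path)
  expect_identical(names(utils::read.delim(path)),
                   c("domain_a", "domain_b", "shared_word"))
})

test_that("generated assignments pass the k = 6 screen across seeds", {
  gate <- paper_gate("MAJORITY")
  clean <- vapply(1:100, function(s)
    nrow(validate_orthogonality(assign_sequences(gate, seed = s),
                                k = 6)) == 0L, NA)
  expect_gte(mean(clean), 0.9)
})

test_that("FASTA export and import round-trip an assignment", {
  gate <- paper_gate("OR")
  a <- assign_sequences(gate, seed = 8)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_gate_fasta(gate, a, path)

  recs <- Biostrings::readDNAStringSet(path)
  expect_identical(length(recs), 5L) # EFHG, fh, efh, fhg, efhg
  expect_setequal(names(recs), c("EFHG", "fh", "efh", "fhg", "efhg"))

  b <- read_gate_fasta(gate, path)
  nm <- sort(names(a))
  expect_identical(as.character(b[nm]), as.character(a[nm]))
})

test_that("FASTA defects are caught and named", {
  gate <- paper_gate("OR")
  a <- assign_sequences(gate, seed = 8)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_gate_fasta(gate, a, path)

  mutate_record <- function(lines, name, fun) {
    i <- grep(paste0("^>", name, "$"), lines) + 1L
    lines[i] <- fun(lines[i])
    lines
  }
  lines <- readLines(path)

  point_mutation <- function(x) {
    first <- substring(x, 1, 1)
    sub <- setdiff(c("A", "C", "G", "T"), first)[1]
    paste0(sub, substring(x, 2))
  }
  # mutating the template breaks complementarity with the lower-case set
  bad <- mutate_record(lines, "EFHG", point_mutation)
  p1 <- withr::local_tempfile(lines = bad, fileext = ".fasta")
  expect_error(read_gate_fasta(gate, p1), "reverse complements")
  # mutating the incumbent contradicts the same domain in efh/fhg/efhg
  bad <- mutate_record(lines, "fh", point_mutation)
  p1b <- withr::local_tempfile(lines = bad, fileext = ".fasta")
  expect_error(read_gate_fasta(gate, p1b), "conflicting")

  bad <- mutate_record(lines, "efh", function(x)
    paste0("N", substring(x, 2)))
  p2 <- withr::local_tempfile(lines = bad, fileext = ".fasta")
  expect_error(read_gate_fasta(gate, p2), "efh")

  bad <- mutate_record(lines, "fhg", function(x) substring(x, 2))
  p3 <- withr::local_tempfile(lines = bad, fileext = ".fasta")
  expect_error(read_gate_fasta(gate, p3), "length")

  p4 <- withr::local_tempfile(lines = lines[-(1:2)], fileext = ".fasta")
  expect_error(read_gate_fasta(gate, p4), "missing")
})

test_that("fixture kinds reproduce their archetype structures", {
  for (n in 4:6) {
    blunt <- generate_fixture("AND-like", n, seed = n)
    expect_identical(exposed_toeholds(blunt), integer(0))
    expect_identical(blunt$footprint, c(1L, as.integer(n)))
    expect_identical(logic_bits(blunt), c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L))

    or_like <- generate_fixture("OR-like", n, seed = n)
    expect_identical(logic_bits(or_like), c(0L, rep(1L, 7)))

    maj_like <- generate_fixture("MAJORITY-like", n, seed = n)
    expect_identical(logic_bits(maj_like),
                     c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))
  }
})

test_that("fixture generation is deterministic and always validates", {
  a <- generate_fixture("random-valid", 7, seed = 123)
  b <- generate_fixture("random-valid", 7, seed = 123)
  expect_identical(a, b)
  for (s in 1:20) {
    g <- generate_fixture("random-valid", sample(2:8, 1), seed = s)
    expect_s3_class(g, "dsd_gate") # construction runs full validation
    for (inp in g$inputs)
      expect_identical(length(strand_run(inp, g)), 2L)
  }
  expect_error(generate_fixture("AND-like", 3, seed = 1), "at least 4")
  expect_error(generate_fixture("random-valid", 9, seed = 1), "2..8")
})
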