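test_that("exposed toeholds are the positions outside the footprint", {
  expect_identical(exposed_toeholds(paper_gate("OR")), c(1L, 4L))
  expect_identical(exposed_toeholds(paper_gate("AND")), integer(0))
  blunt <- generate_fixture("AND-like", 6, seed = 1)
  expect_identical(exposed_toeholds(blunt), integer(0))
})

test_that("anchor sites follow the strong-toehold / terminal-fray rules", {
  maj <- paper_gate("MAJORITY")
  # fh alone cannot anchor anywhere: interior run, fully paired
  expect_identical(nrow(anchor_sites(maj$inputs[[3]], maj)), 0L)

  and <- paper_gate("AND")
  ab <- anchor_sites(and$inputs[[1]], and)
  expect_identical(ab$position, 1L)
  expect_identical(ab$kind, "weak_fray")
  bc <- anchor_sites(and$inputs[[3]], and)
  expect_identical(nrow(bc), 0L)

  or <- paper_gate("OR")
  efh <- anchor_sites(or$inputs[[1]], or)
  expect_identical(efh$position, 1L)
  expect_identical(efh$kind, "strong_toehold")
})

test_that("chains extend to the documented fixpoints", {
  and <- paper_gate("AND")
  all3 <- extend_chains(and, 1:3)
  expect_length(all3$chains, 1L) # both fray ends seed the same chain
  expect_identical(all3$chains[[1]]$coverage, c(1L, 4L))
  expect_setequal(all3$chains[[1]]$members, c("ab", "cd", "bc"))

  two <- extend_chains(and, c(1L, 2L)) # ab + cd, no bridging bc
  expect_length(two$chains, 2L)
  expect_identical(lapply(two$chains, `[[`, "coverage"),
                   list(c(1L, 2L), c(3L, 4L)))
  expect_identical(unique(vapply(two$chains, `[[`, "", "anchor_kind")),
                   "weak_fray")

  maj <- paper_gate("MAJORITY")
  joined <- extend_chains(maj, c("ef", "fh"))
  expect_length(joined$chains, 1L)
  expect_identical(joined$chains[[1]]$anchor_kind, "strong_toehold")
  expect_identical(joined$chains[[1]]$coverage, c(1L, 3L))
  expect_setequal(joined$chains[[1]]$members, c("ef", "fh"))

  expect_length(extend_chains(maj, integer(0))$chains, 0L)
})

test_that("release needs one covering chain or a strong-chain union", {
  maj <- paper_gate("MAJORITY")
  two_strong <- extend_chains(maj, c("ef", "hg"))
  expect_length(two_strong$chains, 2L)
  expect_identical(release_decision(maj, two_strong), 1L)

  and <- paper_gate("AND")
  # two disconnected weak chains jointly cover the footprint but do not open it
  expect_identical(release_decision(and, extend_chains(and, c(1L, 2L))), 0L)
  expect_identical(release_decision(and, extend_chains(and, integer(0))), 0L)
  expect_identical(release_decision(and, extend_chains(and, 1:3)), 1L)
})

test_that("gate outputs equal the intended Boolean functions on all states", {
  st <- all_states()
  or_bits <- logic_bits(paper_gate("OR"))
  and_bits <- logic_bits(paper_gate("AND"))
  maj_bits <- logic_bits(paper_gate("MAJORITY"))
  for (r in seq_len(nrow(st))) {
    x <- st[r, ]
    expect_identical(or_bits[r], as.integer(any(x == 1)))
    expect_identical(and_bits[r], as.integer(all(x == 1)))
    expect_identical(maj_bits[r], as.integer(sum(x) >= 2))
  }
})

test_that("chain growth is order-independent and deterministic", {
  gates <- c(lapply(c("OR", "AND", "MAJORITY"), paper_gate),
             lapply(1:5, function(i)
               generate_fixture("random-valid", 6, seed = i)))
  for (gate in gates) {
    for (subset in input_subsets()) {
      ref <- extend_chains(gate, subset)
      expect_identical(extend_chains(gate, rev(subset)), ref)
      if (length(subset) > 1L)
        expect_identical(extend_chains(gate, sample(subset)), ref)
      expect_identical(extend_chains(gate, subset), ref)
    }
  }
})

test_that("input states parse from all three accepted notations", {
  expect_identical(parse_state("101"), c(1L, 0L, 1L))
  expect_identical(parse_state("(1 0 1)"), c(1L, 0L, 1L))
  expect_identical(parse_state(c(1, 0, 1)), c(1L, 0L, 1L))
  expect_identical(format_state("110"), "(1 1 0)")
  expect_error(parse_state("10"), "three bits")
  expect_error(parse_state("abc"), "three bits")
  expect_error(parse_state(c(1, 2, 0)), "three bits")
  expect_error(evaluate_gate(paper_gate("OR"), "10101"), "three bits")
})

test_that("truth tables and their CSV form round-trip", {
  tt <- truth_table(paper_gate("MAJORITY"))
  expect_s3_class(tt, "dsd_truth_table")
  expect_identical(nrow(tt), 8L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_truth_table(tt, path)
  back <- read_truth_table(path)
  expect_identical(as.data.frame(back), as.data.frame(tt))
  expect_error(read_truth_table(withr::local_tempfile(lines = "x,y\n1,2")),
               "truth-table")
})
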