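test_that("rate parameters are validated", {
  expect_error(rate_parameters(k_strong = -1), "non-negative")
  expect_error(rate_parameters(k_fray = 2, k_strong = 1), "k_fray")
  r <- rate_parameters()
  expect_true(r$k_fray < r$k_strong)
})

test_that("compiled networks mirror the logical moves", {
  and0 <- compile_reactions(paper_gate("AND"), "000")
  expect_length(and0$reactions, 0L)

  or1 <- compile_reactions(paper_gate("OR"), "100")
  kinds <- vapply(or1$reactions, `[[`, "", "kind")
  expect_true("strong_anchor" %in% kinds)
  expect_true("release" %in% kinds)

  and7 <- compile_reactions(paper_gate("AND"), "111")
  kinds <- vapply(and7$reactions, `[[`, "", "kind")
  expect_true("fray_anchor" %in% kinds)
  expect_true("join" %in% kinds)
  expect_error(compile_reactions(paper_gate("AND"), "111", copies = 0),
               "copies")
})

test_that("every reaction in every compiled network conserves strands", {
  st <- all_states()
  for (g in c("OR", "AND", "MAJORITY")) {
    gate <- paper_gate(g)
    for (r in seq_len(nrow(st)))
      expect_true(check_conservation(
        compile_reactions(gate, st[r, ])))
  }
  # and along simulated trajectories
  net <- compile_reactions(paper_gate("MAJORITY"), "110")
  traj <- simulate_network(net, t_end = 200, seed = 3)
  totals <- traj$counts %*% t(net$content)
  for (s in rownames(net$content))
    expect_true(all(totals[, s] == totals[1, s]), info = s)
})

test_that("simulation is reproducible and leaves the caller's RNG alone", {
  net <- compile_reactions(paper_gate("OR"), "111")
  a <- simulate_network(net, t_end = 100, seed = 42)
  set.seed(1); marker <- runif(1); set.seed(1)
  b <- simulate_network(net, t_end = 100, seed = 42)
  expect_identical(a$counts, b$counts)
  expect_identical(a$times, b$times)
  expect_identical(runif(1), marker)
  c <- simulate_network(net, t_end = 100, seed = 43)
  expect_false(identical(a$times, c$times))
})

test_that("a network with no enabled reactions stays constant", {
  net <- compile_reactions(paper_gate("AND"), "000")
  traj <- simulate_network(net, t_end = 50, seed = 1)
  expect_identical(nrow(traj$counts), 1L)
  expect_identical(unname(traj$final), as.numeric(net$init))
  expect_identical(readout(traj)$signal_au, 0)
})

test_that("readout arithmetic follows the boundary rule", {
  fake_traj <- function(free, bound) {
    net <- compile_reactions(paper_gate("OR"), "100")
    final <- stats::setNames(numeric(length(net$species)), net$species)
    final[["free_reporter"]] <- free
    final[[grep("^cplx\\{empty\\|rep\\}$", net$species, value = TRUE)]] <- bound
    structure(list(final = final, network = net, times = 0,
                   counts = matrix(final, nrow = 1), t_final = 0,
                   n_events = 0, seed = 1), class = "dsd_trajectory")
  }
  expect_identical(readout(fake_traj(0, 100))$bit, 0L)
  r <- readout(fake_traj(100, 0), F_max = 150, boundary = 50)
  expect_equal(r$signal_au, 150)
  expect_identical(r$bit, 1L)
  r <- readout(fake_traj(50, 50), F_max = 150, boundary = 50)
  expect_equal(r$signal_au, 75)
  expect_identical(r$bit, 1L)
  # exactly on the boundary: bit 0, with a warning
  expect_warning(r <- readout(fake_traj(50, 100), F_max = 150,
                              boundary = 50), "boundary")
  expect_identical(r$bit, 0L)
  expect_error(readout(fake_traj(1, 1), F_max = 10, boundary = 20),
               "F_max > boundary")
})

test_that("the OR gate under full input releases nearly everything", {
  net <- compile_reactions(paper_gate("OR"), "111")
  ff <- vapply(1:100, function(s)
    readout(simulate_network(net, seed = s, record = FALSE))$free_fraction,
    0)
  expect_gte(stats::median(ff), 0.9)
})

test_that("binarized outputs are invariant under doubling the copies", {
  for (g in c("AND", "MAJORITY")) {
    gate <- paper_gate(g)
    ref <- logic_bits(gate)
    for (copies in c(50L, 100L)) {
      tt <- kinetic_truth_table(gate, copies = copies, seeds = 1:3)
      expect_identical(tt$output, ref, info = paste(g, copies))
    }
  }
})

test_that("the zero-input baseline signal is exactly zero", {
  for (g in c("OR", "AND", "MAJORITY")) {
    tt <- kinetic_truth_table(paper_gate(g), seeds = 1:2)
    expect_identical(tt$signal[1], 0)
  }
})

test_that("trajectories export as long-format TSV", {
  net <- compile_reactions(paper_gate("OR"), "100", copies = 5L)
  traj <- simulate_network(net, t_end = 50, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(traj, path)
  tab <- utils::read.delim(path)
  expect_identical(names(tab), c("time", "species", "count"))
  expect_identical(nrow(tab), nrow(traj$counts) * ncol(traj$counts))
})
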