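test_that("bit utilities match a per-bit scan oracle", {
  expect_identical(occupied_orbitals(strtoi("1010", base = 2)), c(2L, 4L))
  expect_identical(occupied_orbitals(0L), integer(0))
  set.seed(1)
  for (rep in 1:20) {
    bits <- sum(bitwShiftL(1L, sample(0:11, sample(0:6, 1))))
    scan <- which(bitwAnd(bitwShiftR(bits, 0:11), 1L) == 1L)
    expect_identical(occupied_orbitals(bits), as.integer(scan))
    expect_identical(popcount(bits), length(scan))
  }
})

test_that("excitation_degree matches a set-difference oracle exhaustively", {
  # all determinant pairs of (M = 4, 1 alpha, 1 beta)
  dets <- all_determinants(4, 1, 1)
  for (d1 in dets) for (d2 in dets) {
    o <- length(setdiff(occupied_orbitals(d1$alpha),
                        occupied_orbitals(d2$alpha))) +
      length(setdiff(occupied_orbitals(d1$beta),
                     occupied_orbitals(d2$beta)))
    expect_identical(excitation_degree(d1, d2), as.integer(o))
  }
  expect_error(excitation_degree(sdet(1L, 1L), sdet(3L, 1L)),
               "electron counts")
})

test_that("excitation_info signs match hand cases", {
  # alpha 0011 -> 0101: hole 1 -> particle 3 with orbital 2 unoccupied
  i1 <- excitation_info(sdet(3L, 0L), sdet(5L, 0L))
  expect_identical(i1$sign, 1L)
  expect_identical(i1$holes_a, 2L)      # 0011 vs 0101 differ in orbs 2,3
  # alpha 0111 -> 1101: hole 2, particle 4, orbital 3 crossed -> -1
  i2 <- excitation_info(sdet(7L, 0L), sdet(13L, 0L))
  expect_identical(i2$sign, -1L)
})

test_that("excitation signs agree with the permutation-parity oracle", {
  # all ordered pairs at degree <= 2 within (M = 5, 2 alpha, 2 beta)
  dets <- all_determinants(5, 2, 2)
  set.seed(3)
  pick <- sample(length(dets), 28)
  for (i in pick) for (j in pick) {
    d1 <- dets[[i]]; d2 <- dets[[j]]
    deg <- excitation_degree(d1, d2)
    if (deg == 0L || deg > 2L) next
    info <- excitation_info(d1, d2)
    # oracle: parity of aligning explicit spin-orbital operator lists
    expect_identical(info$sign, cirdm:::pair_sign_generic(d2, d1),
                     info = sprintf("pair %d %d", i, j))
    # hermiticity: sign(d1,d2) * sign(d2,d1) = +1
    expect_identical(info$sign * excitation_info(d2, d1)$sign, 1L)
  }
})

orb_mask_test <- function(orbs) sum(bitwShiftL(1L, as.integer(orbs) - 1L))

test_that("string_irrep is the XOR product, checked against D2h table", {
  orbsym <- c(0L, 5L, 6L, 3L, 7L)
  expect_identical(string_irrep(0L, orbsym), 0L)
  expect_identical(string_irrep(2L, orbsym), 5L)
  # D2h product table via explicit label multiplication:
  # (g/u parity XOR) x (C2v-like axis label product)
  d2h_mult <- function(a, b) bitwXor(a, b)  # encoding is XOR-faithful
  set.seed(4)
  for (rep in 1:20) {
    occ <- sample(1:5, sample(1:5, 1))
    expected <- Reduce(d2h_mult, orbsym[occ], 0L)
    expect_identical(string_irrep(orb_mask_test(occ), orbsym), expected)
  }
})

test_that("hamiltonian_element implements the Slater-Condon rules", {
  ints <- convert_notation(
    make_fixture("random-hermitian", seed = 3, M = 4, n_elec = 2),
    "physicists")
  # degree-3 pair is exactly zero
  d1 <- sdet(c(1, 2), c(1), from_orbitals = TRUE)
  d2 <- sdet(c(3, 4), c(2), from_orbitals = TRUE)
  expect_identical(hamiltonian_element(d1, d2, ints), 0)
  # closed-shell 2-electron determinant: 2 h_11 + <11|11> + e_core
  d <- sdet(1L, 1L)
  expect_equal(hamiltonian_element(d, d, ints),
               2 * ints$h[1, 1] + ints$eri[1, 1, 1, 1] + ints$e_core)
  expect_error(hamiltonian_element(d, d, convert_notation(ints, "chemists")),
               "physicists")
})

test_that("dense Hamiltonian equals operator-algebra and external oracles", {
  ints <- make_fixture("random-hermitian", seed = 7, M = 4, n_elec = 3)
  for (nab in list(c(1, 1), c(2, 1))) {
    dets <- all_determinants(4, nab[1], nab[2])
    H1 <- dense_hamiltonian(dets, ints)
    H2 <- oracle_hamiltonian(dets, ints)
    expect_lt(max(abs(H1 - H2)), 1e-12)
    expect_lt(max(abs(H1 - t(H1))), 1e-12)
  }
})

test_that("package FCI matches an independent established FCI program", {
  # reference energies computed with pyscf.fci.direct_spin1 on the
  # bundled FCIDUMP fixtures (2 roots each)
  i1 <- read_fcidump(system.file("extdata", "toy_m4_n4.fcidump",
                                 package = "cirdm", mustWork = TRUE))
  r1 <- fci_solve(i1, n_roots = 2)
  expect_lt(abs(r1$energies[1] - (-3.528980109825)), 1e-9)
  expect_lt(abs(r1$energies[2] - (-2.338405219543)), 1e-9)
  i2 <- read_fcidump(system.file("extdata", "toy_m5_n4_ms2.fcidump",
                                 package = "cirdm", mustWork = TRUE))
  r2 <- fci_solve(i2, n_roots = 2)   # Ms = 1 (3 alpha, 1 beta)
  expect_lt(abs(r2$energies[1] - (-3.924293837233)), 1e-9)
  expect_lt(abs(r2$energies[2] - (-3.446667031860)), 1e-9)
})

test_that("enumerate_substitutions yields each substitution exactly once", {
  # (M = 2, 1a 1b) closed shell: 1 alpha single + 1 beta single + 1 mixed
  d <- sdet(1L, 1L)
  subs <- enumerate_substitutions(d, 2L, 2L)
  expect_length(subs, 3L)
  keys <- vapply(subs, function(s) paste(s$alpha, s$beta), character(1))
  expect_identical(anyDuplicated(keys), 0L)
  degs <- vapply(subs, excitation_degree, integer(1), d1 = d)
  expect_true(all(degs %in% 1:2))
  # mixed-spin doubles count Na(M-Na) Nb(M-Nb) for (6, 2, 2) = 64
  d6 <- sdet(c(1, 2), c(1, 2), from_orbitals = TRUE)
  subs6 <- enumerate_substitutions(d6, 2L, 6L)
  mixed <- sum(vapply(subs6, function(s)
    popcount(bitwXor(s$alpha, d6$alpha)) == 2L &&
      popcount(bitwXor(s$beta, d6$beta)) == 2L, logical(1)))
  expect_identical(mixed, 2L * 4L * 2L * 4L)
  # grand total: singles + same-spin doubles + mixed doubles
  expect_length(subs6, 2 * (2 * 4) + 2 * (1 * choose(4, 2)) + 64)
})
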