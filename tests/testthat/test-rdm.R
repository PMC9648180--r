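# The elementary update rules and all four construction strategies are
# certified against the brute-force second-quantization oracle of
# helper-oracle.R on spaces of <= 8 spin orbitals.

test_that("single-determinant 2-RDMs match operator algebra", {
  # closed-shell 2 electrons in orbital 1: Gamma_1111 = 2, all else 0
  w <- wfn_sd(1L, 1L, 1, 2L)
  G <- rdm2_naive(w, 2L)
  expect_equal(G$gamma[1, 1, 1, 1], 2)
  expect_equal(sum(abs(G$gamma)), 2)
  # open-shell |phi1a phi2a>: full table equals the brute-force oracle
  w2 <- wfn_sd(orb_mask(c(1, 2)), 0L, 1, 2L)
  G2 <- rdm2_naive(w2, 2L)
  Go <- oracle_rdm2(w2)
  expect_lt(max(abs(G2$gamma - Go)), 1e-12)
  expect_equal(G2$gamma[1, 2, 2, 1], 1)
  expect_equal(G2$gamma[1, 2, 1, 2], -1)
})

test_that("elementary updates follow the delta-gated four-case pattern", {
  M <- 4
  # mixed-spin double: exactly 2 of 4 cases fire
  di <- sdet(c(2), c(3), from_orbitals = TRUE)
  dj <- sdet(c(1), c(1), from_orbitals = TRUE)
  info <- cirdm:::pair_diff_info(di, dj)
  ctr <- cirdm:::contrib_two_diff(info)
  expect_identical(nrow(ctr), 2L)
  # same-spin double: all 4 cases fire with alternating signs
  di2 <- sdet(c(3, 4), c(1), from_orbitals = TRUE)
  dj2 <- sdet(c(1, 2), c(1), from_orbitals = TRUE)
  ctr2 <- cirdm:::contrib_two_diff(cirdm:::pair_diff_info(di2, dj2))
  expect_identical(nrow(ctr2), 4L)
  expect_setequal(ctr2[, 5] / ctr2[1, 5], c(1, 1, -1, -1))
  # updates against the oracle on a 2-determinant wavefunction
  w <- wfn_sd(c(di$alpha, dj$alpha), c(di$beta, dj$beta),
              c(0.8, 0.6), M)
  expect_lt(max(abs(rdm2_naive(w, 2L)$gamma - oracle_rdm2(w))), 1e-12)
})

test_that("degree-1 updates and spectator gating match the oracle", {
  # pair differing by one beta spin orbital, with alpha + beta spectators
  di <- sdet(c(1, 2), c(3), from_orbitals = TRUE)
  dj <- sdet(c(1, 2), c(1), from_orbitals = TRUE)
  w <- wfn_sd(c(di$alpha, dj$alpha), c(di$beta, dj$beta), c(0.6, -0.8), 3L)
  expect_lt(max(abs(rdm2_naive(w, 2L)$gamma - oracle_rdm2(w))), 1e-12)
  # spin-mismatched pairing contributes exactly zero: the only surviving
  # one-difference cases involve same-spin exchange gates
  info <- cirdm:::pair_diff_info(di, dj)
  ctr <- cirdm:::contrib_one_diff(info, c(1L, 2L), c(1L, 1L))
  # alpha spectators with a beta difference: Coulomb cases only (2 each)
  expect_identical(nrow(ctr), 4L)
})

test_that("diagonal update reproduces closed-shell pair structure", {
  # doubly occupied orbitals 1, 2: Gamma_1221 = 4 c^2, Gamma_1212 = -2 c^2
  d <- sdet(c(1, 2), c(1, 2), from_orbitals = TRUE)
  G <- array(0, rep(3, 4))
  G <- rdm2_update_no_diff(G, 0.25, d)
  expect_equal(G[1, 2, 2, 1], 4 * 0.25)
  expect_equal(G[1, 2, 1, 2], -2 * 0.25)
  # one electron: no pair terms at all
  G1 <- rdm2_update_no_diff(array(0, rep(3, 4)), 1, sdet(1L, 0L))
  expect_true(all(G1 == 0))
  # trace conservation for a normalized single determinant
  w <- wfn_sd(d$alpha, d$beta, 1, 3L)
  expect_equal(rdm2_trace(rdm2_naive(w, 2L)), 4 * 3)
})

test_that("all strategies and the oracle agree on random wavefunctions", {
  # (M, na, nb) cases keep the oracle within <= 8 spin orbitals
  cases <- list(c(4, 2, 1, 8), c(4, 2, 2, 10), c(3, 2, 2, 9))
  for (cs in cases) {
    w <- random_wfn(cs[1], cs[2], cs[3], n_det = cs[4], seed = cs[1] + cs[4])
    G2 <- rdm2_naive(w, 2L)$gamma
    expect_lt(max(abs(rdm2_naive(w, 1L)$gamma - G2)), 1e-12)
    expect_lt(max(abs(rdm2_naive(w, 3L)$gamma - G2)), 1e-12)
    expect_lt(max(abs(rdm2_from_sd_list(w)$gamma - G2)), 1e-12)
    expect_lt(max(abs(oracle_rdm2(w) - G2)), 1e-12)
    # permutational symmetries Gamma_prsq = Gamma_rpqs = Gamma_qspr
    expect_lt(max(abs(G2 - aperm(G2, c(2, 1, 4, 3)))), 1e-12)
    expect_lt(max(abs(G2 - aperm(G2, c(4, 3, 2, 1)))), 1e-12)
    # trace and positivity of pair occupancies
    ne <- sum(c(cs[2], cs[3]))
    expect_lt(abs(rdm2_trace(rdm2(G2, ne)) - ne * (ne - 1)), 1e-9)
    for (p in 1:cs[1]) for (r in 1:cs[1])
      expect_gte(G2[p, r, r, p], -1e-12)
  }
})

test_that("energy via Eq-5 contraction equals the expectation value", {
  ints <- make_fixture("random-hermitian", seed = 31, M = 4, n_elec = 3)
  w <- random_wfn(4, 2, 1, n_det = 10, seed = 6)
  G <- rdm2_naive(w, 2L)
  g1 <- rdm1_from_rdm2(G)
  e <- energy_from_rdms(ints, g1, G)
  Hd <- dense_hamiltonian(all_determinants(4, 2, 1), ints)
  keys_all <- vapply(all_determinants(4, 2, 1), function(d)
    paste(d$alpha, d$beta), character(1))
  v <- numeric(length(keys_all))
  v[match(paste(w$alpha, w$beta), keys_all)] <- w$coef
  expect_lt(abs(e - as.numeric(t(v) %*% Hd %*% v)), 1e-10)
})

test_that("rdm2_from_fci equals the naive build and the eigenvalue", {
  ints <- make_fixture("random-hermitian", seed = 7, M = 4, n_elec = 4)
  res <- fci_solve(ints)
  st <- res$states[[1]]
  G <- rdm2_from_fci(st)
  w <- civector_to_wfn(st)
  expect_lt(max(abs(G$gamma - rdm2_naive(w, 2L)$gamma)), 1e-10)
  e <- energy_from_rdms(ints, rdm1_from_rdm2(G), G)
  expect_lt(abs(e - res$energies[1]), 1e-9)
})

test_that("rdm2_from_fci pair visits scale as N_SD M^2", {
  # fixed electron counts (1 alpha, 1 beta) over growing M; the mixed
  # double substitutions Na(M-Na) Nb(M-Nb) dominate the visit count
  Ms <- c(8, 12, 16, 20)
  visits <- vapply(Ms, function(M) {
    sa <- enumerate_strings(M, 1, tables = TRUE)
    C <- matrix(0, sa$nstr, sa$nstr)
    C[1, 1] <- 1
    st <- civector(C, sa, sa)
    attr(rdm2_from_fci(st), "pair_visits") / sa$nstr^2
  }, numeric(1))
  # log-log slope of visits / N_SD against M
  fit <- stats::lm(log(visits) ~ log(Ms))
  expect_lt(abs(coef(fit)[2] - 2), 0.2)
})

test_that("rdm2_from_sd_list requires sorted input, search finds subsets", {
  w <- random_wfn(4, 2, 2, n_det = 12, seed = 9)
  wu <- w[rev(seq_len(nrow(w))), ]
  attr(wu, "M") <- 4L
  class(wu) <- c("wfn_sd", "data.frame")
  expect_error(rdm2_from_sd_list(wu), "sort")
  # a determinant whose substitutions all fall outside the list only
  # contributes through its diagonal term
  lone <- wfn_sd(orb_mask(c(1, 2)), orb_mask(c(1, 2)), 1, 6L)
  Gl <- rdm2_from_sd_list(lone)
  expect_lt(max(abs(Gl$gamma - rdm2_naive(lone, 2L)$gamma)), 1e-12)
})

test_that("rdm1 routes agree: direct, contraction, oracle", {
  for (seed in c(2, 5)) {
    w <- random_wfn(4, 2, 2, n_det = 9, seed = seed)
    g_direct <- rdm1_direct(w)
    g_contr <- rdm1_from_rdm2(rdm2_naive(w, 2L))
    go <- oracle_rdm1(w)
    expect_lt(max(abs(g_direct$gamma - go)), 1e-12)
    expect_lt(max(abs(g_contr$gamma - go)), 1e-10)
    expect_lt(max(abs(g_direct$gamma - t(g_direct$gamma))), 1e-12)
    expect_lt(abs(sum(diag(g_direct$gamma)) - 4), 1e-9)
    ev <- eigen(g_direct$gamma, symmetric = TRUE)$values
    expect_true(all(ev > -1e-9 & ev < 2 + 1e-9))
  }
  # closed-shell single determinant: gamma = diag(2, 2, 0, 0)
  w0 <- wfn_sd(orb_mask(c(1, 2)), orb_mask(c(1, 2)), 1, 4L)
  expect_equal(rdm1_from_rdm2(rdm2_naive(w0, 2L))$gamma,
               diag(c(2, 2, 0, 0)))
  expect_error(rdm1_from_rdm2(rdm2(array(0, rep(2, 4)), 1)), "N_e >= 2")
})

test_that("energy_from_rdms trivial identities hold", {
  # zero integrals: energy is e_core
  z <- sfints(matrix(0, 3, 3), array(0, rep(3, 4)), e_core = 2.5,
              n_elec = 2)
  w <- random_wfn(3, 1, 1, seed = 3)
  G <- rdm2_naive(w, 2L)
  expect_equal(energy_from_rdms(z, rdm1_from_rdm2(G), G), 2.5)
  # convention tag is enforced
  Gbad <- G; Gbad$convention <- "half-absorbed"
  expect_error(energy_from_rdms(z, rdm1_from_rdm2(G), Gbad), "convention")
})

test_that("sparse text dump round-trips a 2-RDM", {
  w <- random_wfn(3, 2, 1, seed = 8)
  G <- rdm2_naive(w, 2L)
  path <- withr::local_tempfile(fileext = ".txt")
  write_rdm2_sparse(G, path)
  back <- read_rdm2_sparse(path)
  expect_lt(max(abs(G$gamma - back$gamma)), 1e-12)
  expect_identical(back$n_elec, G$n_elec)
})
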