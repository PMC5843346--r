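# Protonation arithmetic, pKa ingestion, partial charges and the macrodipole

test_that("builtin pKa table covers side chains and termini", {
  st <- make_ionizable_protein(c("GLU", "LYS"), seed = 1)
  pka <- load_pka(st)
  expect_equal(nrow(pka), 4)  # Glu, Lys, N-term, C-term
  expect_setequal(pka$resname, c("GLU", "LYS", "NT", "CT"))
  expect_equal(pka$pka[pka$resname == "GLU"], 4.25)
})

test_that("pKa files are ingested with intrinsic fallback and validation", {
  st <- make_ionizable_protein(c("HIS", "ASP", "GLY"), seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  make_pka_file(data.frame(chain = "A", resseq = 1, resname = "HIS",
                           pka = 6.9, type = "base"), f)
  expect_warning(pka <- load_pka(st, f), "missing from pKa file")
  expect_equal(pka$pka[pka$resname == "HIS"], 6.9)
  expect_equal(pka$pka[pka$resname == "ASP"], 3.65)  # fallback
  make_pka_file(data.frame(chain = "A", resseq = 1, resname = "HIS",
                           pka = 15, type = "base"), f)
  expect_error(load_pka(st, f), "\\[0, 14\\]")
  make_pka_file(data.frame(chain = "A", resseq = 99, resname = "HIS",
                           pka = 6.5, type = "base"), f)
  expect_error(load_pka(st, f), "absent from the structure")
})

test_that("protonation follows Henderson-Hasselbalch in both modes", {
  st <- make_ionizable_protein(c("HIS"), seed = 3)
  pka <- load_pka(st)
  his <- pka$resname == "HIS"
  expect_false(protonation_states(pka, 6.8, "discrete")$protonated[his])
  expect_equal(protonation_states(pka, 6.0, "fractional")$protonated[his], 0.5)
  expect_true(protonation_states(pka, 6.0, "discrete")$protonated[his])  # tie
  expect_error(protonation_states(pka, 15, "discrete"), "pH")
})

test_that("a free backbone with both termini is neutral at pH 7", {
  st <- make_ionizable_protein("GLY", seed = 4)
  pka <- load_pka(st)
  expect_equal(net_charge(protonation_states(pka, 7, "discrete")), 0)
})

test_that("the L-BABP-like inventory flips exactly five sites from pH 6.8 to 5", {
  fx <- lbabp_like_fixture()
  p68 <- protonation_states(fx$pka, 6.8, "discrete")
  p50 <- protonation_states(fx$pka, 5.0, "discrete")
  expect_equal(net_charge(p68), 2)
  expect_equal(net_charge(p50), 7)
  changed <- which(p68$protonated != p50$protonated)
  expect_setequal(paste0(p68$resname[changed], p68$resseq[changed]),
                  fx$truth$flips)
})

test_that("isoelectric point bisection matches symmetry and grid-scan oracles", {
  tab <- function(pka, type) {
    d <- data.frame(chain = "A", resseq = seq_along(pka),
                    resname = ifelse(type == "acid", "ASP", "LYS"),
                    pka = pka, type = type)
    class(d) <- c("pka_table", "data.frame")
    d
  }
  expect_equal(isoelectric_point(tab(c(4, 10), c("acid", "base"))), 7,
               tolerance = 1e-3)
  # frozen from a 1e-5-step grid scan of the closed-form fractional charge
  expect_equal(isoelectric_point(tab(c(4, 5, 9), c("acid", "acid", "base"))),
               4.49997, tolerance = 1e-3)
  expect_error(isoelectric_point(tab(c(4, 5), c("acid", "acid"))),
               "acid and one base")
})

test_that("formal charges sit on canonical atoms and sum to the net charge", {
  fx <- lbabp_like_fixture()
  st <- fx$structure
  for (ph in c(3, 5, 6.8, 9, 12)) {
    prot <- protonation_states(fx$pka, ph, "discrete")
    cs <- assign_partial_charges(st, prot)
    expect_equal(cs$net_charge, net_charge(prot), tolerance = 1e-9)
  }
  prot <- protonation_states(fx$pka, 6.8, "discrete")
  cs <- assign_partial_charges(st, prot)
  glu_o <- select_atoms(st, resseq = 40, name = c("OE1", "OE2"))
  expect_equal(cs$per_atom_charge[glu_o], c(-0.5, -0.5))
  prot5 <- protonation_states(fx$pka, 5, "discrete")
  cs5 <- assign_partial_charges(st, prot5)
  his_n <- select_atoms(st, resseq = 83, name = c("ND1", "NE2"))
  expect_equal(sum(cs5$per_atom_charge[his_n]), 1)
})

test_that("fractional net charge decreases in pH and vanishes at the pI", {
  fx <- rep1_like_fixture()
  phs <- seq(1, 13, by = 0.5)
  z <- vapply(phs, function(p)
    net_charge(protonation_states(fx$pka, p, "fractional")), numeric(1))
  expect_true(all(diff(z) < 0))
  pI <- isoelectric_point(fx$pka)
  expect_lt(abs(net_charge(protonation_states(fx$pka, pI, "fractional"))), 1e-3)
})

test_that("discrete net charge saturates at the base/acid counts at extreme pH", {
  fx <- lbabp_like_fixture()
  n_base <- sum(fx$pka$type == "base")
  n_acid <- sum(fx$pka$type == "acid")
  expect_equal(net_charge(protonation_states(fx$pka, 0, "discrete")), n_base)
  expect_equal(net_charge(protonation_states(fx$pka, 14, "discrete")), -n_acid)
})

test_that("macrodipole matches the unit-separation value and a direct-sum oracle", {
  atoms <- data.frame(serial = 1:2, name = c("Q1", "Q2"), resname = "STE",
                      chain = "A", resseq = 1, x = 0, y = 0,
                      z = c(0.5, -0.5), element = "C", hetero = FALSE)
  st <- protein_structure(atoms, "dipole")
  cs <- charge_state_from_vector(st, c(1, -1))
  d <- macrodipole(cs, st)
  expect_equal(d$vector, c(0, 0, 4.80321), tolerance = 1e-9)
  expect_equal(d$magnitude, 4.80321, tolerance = 1e-9)

  set.seed(99)
  n <- 50
  xyz <- matrix(stats::rnorm(3 * n, sd = 8), ncol = 3)
  q <- stats::rnorm(n)
  at <- data.frame(serial = 1:n, name = "Q", resname = "STE", chain = "A",
                   resseq = 1, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   element = "C", hetero = FALSE)
  st2 <- protein_structure(at, "rand")
  cs2 <- charge_state_from_vector(st2, q)
  d2 <- macrodipole(cs2, st2, origin_rule = "com")
  # brute-force direct summation about the same origin
  r0 <- colMeans(xyz)  # equal masses -> COM is the centroid
  mu <- c(0, 0, 0)
  for (i in 1:n) mu <- mu + q[i] * (xyz[i, ] - r0)
  expect_equal(d2$vector, mu * 4.80321, tolerance = 1e-9)
})

test_that("neutral-set dipoles are translation invariant; charged sets obey the origin-shift identity", {
  pp <- make_point_protein(30, 200, 0, seed = 12)
  base <- macrodipole(pp$charge_state, pp$structure)
  set.seed(13)
  for (rep in 1:5) {
    shift <- stats::rnorm(3, sd = 30)
    st <- pp$structure
    st$atoms[, c("x", "y", "z")] <- sweep(coords(st), 2, -shift)
    d <- macrodipole(pp$charge_state, st)
    expect_equal(d$vector, base$vector, tolerance = 1e-9)
  }
  ppq <- make_point_protein(30, 200, 3, seed = 14)
  d0 <- macrodipole(ppq$charge_state, ppq$structure, origin_rule = "com")
  delta <- c(1.5, -2.25, 0.75)  # Angstrom
  d1 <- macrodipole(ppq$charge_state, ppq$structure,
                    origin_rule = d0$origin + delta)
  expect_equal(d1$vector, d0$vector - 3 * delta * 4.80321, tolerance = 1e-9)
})

test_that("dipole-axis angles cover parallel, antiparallel and oblique cases", {
  d <- list(vector = c(1, 1, 0), magnitude = sqrt(2))
  class(d) <- "dipole_result"
  expect_equal(dipole_axis_angle(d, c(1, 1, 0)), 0, tolerance = 1e-5)
  expect_equal(dipole_axis_angle(d, c(-1, -1, 0)), 180, tolerance = 1e-5)
  expect_equal(dipole_axis_angle(d, c(1, 0, 0)), 45)
  expect_error(dipole_axis_angle(d, c(0, 0, 0)), "zero vector")
})
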