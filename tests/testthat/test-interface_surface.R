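lone_atom <- function(x = 0, y = 0, z = 0, partner = "A", resno = 1L,
                      chain = partner) {
  data.frame(record = "ATOM", serial = 1L, name = "CB", alt = "",
             resname = "ALA", chain = chain, resno = resno, icode = "",
             x = x, y = y, z = z, occ = 1, element = "C",
             is_heavy = TRUE, partner = partner,
             reskey = paste0(chain, ":", resno),
             stringsAsFactors = FALSE)
}

test_that("an isolated atom's sampled area matches the analytic sphere within 1%", {
  analytic <- 4 * pi * (1.87 + 1.4)^2
  a960 <- atom_sasa(lone_atom(), sasa_quick(960))
  expect_lt(abs(a960 - analytic) / analytic, 0.01)
  # error shrinks as the lattice grows
  a240 <- atom_sasa(lone_atom(), sasa_quick(240))
  a3840 <- atom_sasa(lone_atom(), sasa_quick(3840))
  expect_lte(abs(a3840 - analytic), abs(a240 - analytic))
})

test_that("two-atom areas match the analytic two-sphere cap formula", {
  R <- 1.87 + 1.4
  for (d in c(1, 2, 3, 4, 6)) {
    at <- rbind(lone_atom(), lone_atom(x = d, resno = 2L))
    areas <- atom_sasa(at, sasa_quick(1920))
    expected <- if (d < 2 * R) two_sphere_each(R, d) else 4 * pi * R^2
    expect_equal(areas[1], expected, tolerance = 0.015)
    expect_equal(areas[2], expected, tolerance = 0.015)
  }
})

test_that("atoms beyond occlusion range keep their isolated areas", {
  at <- rbind(lone_atom(), lone_atom(x = 2 * (1.87 + 1.4) + 0.1,
                                     resno = 2L))
  areas <- atom_sasa(at, sasa_quick())
  expect_equal(areas, rep(4 * pi * (1.87 + 1.4)^2, 2), tolerance = 1e-9)
})

test_that("hydrogens neither contribute nor occlude", {
  at <- rbind(lone_atom(), lone_atom(x = 1.0, resno = 2L))
  at$element[2] <- "H"
  at$name[2] <- "HB"
  at$is_heavy[2] <- FALSE
  areas <- atom_sasa(at, sasa_quick())
  expect_equal(areas[2], 0)
  expect_equal(areas[1], atom_sasa(lone_atom(), sasa_quick()))
})

test_that("unknown atom types raise an error naming the atom", {
  at <- lone_atom()
  at$element <- "ZN"
  at$name <- "ZN"
  at$resname <- "ZN"
  expect_error(atom_sasa(at, sasa_quick()), "ZN",
               class = "mdc_error_unknown_atom")
})

test_that("interface area is symmetric, zero for distant partners, and positive at contact", {
  p <- tempfile(fileext = ".pdb")
  generate_toy_complex(4, 4, slots = cbind(c(1, 3), c(1, 3)), path = p)
  fr_ab <- read_multimodel_pdb(p, "A", "B")$frames[[1]]
  fr_ba <- read_multimodel_pdb(p, "B", "A")$frames[[1]]
  expect_equal(interface_area(fr_ab), interface_area(fr_ba))
  expect_gt(interface_area(fr_ab), 0)

  far <- generate_toy_complex(4, 4)      # no slots: partners 20 A apart
  expect_equal(interface_area(far), 0, tolerance = 1e-9)
})

test_that("per-residue burial sums to twice the interface area", {
  fr <- generate_toy_complex(5, 5, slots = cbind(c(2, 4), c(2, 4)),
                             atoms_per_residue = 3L)
  params <- sasa_quick()
  rep_ <- residue_burial(fr, params)
  expect_true(all(rep_$asa_complex <= rep_$asa_free + 1e-6))
  lost <- sum(rep_$asa_free - rep_$asa_complex)
  expect_equal(lost, 2 * interface_area(fr, params), tolerance = 1e-9)

  # residues remote from the interface are essentially unburied
  remote <- rep_[rep_$chain == "A" & !(rep_$resno %in% c(2, 4)), ]
  expect_true(all(remote$pct_buried < 1))
  expect_true(all(rep_$pct_buried >= -1e-6 & rep_$pct_buried <= 100,
                  na.rm = TRUE))
})

test_that("interface area is invariant under rigid-body motion within 0.5%", {
  # an irregular (jittered) interface: on a perfectly periodic lattice
  # the per-atom lattice-orientation artifact repeats coherently in
  # every slot instead of averaging out across atoms
  fr <- generate_toy_complex(24, 24,
                             slots = cbind(seq(1, 24, 2), seq(1, 24, 2)),
                             atoms_per_residue = 3L)
  set.seed(10)
  n <- nrow(fr$atoms)
  fr$atoms$x <- fr$atoms$x + runif(n, -0.4, 0.4)
  fr$atoms$y <- fr$atoms$y + runif(n, -0.4, 0.4)
  fr$atoms$z <- fr$atoms$z + runif(n, -0.4, 0.4)
  base <- interface_area(fr)
  for (rep in 1:3) {
    moved <- transform_frame(fr, shift = rnorm(3, sd = 10))
    expect_lt(abs(interface_area(moved) - base) / base, 0.005)
  }
})

test_that("area series tracks alternating geometries and degenerate N", {
  traj <- scripted_trajectory(cbind(2, 2),
                              schedule = matrix(c(TRUE, FALSE, TRUE,
                                                  FALSE), 4, 1),
                              n_res_a = 3, n_res_b = 3)
  params <- sasa_quick(240)
  ser <- area_series(traj, params)
  a_on <- interface_area(traj$frames[[1]], params)
  a_off <- interface_area(traj$frames[[2]], params)
  expect_equal(ser$per_frame_area, c(a_on, a_off, a_on, a_off))
  expect_equal(ser$mean, mean(c(a_on, a_off, a_on, a_off)))

  same <- area_series(scripted_trajectory(cbind(2, 2),
                                          schedule = matrix(TRUE, 3, 1),
                                          n_res_a = 3, n_res_b = 3),
                      params)
  expect_equal(same$sd, 0)
  expect_true(same$sd_defined)

  single <- area_series(scripted_trajectory(cbind(2, 2),
                                            schedule = matrix(TRUE, 1, 1),
                                            n_res_a = 3, n_res_b = 3),
                        params)
  expect_equal(single$sd, 0)
  expect_false(single$sd_defined)
})

test_that("area and burial writers emit the documented tables", {
  fr <- generate_toy_complex(3, 3, slots = cbind(2, 2))
  traj <- scripted_trajectory(cbind(2, 2), schedule = matrix(TRUE, 2, 1),
                              n_res_a = 3, n_res_b = 3)
  params <- sasa_quick(240)
  pa <- tempfile(fileext = ".tsv")
  write_area_tsv(area_series(traj, params, reference_area = 123.4), pa)
  lines <- readLines(pa)
  expect_equal(lines[1], "frame\tarea_A2")
  expect_true(any(grepl("^# reference\t123.40$", lines)))

  pb <- tempfile(fileext = ".tsv")
  write_burial_tsv(residue_burial(fr, params), pb)
  tab <- read.delim(pb)
  expect_named(tab, c("chain", "resnum", "resname", "asa_free",
                      "asa_complex", "pct_buried"))
  expect_equal(nrow(tab), 6L)
})
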