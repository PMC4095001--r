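# Independent oracle for the conservation statistics: direct counting
# over a presence schedule, bypassing contact detection entirely.
oracle_stats <- function(schedule, thresholds = c(0.5, 0.7, 0.9)) {
  n <- nrow(schedule)
  cr <- colSums(schedule) / n
  cr <- cr[cr > 0]
  nc_i <- rowSums(schedule)
  list(cr = unname(sort(cr, decreasing = TRUE)),
       mean_nc = mean(nc_i),
       c_t = vapply(thresholds, function(t) sum(cr >= t) / mean(nc_i),
                    numeric(1)))
}

test_that("the 10-frame worked example reproduces the enumerated statistics", {
  traj <- worked_toy()          # contacts in 10, 7 and 3 of 10 frames
  sets <- trajectory_contacts(traj)
  rec <- conservation_rates(sets)
  expect_equal(sort(rec$cr, decreasing = TRUE), c(1.0, 0.7, 0.3))
  expect_equal(sort(rec$nc, decreasing = TRUE), c(10L, 7L, 3L))

  nc_i <- vapply(sets, `[[`, integer(1), "n_contacts")
  expect_equal(sum(nc_i), 20L)
  summ <- conservation_coefficients(rec, nc_i)
  expect_equal(summ$mean_nc, 2.0)
  expect_equal(summ$nc_at_threshold, c(2L, 2L, 1L))
  expect_equal(summ$coefficients, c(1.0, 1.0, 0.5))

  # same numbers from the schedule-counting oracle
  orc <- oracle_stats(cbind(rep(TRUE, 10),
                            rep(c(TRUE, FALSE), c(7, 3)),
                            rep(c(TRUE, FALSE), c(3, 7))))
  expect_equal(sort(rec$cr, decreasing = TRUE), orc$cr)
  expect_equal(summ$coefficients, orc$c_t)
})

test_that("conservation rates hit the boundary cases exactly", {
  # present in all frames -> cr = 1; never present -> no record
  traj <- scripted_trajectory(
    slots = cbind(c(1, 2), c(1, 2)),
    schedule = cbind(rep(TRUE, 10), rep(FALSE, 10)),
    n_res_a = 3, n_res_b = 3)
  rec <- conservation_rates(trajectory_contacts(traj))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$cr, 1.0)
  expect_equal(rec$key_a, "A:1")

  # a contact at exactly the threshold fraction counts ("at least")
  traj7 <- scripted_trajectory(cbind(1, 1),
                               schedule = matrix(rep(c(TRUE, FALSE),
                                                     c(7, 3))),
                               n_res_a = 2, n_res_b = 2)
  rec7 <- conservation_rates(trajectory_contacts(traj7))
  expect_equal(rec7$cr, 0.7)
  s <- conservation_coefficients(rec7, vapply(trajectory_contacts(traj7),
                                              `[[`, integer(1),
                                              "n_contacts"))
  expect_equal(s$nc_at_threshold[s$thresholds == 0.70], 1L)
})

test_that("a single frame yields cr = 1 and unit coefficients", {
  traj <- scripted_trajectory(cbind(c(1, 2), c(1, 2)),
                              schedule = matrix(TRUE, 1, 2),
                              n_res_a = 3, n_res_b = 3)
  sets <- trajectory_contacts(traj)
  rec <- conservation_rates(sets)
  expect_true(all(rec$cr == 1))
  summ <- conservation_coefficients(rec, sets[[1]]$n_contacts)
  expect_equal(unname(summ$coefficients), rep(1.0, 3))
})

test_that("threshold monotonicity and the double-counting identity hold on randomized ensembles", {
  set.seed(99)
  for (rep in 1:100) {
    ns <- sample(1:5, 1)
    nf <- sample(2:12, 1)
    schedule <- matrix(runif(nf * ns) < runif(1, 0.2, 1), nf, ns)
    if (!any(schedule)) schedule[1, 1] <- TRUE
    traj <- scripted_trajectory(
      slots = cbind(seq_len(ns), seq_len(ns)),
      schedule = schedule, n_res_a = ns + 1, n_res_b = ns + 1)
    sets <- trajectory_contacts(traj)
    rec <- conservation_rates(sets)
    nc_i <- vapply(sets, `[[`, integer(1), "n_contacts")
    expect_equal(sum(rec$nc), sum(nc_i))          # identity
    summ <- conservation_coefficients(rec, nc_i)
    expect_true(all(diff(summ$coefficients) <= 1e-12))  # C_90 <= C_70 <= C_50
    expect_equal(summ$coefficients, oracle_stats(schedule)$c_t)
  }
})

test_that("coefficients above 1 are possible and are not clipped", {
  # 2 frames: frame 1 has contacts {a, b}, frame 2 has {} -> mean 1,
  # nc_50 = 2, C_50 = 2
  schedule <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  traj <- scripted_trajectory(cbind(1:2, 1:2), schedule = schedule,
                              n_res_a = 3, n_res_b = 3)
  sets <- trajectory_contacts(traj)
  rec <- conservation_rates(sets)
  summ <- conservation_coefficients(rec, c(2L, 0L))
  expect_equal(summ$coefficients[summ$thresholds == 0.5], 2.0)
})

test_that("degenerate inputs raise identified errors", {
  expect_error(conservation_rates(list()), class = "mdc_error_empty_input")
  traj <- scripted_trajectory(cbind(1, 1), schedule = matrix(FALSE, 3, 1),
                              n_res_a = 2, n_res_b = 2)
  sets <- trajectory_contacts(traj)
  rec <- conservation_rates(sets)
  expect_equal(nrow(rec), 0L)
  expect_error(conservation_coefficients(rec, rep(0L, 3)),
               class = "mdc_error_no_contacts")
  expect_error(conservation_coefficients(rec, rep(0L, 2)),
               class = "mdc_error_bad_input")
  expect_error(conservation_coefficients(rec, rep(1L, 3), thresholds = 0),
               class = "mdc_error_bad_threshold")
})

test_that("the consensus matrix places rates at the right cells and zeros elsewhere", {
  traj <- worked_toy()
  sets <- trajectory_contacts(traj)
  rec <- conservation_rates(sets)
  m <- consensus_matrix(rec, traj$registry)
  expect_equal(dim(m), c(sum(traj$registry$partner == "A"),
                         sum(traj$registry$partner == "B")))
  expect_equal(sum(m > 0), 3L)
  expect_equal(unname(m["A:1", "B:1"]), 1.0)
  expect_equal(unname(m["A:2", "B:2"]), 0.7)
  expect_equal(unname(m["A:3", "B:3"]), 0.3)
  expect_true(all(m >= 0 & m <= 1))

  # no records -> all-zero matrix
  m0 <- consensus_matrix(rec[0, ], traj$registry)
  expect_true(all(m0 == 0))

  # registry mismatch -> error
  expect_error(consensus_matrix(rec, traj$registry[-1, ]),
               class = "mdc_error_registry_mismatch")
})

test_that("record and summary writers emit the documented tables", {
  traj <- worked_toy()
  sets <- trajectory_contacts(traj)
  rec <- conservation_rates(sets)
  summ <- conservation_coefficients(rec,
                                    vapply(sets, `[[`, integer(1),
                                           "n_contacts"))
  p <- tempfile(fileext = ".tsv")
  write_records_tsv(rec, p)
  tab <- read.delim(p, colClasses = c(CR_kl = "character"))
  expect_named(tab, c("chain_A", "resnum_A", "resname_A", "chain_B",
                      "resnum_B", "resname_B", "nc_kl", "CR_kl"))
  expect_equal(tab$CR_kl, c("1.00", "0.70", "0.30"))

  ps <- tempfile(fileext = ".tsv")
  write_summary(summ, ps)
  lines <- readLines(ps)
  expect_true(any(grepl("^C_70\t2\t1.00$", lines)))
  expect_true(any(grepl("^C_90\t1\t0.50$", lines)))

  pm <- tempfile(fileext = ".txt")
  write_consensus_matrix(consensus_matrix(rec, traj$registry), pm)
  m_back <- as.matrix(read.delim(pm, row.names = 1, check.names = FALSE))
  expect_equal(m_back["A:2", "B:2"], 0.7)
})
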